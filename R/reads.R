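#' Configuration of read filtering and OTU clustering
#'
#' Defaults follow standard practice for fungal ITS2 pyrosequencing data:
#' 3' tails trimmed at a minimum Phred quality of 27, reads shorter than
#' 150 bp discarded, reads assembled within each sample at 97% similarity and
#' the within-sample consensus sequences assembled across samples at 95%
#' (ITS-appropriate; use 0.998 for a conserved marker such as rbcL), OTUs with
#' fewer than five reads in every sample discarded, and samples with fewer
#' than 20 high-quality reads excluded.
#'
#' @param min_tail_quality Minimum Phred score retained at the 3' end.
#' @param min_length Minimum read length after trimming (bases).
#' @param within_sample_similarity Similarity cutoff for within-sample
#'   clustering, in (0, 1].
#' @param among_sample_similarity Similarity cutoff for among-sample
#'   clustering of within-sample consensi.
#' @param min_reads_per_otu An OTU is kept only if it reaches this many reads
#'   in at least one sample.
#' @param min_reads_per_sample Samples with fewer high-quality reads than this
#'   are excluded.
#' @return An object of class `cluster_config`.
#' @export
cluster_config <- function(min_tail_quality = 27L, min_length = 150L,
                           within_sample_similarity = 0.97,
                           among_sample_similarity = 0.95,
                           min_reads_per_otu = 5L,
                           min_reads_per_sample = 20L) {
  if (within_sample_similarity <= 0 || within_sample_similarity > 1 ||
      among_sample_similarity <= 0 || among_sample_similarity > 1)
    stop("similarity cutoffs must be in (0, 1]")
  if (min_tail_quality < 0 || min_length < 0 || min_reads_per_otu < 0 ||
      min_reads_per_sample < 0)
    stop("thresholds must be >= 0")
  structure(list(min_tail_quality = as.integer(min_tail_quality),
                 min_length = as.integer(min_length),
                 within_sample_similarity = within_sample_similarity,
                 among_sample_similarity = among_sample_similarity,
                 min_reads_per_otu = as.integer(min_reads_per_otu),
                 min_reads_per_sample = as.integer(min_reads_per_sample)),
            class = "cluster_config")
}

#' Quality-trim 3' tails and length-filter reads
#'
#' Each read is truncated at its last base with Phred quality at or above
#' `min_tail_quality` (interior low-quality bases are kept); reads shorter
#' than `min_length` after trimming are removed. Reads without a quality
#' string pass through untrimmed and are only length-filtered.
#'
#' @param reads Data frame with columns `read_id`, `sample_id`, `sequence`
#'   and optionally `quality` (Phred+33 string of the same length).
#' @param config A [cluster_config()].
#' @return The filtered data frame (same columns, trimmed sequences).
#' @export
trim_and_filter <- function(reads, config = cluster_config()) {
  stopifnot(is.data.frame(reads), all(c("sample_id", "sequence") %in% names(reads)))
  if ("quality" %in% names(reads) && nrow(reads) > 0) {
    bad <- which(nchar(reads$quality) != nchar(reads$sequence))
    if (length(bad) > 0)
      stop(sprintf("malformed record(s): quality/sequence length mismatch at row(s) %s",
                   paste(utils::head(bad, 5L), collapse = ", ")))
    keep_len <- vapply(reads$quality, function(q) {
      qs <- utf8ToInt(q) - 33L
      ok <- which(qs >= config$min_tail_quality)
      if (length(ok) == 0L) 0L else ok[length(ok)]
    }, integer(1), USE.NAMES = FALSE)
    reads$sequence <- substr(reads$sequence, 1L, keep_len)
    reads$quality <- substr(reads$quality, 1L, keep_len)
  }
  reads[nchar(reads$sequence) >= config$min_length, , drop = FALSE]
}

# ACGTN scoring: +1 for identical letters, 0 otherwise; gap columns carry a
# small penalty so gaps are only opened when they buy at least one match
identity_submat <- function() {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(0, 5, 5, dimnames = list(b, b))
  diag(m) <- 1
  m
}

#' Global-alignment identity between two sequences
#'
#' Needleman-Wunsch global alignment (match = 1, mismatch = 0, gap columns
#' penalized at 0.5 so they are used only when they recover matches);
#' identity is the number of matched columns divided by the total number of
#' alignment columns, with gap columns counting as mismatches. Symmetric, and
#' `pairwise_identity(a, a) == 1`.
#'
#' @param a,b Nucleotide strings over A/C/G/T/N.
#' @return Identity in \[0, 1\].
#' @examples
#' pairwise_identity("ACGTACGT", "ACGTACGA")  # 7/8
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = identity_submat(),
                                       gapOpening = 0, gapExtension = 0.5)
  Biostrings::nmatch(aln) / nchar(as.character(Biostrings::pattern(aln)))
}

# all-pairs identity matrix; one vectorized alignment call per subject
identity_matrix <- function(seqs) {
  n <- length(seqs)
  m <- diag(1, n)
  if (n < 2L) return(m)
  sm <- identity_submat()
  set <- Biostrings::DNAStringSet(seqs)
  for (i in seq_len(n - 1L)) {
    aln <- Biostrings::pairwiseAlignment(set[(i + 1L):n], set[[i]],
                                         type = "global",
                                         substitutionMatrix = sm,
                                         gapOpening = 0, gapExtension = 0.5)
    id <- Biostrings::nmatch(aln) /
      nchar(as.character(Biostrings::pattern(aln)))
    m[i, (i + 1L):n] <- id
    m[(i + 1L):n, i] <- id
  }
  m
}

# complete-linkage agglomeration on a distance matrix, merging while the
# smallest cluster-pair distance is within `radius`; ties broken by the
# smallest (i, j) cluster-index pair, making the result independent of the
# input order once sequences are canonically sorted
agglomerate_complete <- function(D, radius) {
  n <- nrow(D)
  eps <- 1e-9
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  W <- D
  W[lower.tri(W, diag = TRUE)] <- Inf  # candidate pairs, i < j
  repeat {
    if (sum(active) < 2L) break
    dmin <- min(W)
    if (!is.finite(dmin) || dmin > radius + eps) break
    cand <- which(W <= dmin + eps, arr.ind = TRUE)
    k <- order(cand[, 1L], cand[, 2L])[1L]   # smallest (i, j) among ties
    i <- cand[k, 1L]; j <- cand[k, 2L]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    for (t in which(active)) {               # complete-linkage update
      if (t == i || t == j) next
      dt <- max(D[i, t], D[j, t])
      D[i, t] <- dt; D[t, i] <- dt
      if (t > i) W[i, t] <- dt else W[t, i] <- dt
    }
    active[j] <- FALSE
    W[j, ] <- Inf; W[, j] <- Inf
  }
  clusters[active]
}

# majority-rule consensus of near-identical member sequences: members are
# star-aligned to the first (canonical head) member; insertions relative to
# the head are dropped; per-column majority over {A,C,G,T,N,-} weighted by
# member abundance; base ties resolved alphabetically; a column is removed
# only when the gap strictly wins
majority_consensus <- function(seqs, weights = rep(1, length(seqs))) {
  head_seq <- seqs[1]
  if (all(seqs == head_seq)) return(head_seq)
  L <- nchar(head_seq)
  letters5 <- c("A", "C", "G", "T", "N", "-")
  tab <- matrix(0, length(letters5), L, dimnames = list(letters5, NULL))
  hc <- strsplit(head_seq, "")[[1]]
  tab[cbind(match(hc, letters5), seq_len(L))] <- weights[1]
  others <- setdiff(seq_along(seqs), 1L)
  if (length(others) > 0) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(seqs[others]), head_seq, type = "global",
      substitutionMatrix = identity_submat(), gapOpening = 0, gapExtension = 0.5)
    pat <- as.character(Biostrings::pattern(aln))
    sub <- as.character(Biostrings::subject(aln))
    for (k in seq_along(others)) {
      pc <- strsplit(pat[k], "")[[1]]
      sc <- strsplit(sub[k], "")[[1]]
      keep <- sc != "-"
      cols <- seq_len(sum(keep))
      tab[cbind(match(pc[keep], letters5), cols)] <-
        tab[cbind(match(pc[keep], letters5), cols)] + weights[others[k]]
    }
  }
  cons <- character(L)
  for (j in seq_len(L)) {
    col <- tab[, j]
    base_best <- names(which.max(col[1:5]))  # alphabetical tie-break via order
    if (col["-"] > col[base_best]) cons[j] <- "" else cons[j] <- base_best
  }
  paste(cons, collapse = "")
}

#' Complete-linkage consensus clustering of sequences
#'
#' Agglomerative complete-linkage clustering on 1 - identity distance,
#' stopping at radius `1 - cutoff`, so that every pair of sequences within a
#' cluster has identity >= `cutoff`. Sequences are first canonically sorted
#' (descending abundance, then lexicographic) and identical sequences pooled;
#' merge-distance ties are broken by the smallest cluster index, which makes
#' the partition invariant to the input order. Each cluster is summarized by
#' a majority-rule consensus sequence.
#'
#' @param seqs Character vector of sequences.
#' @param cutoff Similarity cutoff in (0, 1].
#' @param abundance Per-sequence weights (read counts); default 1 each.
#' @return A list of clusters, each with elements `consensus`, `members`
#'   (indices into `seqs`) and `abundance` (total weight).
#' @examples
#' consensus_cluster(c("ACGTACGT", "ACGTACGT", "TTTTTTTT"), cutoff = 0.97)
#' @export
consensus_cluster <- function(seqs, cutoff, abundance = rep(1, length(seqs))) {
  if (length(seqs) == 0L) return(list())
  if (cutoff <= 0 || cutoff > 1) stop("'cutoff' must be in (0, 1]")
  if (any(!nzchar(seqs))) stop("sequences must be non-empty")
  stopifnot(length(abundance) == length(seqs))

  # pool identical sequences, then canonical order
  useq <- unique(seqs)
  uab <- vapply(useq, function(s) sum(abundance[seqs == s]), numeric(1),
                USE.NAMES = FALSE)
  ord <- order(-uab, useq)
  useq <- useq[ord]; uab <- uab[ord]

  D <- 1 - identity_matrix(useq)
  groups <- agglomerate_complete(D, radius = 1 - cutoff)
  # deterministic output order: by canonical index of each cluster head
  groups <- groups[order(vapply(groups, min, integer(1)))]
  lapply(groups, function(g) {
    g <- sort(g)
    members <- which(seqs %in% useq[g])
    list(consensus = majority_consensus(useq[g], uab[g]),
         members = members,
         abundance = sum(uab[g]))
  })
}

#' Two-stage OTU construction with abundance filters
#'
#' Stage 1 clusters reads within each sample at `within_sample_similarity`
#' and replaces them by within-sample consensus sequences (denoising). Stage
#' 2 clusters those consensi across samples at `among_sample_similarity`; the
#' among-sample consensus sequences are the OTUs. Afterwards, singleton OTUs
#' (one read in total) are removed, OTUs that never reach
#' `min_reads_per_otu` reads in any single sample are removed, and samples
#' with fewer than `min_reads_per_sample` high-quality reads are excluded.
#'
#' @param reads Data frame with `read_id`, `sample_id`, `sequence` and
#'   optionally `quality`; quality trimming and length filtering are applied
#'   when a `quality` column is present.
#' @param config A [cluster_config()].
#' @return Object of class `otu_table`: list with `counts` (integer matrix,
#'   samples x OTUs), `consensus` (named character), `excluded_samples`, and
#'   `log` (a data frame with the filtering waterfall).
#' @export
two_stage_otu_pipeline <- function(reads, config = cluster_config()) {
  stopifnot(is.data.frame(reads))
  log <- data.frame(stage = "input", reads = nrow(reads),
                    otus = NA_integer_, samples = length(unique(reads$sample_id)))
  if (nrow(reads) == 0L) {
    return(structure(list(counts = matrix(0L, 0, 0), consensus = character(),
                          excluded_samples = character(), log = log),
                     class = "otu_table"))
  }
  reads <- trim_and_filter(reads, config)
  log <- rbind(log, data.frame(stage = "quality_filtered", reads = nrow(reads),
                               otus = NA, samples = length(unique(reads$sample_id))))
  samples <- sort(unique(reads$sample_id))
  hq_reads <- vapply(samples, function(s) sum(reads$sample_id == s), integer(1))

  # stage 1: within-sample clustering
  consensi <- list()
  for (s in samples) {
    sub <- reads$sequence[reads$sample_id == s]
    if (length(sub) == 0L) next
    cl <- consensus_cluster(sub, config$within_sample_similarity)
    consensi[[s]] <- data.frame(
      sample_id = s,
      sequence = vapply(cl, `[[`, "", "consensus"),
      n_reads = vapply(cl, `[[`, numeric(1), "abundance"),
      stringsAsFactors = FALSE)
  }
  wtab <- do.call(rbind, consensi)
  log <- rbind(log, data.frame(stage = "within_sample_consensi",
                               reads = sum(wtab$n_reads), otus = nrow(wtab),
                               samples = length(unique(wtab$sample_id))))

  # stage 2: among-sample clustering of within-sample consensi
  cl2 <- consensus_cluster(wtab$sequence, config$among_sample_similarity,
                           abundance = wtab$n_reads)
  otu_ids <- sprintf("OTU%04d", seq_along(cl2))
  counts <- matrix(0L, length(samples), length(cl2),
                   dimnames = list(samples, otu_ids))
  for (k in seq_along(cl2)) {
    mem <- cl2[[k]]$members
    agg <- tapply(wtab$n_reads[mem], wtab$sample_id[mem], sum)
    counts[names(agg), k] <- as.integer(agg)
  }
  consensus <- stats::setNames(vapply(cl2, `[[`, "", "consensus"), otu_ids)
  log <- rbind(log, data.frame(stage = "otus_raw", reads = sum(counts),
                               otus = ncol(counts), samples = nrow(counts)))

  # singleton OTUs: one read in total
  keep <- colSums(counts) > 1L
  counts <- counts[, keep, drop = FALSE]; consensus <- consensus[keep]
  log <- rbind(log, data.frame(stage = "singletons_removed", reads = sum(counts),
                               otus = ncol(counts), samples = nrow(counts)))

  # OTUs below min_reads_per_otu in every sample
  keep <- apply(counts, 2L, max) >= config$min_reads_per_otu
  counts <- counts[, keep, drop = FALSE]; consensus <- consensus[keep]
  log <- rbind(log, data.frame(stage = "low_count_otus_removed",
                               reads = sum(counts), otus = ncol(counts),
                               samples = nrow(counts)))

  # shallow samples (judged on high-quality reads entering assembly)
  shallow <- samples[hq_reads < config$min_reads_per_sample]
  counts <- counts[setdiff(samples, shallow), , drop = FALSE]
  empty_otu <- colSums(counts) == 0L
  counts <- counts[, !empty_otu, drop = FALSE]
  consensus <- consensus[!empty_otu]
  log <- rbind(log, data.frame(stage = "shallow_samples_removed",
                               reads = sum(counts), otus = ncol(counts),
                               samples = nrow(counts)))

  structure(list(counts = counts, consensus = consensus,
                 excluded_samples = shallow, log = log),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d OTUs (%d reads); %d sample(s) excluded\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts),
              length(x$excluded_samples)))
  print(x$log, row.names = FALSE)
  invisible(x)
}
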