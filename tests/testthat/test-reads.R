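phred <- function(q, n) strrep(intToUtf8(q + 33L), n)

test_that("3' tails are trimmed at the quality threshold and short reads dropped", {
  reads <- data.frame(
    read_id = c("r1", "r2", "r3"),
    sample_id = "s1",
    sequence = c(strrep("A", 200), strrep("C", 200), strrep("G", 160)),
    quality = c(paste0(phred(30, 140), phred(20, 60)),  # low tail -> 140 bp
                phred(30, 200),                          # untouched
                paste0(phred(30, 150), phred(20, 10))),  # trims to 150, kept
    stringsAsFactors = FALSE)
  out <- trim_and_filter(reads, cluster_config())
  expect_identical(out$read_id, c("r2", "r3"))
  expect_equal(nchar(out$sequence), c(200L, 150L))

  # retained set equals brute-force per-read application of the rule
  set.seed(8)
  n <- 200
  lens <- sample(140:220, n, replace = TRUE)
  qs <- lapply(lens, function(L) sample(c(20L, 27L, 35L), L, replace = TRUE,
                                        prob = c(0.2, 0.2, 0.6)))
  batch <- data.frame(
    read_id = sprintf("r%03d", 1:n), sample_id = "s1",
    sequence = vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""), ""),
    quality = vapply(qs, function(q) intToUtf8(q + 33L), ""),
    stringsAsFactors = FALSE)
  got <- trim_and_filter(batch, cluster_config())
  want_len <- vapply(qs, function(q) {
    ok <- which(q >= 27L); if (length(ok) == 0) 0L else ok[length(ok)]
  }, 0L)
  expect_identical(got$read_id, batch$read_id[want_len >= 150L])
  expect_equal(nchar(got$sequence), want_len[want_len >= 150L])
})

test_that("malformed records are rejected with their index", {
  bad <- data.frame(read_id = c("a", "b"), sample_id = "s",
                    sequence = c("ACGT", "ACGT"),
                    quality = c("IIII", "III"), stringsAsFactors = FALSE)
  expect_error(trim_and_filter(bad), "row\\(s\\) 2")
})

test_that("pairwise identity matches its definition and the DP oracle", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"), 1)
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGA"), 7 / 8)
  expect_error(pairwise_identity("", "ACGT"), "non-empty")
  # symmetry
  expect_equal(pairwise_identity("ACGTTGCA", "AGGTTACA"),
               pairwise_identity("AGGTTACA", "ACGTTGCA"))
  # substitution-mutated random 100-mers vs quadratic DP reference
  set.seed(10)
  for (rate in c(0.02, 0.05, 0.10)) {
    for (k in 1:5) {
      a <- sample(c("A", "C", "G", "T"), 100, TRUE)
      b <- a
      mut <- runif(100) < rate
      b[mut] <- vapply(b[mut], function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
      sa <- paste(a, collapse = ""); sb <- paste(b, collapse = "")
      expect_equal(pairwise_identity(sa, sb), dp_identity(sa, sb))
    }
  }
})

test_that("consensus clustering handles degenerate and constructed cases", {
  one <- consensus_cluster(rep("ACGTACGTACGT", 4), 0.97)
  expect_length(one, 1)
  expect_equal(one[[1]]$consensus, "ACGTACGTACGT")
  expect_equal(one[[1]]$abundance, 4)

  # two 100-bp groups at 90% inter-group identity, cutoff 0.95 -> 2 OTUs
  set.seed(2)
  base <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  other <- strsplit(base, "")[[1]]
  pos <- sample(100, 10)
  other[pos] <- vapply(other[pos], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  other <- paste(other, collapse = "")
  expect_equal(pairwise_identity(base, other), 0.90)
  cl <- consensus_cluster(c(base, base, other, other), 0.95)
  expect_length(cl, 2)

  expect_error(consensus_cluster("ACGT", 1.5), "cutoff")
})

test_that("clustering equals the brute-force complete-linkage oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    refs <- emit_reference_set(5, length = 60, divergence = 0.06)
    cm <- matrix(rpois(5, 6) + 1L, 1, 5,
                 dimnames = list("s1", names(refs)))
    rd <- emit_reads(cm, refs, error_rate = 0.03)
    cl <- consensus_cluster(rd$sequence, 0.95)
    # rebuild the canonical ordering the package documents, then run the
    # independent naive agglomerator on the same distances
    seqs <- rd$sequence
    useq <- unique(seqs)
    uab <- vapply(useq, function(s) sum(seqs == s), 0, USE.NAMES = FALSE)
    ord <- order(-uab, useq)
    useq <- useq[ord]
    D <- 1 - mycoroot:::identity_matrix(useq)
    want <- naive_complete_linkage(D, radius = 0.05)
    got <- lapply(cl, function(g) sort(match(unique(seqs[g$members]), useq)))
    expect_equal(partition_key(got), partition_key(want))
  }
})

test_that("cluster partitions are invariant to input order", {
  set.seed(33)
  refs <- emit_reference_set(4, length = 80, divergence = 0.08)
  cm <- matrix(c(5L, 3L, 8L, 2L), 1, 4, dimnames = list("s1", names(refs)))
  rd <- emit_reads(cm, refs, error_rate = 0.02)
  cl1 <- consensus_cluster(rd$sequence, 0.9)
  perm <- sample(nrow(rd))
  cl2 <- consensus_cluster(rd$sequence[perm], 0.9)
  key <- function(cl, seqs) partition_key(lapply(cl, function(g)
    sort(unique(seqs[g$members]))))
  expect_equal(key(cl1, rd$sequence), key(cl2, rd$sequence[perm]))
  expect_setequal(vapply(cl1, `[[`, "", "consensus"),
                  vapply(cl2, `[[`, "", "consensus"))
})

test_that("two-stage pipeline recovers ground-truth OTUs and applies filters", {
  for (seed in 1:5) {
    k <- 4L
    refs <- emit_reference_set(k, length = 150, divergence = 0.05, seed = seed)
    cm <- matrix(rpois(3 * k, 8) + 5L, 3, k,
                 dimnames = list(paste0("s", 1:3), names(refs)))
    rd <- emit_reads(cm, refs, error_rate = 0.01, seed = seed + 100)
    ot <- two_stage_otu_pipeline(rd, cluster_config(min_length = 100))
    expect_equal(ncol(ot$counts), k)
    # a few reads may be lost to the singleton/low-count OTU filters
    expect_gte(sum(ot$counts), 0.9 * sum(cm))
  }
})

test_that("low-count OTU and shallow-sample filters follow their thresholds", {
  refs <- emit_reference_set(3, length = 150, divergence = 0.08, seed = 6)
  # OTU3 has max per-sample count 4 -> removed; OTU2 reaches 5 once -> kept
  cm <- rbind(s1 = c(30L, 5L, 4L), s2 = c(30L, 2L, 4L))
  colnames(cm) <- names(refs)
  rd <- emit_reads(cm, refs, error_rate = 0, seed = 7)
  ot <- two_stage_otu_pipeline(rd, cluster_config(min_length = 100))
  expect_equal(ncol(ot$counts), 2L)
  expect_equal(sort(unname(colSums(ot$counts))), c(7, 60))

  # a sample with 19 reads is excluded, 20 reads is kept
  cm2 <- rbind(s19 = c(19L, 0L, 0L), s20 = c(20L, 0L, 0L))
  colnames(cm2) <- names(refs)
  rd2 <- emit_reads(cm2, refs, error_rate = 0, seed = 8)
  ot2 <- two_stage_otu_pipeline(rd2, cluster_config(min_length = 100))
  expect_identical(ot2$excluded_samples, "s19")
  expect_identical(rownames(ot2$counts), "s20")
})

test_that("raising the per-OTU read threshold never increases the OTU count", {
  refs <- emit_reference_set(6, length = 120, divergence = 0.06, seed = 9)
  set.seed(9)
  cm <- matrix(rpois(4 * 6, 3), 4, 6,
               dimnames = list(paste0("s", 1:4), names(refs)))
  rd <- emit_reads(cm, refs, error_rate = 0.01, seed = 10)
  n_otus <- vapply(c(1L, 3L, 5L, 8L), function(th) {
    ot <- two_stage_otu_pipeline(
      rd, cluster_config(min_length = 100, min_reads_per_otu = th,
                         min_reads_per_sample = 1L))
    ncol(ot$counts)
  }, 0L)
  expect_true(all(diff(n_otus) <= 0))
})
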