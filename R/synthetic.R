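#' Sampling-grid specification
#'
#' Describes a regular rectangular sampling grid. Positions are indexed by
#' 0-based (row, col) and live at `row * spacing`, `col * spacing` metres, so
#' Euclidean distances between positions are in metres.
#'
#' @param n_rows,n_cols Number of grid rows and columns (default 30 x 40,
#'   i.e. 1200 sampling positions).
#' @param spacing Metres between neighbouring positions (default 1).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(10, 10)
#' g$n_rows * g$n_cols
#' @export
grid_spec <- function(n_rows = 30L, n_cols = 40L, spacing = 1) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || n_rows < 1L || is.na(n_cols) || n_cols < 1L)
    stop("grid dimensions must be integers >= 1")
  if (!is.finite(spacing) || spacing <= 0) stop("'spacing' must be > 0")
  structure(list(n_rows = n_rows, n_cols = n_cols, spacing = spacing),
            class = "grid_spec")
}

#' Parameters of the synthetic root-community generator
#'
#' Defaults emulate a mixed subtropical forest plot sampled on a 30 x 40 grid
#' at 1-m spacing: about a quarter of root samples fagaceous (ectomycorrhizal
#' hosts), three fungal guilds (ectomycorrhizal, arbuscular mycorrhizal,
#' unknown) with strong host-guild preference, spillover of ectomycorrhizal
#' fungi onto non-fagaceous roots adjacent to fagaceous ones, overdispersed
#' per-sample read depths (mean ~99 reads, SD ~62) and a small fraction of
#' contaminant reads.
#'
#' @param n_plant_species Total number of plant species (>= 2; up to three of
#'   them fagaceous).
#' @param fagaceous_fraction Fraction of sampling positions occupied by
#'   fagaceous hosts.
#' @param host_clump_length Spatial correlation scale (metres) of host
#'   identity; must be > 0. Small values approach spatial independence.
#' @param n_ecm_otus,n_am_otus,n_unknown_otus OTU richness per guild.
#' @param pref_ecm_on_fagaceous Multiplier (>= 1) on ectomycorrhizal occupancy
#'   odds for fagaceous hosts.
#' @param pref_am_on_nonfagaceous Multiplier (>= 1) on arbuscular-mycorrhizal
#'   occupancy odds for non-fagaceous hosts.
#' @param spillover_strength Increase in ectomycorrhizal occupancy odds on a
#'   non-fagaceous root per adjacent fagaceous position (>= 0): odds are
#'   multiplied by `1 + spillover_strength * n_adjacent_fagaceous`.
#' @param base_occupancy Named vector: median baseline per-OTU occupancy
#'   probability for `EcM`, `AM` and `unknown` OTUs on a host without any
#'   preference multiplier.
#' @param abundance_sdlog Log-scale SD of among-OTU heterogeneity in occupancy
#'   odds and read abundance.
#' @param mean_depth Mean reads per sample; must be > 0.
#' @param depth_dispersion Target SD of reads per sample. When
#'   `depth_dispersion^2 > mean_depth` depths are negative binomial, else
#'   Poisson.
#' @param contaminant_rate Proportion of reads drawn from the full OTU pool
#'   irrespective of residency (flagged as contaminants in the truth).
#' @param neighborhood Adjacency definition used for spillover, `"rook4"`
#'   (N/S/E/W) or `"moore8"`; kept identical to the spatial-analysis default
#'   so recovery tests are self-consistent.
#' @param seed Optional RNG seed; fixing it fixes the generated dataset.
#' @return An object of class `community_params`.
#' @export
community_params <- function(n_plant_species = 12L,
                             fagaceous_fraction = 0.252,
                             host_clump_length = 3,
                             n_ecm_otus = 132L,
                             n_am_otus = 58L,
                             n_unknown_otus = 390L,
                             pref_ecm_on_fagaceous = 5,
                             pref_am_on_nonfagaceous = 40,
                             spillover_strength = 0.5,
                             base_occupancy = c(EcM = 0.0028, AM = 0.0003,
                                                unknown = 0.0045),
                             abundance_sdlog = 1,
                             mean_depth = 98.7,
                             depth_dispersion = 62.2,
                             contaminant_rate = 0.02,
                             neighborhood = c("rook4", "moore8"),
                             seed = NULL) {
  neighborhood <- match.arg(neighborhood)
  p <- list(n_plant_species = as.integer(n_plant_species),
            fagaceous_fraction = fagaceous_fraction,
            host_clump_length = host_clump_length,
            n_ecm_otus = as.integer(n_ecm_otus),
            n_am_otus = as.integer(n_am_otus),
            n_unknown_otus = as.integer(n_unknown_otus),
            pref_ecm_on_fagaceous = pref_ecm_on_fagaceous,
            pref_am_on_nonfagaceous = pref_am_on_nonfagaceous,
            spillover_strength = spillover_strength,
            base_occupancy = base_occupancy,
            abundance_sdlog = abundance_sdlog,
            mean_depth = mean_depth,
            depth_dispersion = depth_dispersion,
            contaminant_rate = contaminant_rate,
            neighborhood = neighborhood,
            seed = seed)
  if (p$n_plant_species < 2L) stop("need at least 2 plant species")
  if (fagaceous_fraction < 0 || fagaceous_fraction > 1)
    stop("'fagaceous_fraction' must be in [0, 1]")
  if (!is.finite(host_clump_length) || host_clump_length <= 0)
    stop("'host_clump_length' must be > 0")
  if (any(c(p$n_ecm_otus, p$n_am_otus, p$n_unknown_otus) < 0L))
    stop("OTU counts must be >= 0")
  if (pref_ecm_on_fagaceous < 1 || pref_am_on_nonfagaceous < 1)
    stop("preference multipliers must be >= 1")
  if (spillover_strength < 0) stop("'spillover_strength' must be >= 0")
  if (!all(c("EcM", "AM", "unknown") %in% names(base_occupancy)) ||
      any(base_occupancy <= 0) || any(base_occupancy >= 1))
    stop("'base_occupancy' needs EcM/AM/unknown probabilities in (0, 1)")
  if (!is.finite(mean_depth) || mean_depth <= 0)
    stop("'mean_depth' must be > 0")
  if (depth_dispersion < 0) stop("'depth_dispersion' must be >= 0")
  if (contaminant_rate < 0 || contaminant_rate > 1)
    stop("'contaminant_rate' must be in [0, 1]")
  structure(p, class = "community_params")
}

# Gaussian smoothing of a matrix-valued white-noise field, separable kernel,
# reflected edges; length scale in grid cells.
smooth_field <- function(m, scale) {
  if (scale < 0.3) return(m)  # kernel narrower than one cell: identity
  h <- max(1L, as.integer(ceiling(3 * scale)))
  k <- stats::dnorm(seq(-h, h), sd = scale)
  k <- k / sum(k)
  conv1 <- function(x) {
    n <- length(x)
    idx <- c(pmin(h:1, n), seq_len(n), pmax(n - seq_len(h) + 1L, 1L))
    stats::convolve(x[idx], k, type = "filter")
  }
  m <- apply(m, 2L, conv1)
  t(apply(m, 1L, conv1))
}

neighbor_offsets <- function(neighborhood) {
  rook <- cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  if (neighborhood == "rook4") rook
  else rbind(rook, cbind(dr = c(-1L, -1L, 1L, 1L), dc = c(-1L, 1L, -1L, 1L)))
}

nonfag_families <- c("Lauraceae", "Euphorbiaceae", "Theaceae", "Apocynaceae",
                     "Rubiaceae", "Symplocaceae", "Vitaceae")

#' Assign host plants to grid positions
#'
#' Hosts are spatially clumped: smoothed Gaussian random fields (one deciding
#' fagaceous vs non-fagaceous status by a rank threshold, one per species for
#' identity within each group) give tunable patch sizes while keeping the
#' realized fagaceous fraction at its target.
#'
#' @param grid A [grid_spec()].
#' @param params A [community_params()].
#' @param seed Optional seed (defaults to `params$seed`).
#' @return Data frame with one row per position: `sample_id`, 0-based `row`
#'   and `col`, `host_species`, `host_family`.
#' @export
generate_hosts <- function(grid, params, seed = params$seed) {
  stopifnot(inherits(grid, "grid_spec"), inherits(params, "community_params"))
  if (!is.null(seed)) set.seed(seed)
  .generate_hosts(grid, params)
}

.generate_hosts <- function(grid, params) {
  nr <- grid$n_rows; nc <- grid$n_cols; n <- nr * nc
  scale <- params$host_clump_length / grid$spacing
  fag_field <- smooth_field(matrix(stats::rnorm(n), nr, nc), scale)
  n_fag <- round(params$fagaceous_fraction * n)
  is_fag <- rank(-c(fag_field), ties.method = "first") <= n_fag

  n_fag_sp <- if (params$fagaceous_fraction > 0) min(3L, params$n_plant_species - 1L) else 0L
  n_non_sp <- params$n_plant_species - n_fag_sp
  pick_species <- function(k) {
    if (k == 1L) return(rep(1L, n))
    f <- vapply(seq_len(k),
                function(i) c(smooth_field(matrix(stats::rnorm(n), nr, nc), scale)),
                numeric(n))
    max.col(f, ties.method = "first")
  }
  sp <- character(n)
  if (n_fag_sp > 0L) {
    sp[is_fag] <- sprintf("fagaceous_sp%02d", pick_species(n_fag_sp)[is_fag])
  }
  sp[!is_fag] <- sprintf("nonfagaceous_sp%02d", pick_species(n_non_sp)[!is_fag])
  fam <- ifelse(is_fag, "Fagaceae",
                nonfag_families[(as.integer(sub(".*sp", "", sp)) - 1L) %%
                                  length(nonfag_families) + 1L])
  rows <- rep(seq_len(nr) - 1L, times = nc)
  cols <- rep(seq_len(nc) - 1L, each = nr)
  out <- data.frame(sample_id = sprintf("s%03d_%03d", rows, cols),
                    row = rows, col = cols,
                    host_species = sp, host_family = fam,
                    stringsAsFactors = FALSE)
  attr(out, "grid") <- grid
  out
}

# number of fagaceous neighbours for every position in a host table
count_fagaceous_neighbors <- function(hosts, grid, neighborhood) {
  off <- neighbor_offsets(neighborhood)
  fag <- matrix(FALSE, grid$n_rows, grid$n_cols)
  fag[cbind(hosts$row + 1L, hosts$col + 1L)] <- hosts$host_family == "Fagaceae"
  n_adj <- integer(nrow(hosts))
  for (i in seq_len(nrow(off))) {
    r <- hosts$row + 1L + off[i, "dr"]
    c <- hosts$col + 1L + off[i, "dc"]
    ok <- r >= 1L & r <= grid$n_rows & c >= 1L & c <= grid$n_cols
    n_adj[ok] <- n_adj[ok] + fag[cbind(r[ok], c[ok])]
  }
  n_adj
}

#' Simulate which fungal OTUs reside in each root sample
#'
#' Per-OTU baseline occupancy odds are lognormally heterogeneous around the
#' guild's `base_occupancy`. Ectomycorrhizal odds are multiplied by
#' `pref_ecm_on_fagaceous` on fagaceous hosts and by
#' `1 + spillover_strength * n_adjacent_fagaceous` on non-fagaceous hosts;
#' arbuscular-mycorrhizal odds by `pref_am_on_nonfagaceous` on non-fagaceous
#' hosts; unknown-guild OTUs are host-indifferent.
#'
#' @param hosts Host table from [generate_hosts()].
#' @param params A [community_params()].
#' @param seed Optional seed.
#' @return An object of class `myco_occupancy`: logical residency matrix
#'   (samples x OTUs), guild vector, per-OTU baseline odds and per-sample
#'   fagaceous-neighbour counts.
#' @export
simulate_occupancy <- function(hosts, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .simulate_occupancy(hosts, params)
}

.simulate_occupancy <- function(hosts, params) {
  grid <- attr(hosts, "grid")
  stopifnot(!is.null(grid))
  guild <- rep(c("EcM", "AM", "unknown"),
               times = c(params$n_ecm_otus, params$n_am_otus, params$n_unknown_otus))
  S <- length(guild)
  otu_id <- sprintf("OTU%04d", seq_len(S))
  base_p <- params$base_occupancy[guild]
  odds0 <- base_p / (1 - base_p) *
    exp(stats::rnorm(S, 0, params$abundance_sdlog))
  n_adj <- count_fagaceous_neighbors(hosts, grid, params$neighborhood)
  is_fag <- hosts$host_family == "Fagaceae"

  mult <- matrix(1, nrow(hosts), S)
  ecm <- guild == "EcM"; am <- guild == "AM"
  mult[is_fag, ecm] <- params$pref_ecm_on_fagaceous
  mult[!is_fag, ecm] <- 1 + params$spillover_strength * n_adj[!is_fag]
  mult[!is_fag, am] <- params$pref_am_on_nonfagaceous
  odds <- sweep(mult, 2L, odds0, `*`)
  p <- odds / (1 + odds)
  occ <- matrix(stats::runif(length(p)) < p, nrow(hosts), S,
                dimnames = list(hosts$sample_id, otu_id))
  structure(list(occupancy = occ, guild = stats::setNames(guild, otu_id),
                 otu_id = otu_id, base_odds = odds0, n_adj_fagaceous = n_adj,
                 hosts = hosts),
            class = "myco_occupancy")
}

#' Simulate per-sample OTU read counts
#'
#' Sample depths are negative binomial with mean `mean_depth` and SD
#' `depth_dispersion` (Poisson when the target SD implies underdispersion).
#' A binomial share `contaminant_rate` of each sample's reads is drawn
#' uniformly from the full OTU pool and flagged as contaminant in the truth;
#' the rest are allocated multinomially among the sample's resident OTUs with
#' lognormal per-OTU abundance weights.
#'
#' @param occ A `myco_occupancy` from [simulate_occupancy()].
#' @param params A [community_params()].
#' @param seed Optional seed.
#' @return An object of class `myco_community` (see [simulate_community()]).
#' @export
simulate_reads <- function(occ, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .simulate_reads(occ, params)
}

.simulate_reads <- function(occ, params) {
  stopifnot(inherits(occ, "myco_occupancy"))
  if (params$mean_depth <= 0) stop("'mean_depth' must be > 0")
  n <- nrow(occ$occupancy); S <- ncol(occ$occupancy)
  w <- stats::rlnorm(S, 0, params$abundance_sdlog)
  mu <- params$mean_depth; v <- params$depth_dispersion^2
  depth <- if (v > mu) {
    stats::rnbinom(n, mu = mu, size = mu^2 / (v - mu))
  } else {
    stats::rpois(n, mu)
  }
  counts <- matrix(0L, n, S, dimnames = dimnames(occ$occupancy))
  contam <- matrix(0L, n, S, dimnames = dimnames(occ$occupancy))
  for (i in seq_len(n)) {
    if (depth[i] == 0L) next
    res <- which(occ$occupancy[i, ])
    n_cont <- if (length(res) > 0L) {
      stats::rbinom(1L, depth[i], params$contaminant_rate)
    } else {
      depth[i]
    }
    if (n_cont > 0L) {
      contam[i, ] <- tabulate(sample.int(S, n_cont, replace = TRUE), nbins = S)
    }
    n_res <- depth[i] - n_cont
    if (n_res > 0L) {
      counts[i, res] <- counts[i, res] +
        as.integer(stats::rmultinom(1L, n_res, prob = w[res]))
    }
  }
  counts <- counts + contam
  annotation <- make_annotation(occ$otu_id, occ$guild)
  structure(list(meta = occ$hosts, counts = counts, annotation = annotation,
                 truth = list(occupancy = occ$occupancy, guild = occ$guild,
                              contaminant_counts = contam, depth = depth,
                              n_adj_fagaceous = occ$n_adj_fagaceous,
                              abundance_weights = w, params = params,
                              grid = attr(occ$hosts, "grid"))),
            class = "myco_community")
}

# plausible taxonomic labels per guild; some genus/order slots left NA so that
# downstream "unidentified" pooling is exercised
make_annotation <- function(otu_id, guild) {
  S <- length(otu_id)
  phylum <- character(S); ord <- character(S); genus <- character(S)
  ecm_gen <- c("Russula", "Tomentella", "Lactarius", "Sebacina", "Clavulina", NA)
  ecm_ord <- c("Russulales", "Thelephorales", "Russulales", "Sebacinales",
               "Cantharellales", "Agaricales")
  unk_ord <- c("Helotiales", "Hypocreales", "Chaetothyriales", NA, NA)
  for (i in seq_len(S)) {
    g <- guild[i]
    if (g == "EcM") {
      k <- (i - 1L) %% length(ecm_gen) + 1L
      phylum[i] <- "Basidiomycota"; ord[i] <- ecm_ord[k]; genus[i] <- ecm_gen[k]
    } else if (g == "AM") {
      phylum[i] <- "Glomeromycota"; ord[i] <- "Glomerales"
      genus[i] <- c("Glomus", "Rhizophagus", NA)[(i - 1L) %% 3L + 1L]
    } else {
      phylum[i] <- "Ascomycota"
      ord[i] <- unk_ord[(i - 1L) %% length(unk_ord) + 1L]
      genus[i] <- NA
    }
  }
  data.frame(otu_id = otu_id, phylum = phylum, order = ord, genus = genus,
             guild = unname(guild), stringsAsFactors = FALSE)
}

#' Generate a complete synthetic grid community
#'
#' Runs [generate_hosts()], [simulate_occupancy()] and [simulate_reads()]
#' under a single seed. The result carries the observable data (host metadata,
#' read-count matrix, OTU annotation) plus the full generating truth.
#'
#' @param grid A [grid_spec()] (default 30 x 40 at 1 m).
#' @param params A [community_params()].
#' @param seed Seed fixing the whole dataset (defaults to `params$seed`).
#' @return Object of class `myco_community` with elements `meta`, `counts`,
#'   `annotation` and `truth`.
#' @examples
#' com <- simulate_community(grid_spec(8, 8), community_params(seed = 1))
#' dim(com$counts)
#' @export
simulate_community <- function(grid = grid_spec(), params = community_params(),
                               seed = params$seed) {
  if (!is.null(seed)) set.seed(seed)
  hosts <- .generate_hosts(grid, params)
  occ <- .simulate_occupancy(hosts, params)
  .simulate_reads(occ, params)
}

#' Realized adjacency-spillover odds ratio from the generating truth
#'
#' Cross-product odds ratio relating "has at least one resident
#' ectomycorrhizal OTU" to "has at least one adjacent fagaceous position",
#' over non-fagaceous samples, computed from true residency (not reads).
#'
#' @param com A `myco_community`.
#' @return Numeric odds ratio (may be `Inf`/`NaN` for degenerate tables).
#' @export
realized_spillover_or <- function(com) {
  stopifnot(inherits(com, "myco_community"))
  nf <- com$meta$host_family != "Fagaceae"
  ecm <- com$truth$guild == "EcM"
  has_ecm <- rowSums(com$truth$occupancy[nf, ecm, drop = FALSE]) > 0
  adj <- com$truth$n_adj_fagaceous[nf] > 0
  a <- sum(adj & has_ecm); b <- sum(adj & !has_ecm)
  c_ <- sum(!adj & has_ecm); d <- sum(!adj & !has_ecm)
  (a * d) / (b * c_)
}

#' @export
print.myco_community <- function(x, ...) {
  cat(sprintf("Synthetic root community: %d samples x %d OTUs\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  fagaceous samples: %d (%.1f%%)\n",
              sum(x$meta$host_family == "Fagaceae"),
              100 * mean(x$meta$host_family == "Fagaceae")))
  cat(sprintf("  reads/sample: mean %.1f, SD %.1f\n",
              mean(rowSums(x$counts)), stats::sd(rowSums(x$counts))))
  invisible(x)
}

#' Reference sequences for read emission
#'
#' Builds `n` OTU reference sequences by mutating a common random ancestor at
#' a fixed proportion of positions, giving a controlled divergence between
#' references for clustering tests.
#'
#' @param n Number of references.
#' @param length Sequence length in bases.
#' @param divergence Proportion of positions mutated per reference relative to
#'   the ancestor (pairwise divergence is about twice this for distinct
#'   references).
#' @param seed Optional seed.
#' @return Character vector of reference sequences named `OTU****`.
#' @export
emit_reference_set <- function(n, length = 200L, divergence = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, length, replace = TRUE)
  refs <- vapply(seq_len(n), function(i) {
    x <- anc
    k <- round(divergence * length)
    if (k > 0) {
      pos <- sample.int(length, k)
      x[pos] <- vapply(x[pos], function(b) sample(setdiff(bases, b), 1L), "")
    }
    paste(x, collapse = "")
  }, "")
  names(refs) <- sprintf("OTU%04d", seq_len(n))
  refs
}

#' Emit error-prone reads from reference sequences
#'
#' Expands a sample x OTU count matrix into individual reads: each read copies
#' its OTU's reference with independent per-base substitution errors, and gets
#' a Phred quality string that is uniformly high except for an optional
#' low-quality 3' tail (to exercise quality trimming).
#'
#' @param counts Integer matrix, samples x OTUs; column names must match
#'   `names(refs)`.
#' @param refs Named reference sequences from [emit_reference_set()].
#' @param error_rate Per-base substitution probability.
#' @param quality_high Phred score of the high-quality portion.
#' @param tail_length,tail_quality Length and Phred score of the low-quality
#'   3' tail appended by lengthening each read with random bases.
#' @param seed Optional seed.
#' @return Data frame `read_id`, `sample_id`, `sequence`, `quality`
#'   (Phred+33 string) with an `otu` column giving the true source OTU.
#' @export
emit_reads <- function(counts, refs, error_rate = 0.01, quality_high = 38L,
                       tail_length = 0L, tail_quality = 15L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(colnames(counts) %in% names(refs)))
  bases <- c("A", "C", "G", "T")
  out <- vector("list", sum(counts > 0))
  k <- 0L; serial <- 0L
  for (i in seq_len(nrow(counts))) {
    for (j in which(counts[i, ] > 0)) {
      ref <- strsplit(refs[[colnames(counts)[j]]], "")[[1]]
      reads <- vapply(seq_len(counts[i, j]), function(r) {
        x <- ref
        err <- stats::runif(length(x)) < error_rate
        if (any(err)) {
          x[err] <- vapply(x[err], function(b) sample(setdiff(bases, b), 1L), "")
        }
        if (tail_length > 0L) {
          x <- c(x, sample(bases, tail_length, replace = TRUE))
        }
        paste(x, collapse = "")
      }, "")
      qual <- paste(c(rep(intToUtf8(quality_high + 33L), length(ref)),
                      rep(intToUtf8(tail_quality + 33L), tail_length)),
                    collapse = "")
      k <- k + 1L
      out[[k]] <- data.frame(
        read_id = sprintf("read%06d", serial + seq_len(counts[i, j])),
        sample_id = rownames(counts)[i],
        sequence = reads, quality = qual,
        otu = colnames(counts)[j], stringsAsFactors = FALSE)
      serial <- serial + counts[i, j]
    }
  }
  if (k == 0L) {
    return(data.frame(read_id = character(), sample_id = character(),
                      sequence = character(), quality = character(),
                      otu = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out[seq_len(k)])
}
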