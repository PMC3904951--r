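#' Raup-Crick null-model dissimilarity
#'
#' Probabilistic beta-diversity between binary samples: for each pair, null
#' assemblages are drawn preserving each sample's observed richness, with
#' OTUs sampled (without replacement) with probability proportional to their
#' occurrence frequency across the community. The dissimilarity is the
#' fraction of null draws in which the pair shares at least as many OTUs as
#' observed, so values near 1 mean the pair shares less than expected by
#' chance (more dissimilar) and values near 0 mean it shares more.
#'
#' @param presence Binary matrix (samples x OTUs) with at least two samples.
#' @param n_null Number of null randomizations (default 999, minimum 99).
#' @param seed Optional seed.
#' @return Symmetric matrix in \[0, 1\] with zero diagonal, class
#'   `raup_crick`. Pairs involving a sample with zero OTUs are `NA` and
#'   listed in attribute `undefined_samples`.
#' @export
raup_crick <- function(presence, n_null = 999L, seed = NULL) {
  pres <- unclass(presence)
  pres <- (as.matrix(pres) > 0) * 1L
  n <- nrow(pres)
  if (n < 2L) stop("need at least two samples")
  if (n_null < 99L) stop("'n_null' must be >= 99")
  if (!is.null(seed)) set.seed(seed)
  S <- ncol(pres)
  freq <- colSums(pres)
  rich <- rowSums(pres)
  empty <- rich == 0L
  obs_shared <- tcrossprod(pres)
  ge <- matrix(0L, n, n)
  null <- matrix(0L, n, S)
  for (b in seq_len(n_null)) {
    null[] <- 0L
    for (i in seq_len(n)) {
      if (rich[i] == 0L) next
      null[i, sample.int(S, rich[i], prob = freq)] <- 1L
    }
    ge <- ge + (tcrossprod(null) >= obs_shared)
  }
  rc <- ge / n_null
  diag(rc) <- 0
  rc[empty, ] <- NA_real_
  rc[, empty] <- NA_real_
  diag(rc) <- ifelse(empty, NA_real_, 0)
  dimnames(rc) <- list(rownames(pres), rownames(pres))
  structure(rc, class = c("raup_crick", "matrix"),
            n_null = n_null, seed = seed,
            undefined_samples = rownames(pres)[empty])
}

#' Mantel correlogram over metric distance classes
#'
#' Mantel correlation between a community dissimilarity matrix and the
#' membership matrix of each geographic distance class, permutation-tested,
#' with simultaneous Bonferroni correction over the tested classes. Classes
#' are contiguous bins of width `class_width` metres, and only classes whose
#' upper bound does not exceed half the maximum inter-sample distance are
#' tested (more distant classes are reported but flagged untested). Positive
#' `r` at a class means samples in that distance class are more similar than
#' average (positive spatial autocorrelation). Computation is delegated to
#' \code{vegan::mantel.correlog} with these settings.
#'
#' @param diss Square symmetric dissimilarity matrix (no `NA`s), e.g. from
#'   [raup_crick()].
#' @param coords Two-column matrix/data frame of metric coordinates (x, y) in
#'   the same sample order as `diss`.
#' @param class_width Width of each distance class in metres (default 1).
#' @param n_perm Permutations per class (default 1000).
#' @param alpha Significance level applied after Bonferroni correction.
#' @param seed Optional seed for the permutation test.
#' @return Object of class `mantel_correlogram`: data frame with per-class
#'   `d_lower`, `d_upper`, `d_mid`, `n_pairs`, `r`, `p`, `p_corrected`,
#'   `tested` and `significant`.
#' @export
mantel_correlogram <- function(diss, coords, class_width = 1, n_perm = 1000L,
                               alpha = 0.05, seed = NULL) {
  D <- as.matrix(diss)
  if (any(is.na(D))) stop("'diss' contains NA; drop undefined samples first")
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(D)) stop("'coords' must match 'diss' rows")
  dgeo <- stats::dist(coords)
  dmax <- max(dgeo)
  half <- dmax / 2
  breaks <- seq(0, ceiling(dmax / class_width) * class_width, by = class_width)
  if (length(breaks) < 3L) stop("grid too small for distance classes")
  if (!is.null(seed)) set.seed(seed)
  res <- vegan::mantel.correlog(D, D.geo = as.matrix(dgeo),
                                break.pts = breaks, cutoff = FALSE,
                                nperm = n_perm, mult = "none")
  tab <- as.data.frame(res$mantel.res)
  d_lower <- breaks[-length(breaks)]
  d_upper <- breaks[-1L]
  tested <- d_upper <= half & !is.na(tab[, "Pr(Mantel)"]) & tab[, "n.dist"] > 2
  # the permutation engine reports the tail matching the observed sign;
  # doubling it gives a two-sided p that is uniform under the null
  p <- ifelse(tested, pmin(1, 2 * tab[, "Pr(Mantel)"]), NA_real_)
  n_tested <- sum(tested)
  p_corr <- pmin(1, p * n_tested)
  out <- data.frame(class = seq_along(d_lower),
                    d_lower = d_lower, d_upper = d_upper,
                    d_mid = tab[, "class.index"],
                    n_pairs = tab[, "n.dist"] / 2,
                    r = tab[, "Mantel.cor"],
                    p = p, p_corrected = p_corr,
                    tested = tested,
                    significant = !is.na(p_corr) & p_corr < alpha)
  structure(out, class = c("mantel_correlogram", "data.frame"),
            n_perm = n_perm, alpha = alpha, n_tested = n_tested,
            max_distance = dmax)
}

#' @export
print.mantel_correlogram <- function(x, ...) {
  cat(sprintf("Mantel correlogram (%d permutations, %d tested classes, Bonferroni):\n",
              attr(x, "n_perm"), attr(x, "n_tested")))
  print.data.frame(round_df(x), row.names = FALSE)
  invisible(x)
}

round_df <- function(x) {
  x[] <- lapply(x, function(c) if (is.numeric(c)) round(c, 4) else c)
  x
}

#' Classify non-fagaceous samples by adjacency to fagaceous plants
#'
#' For every non-fagaceous root sample on the grid, counts neighbouring
#' positions (rook 4- or Moore 8-neighbourhood) that carry sequence data and
#' how many of those hold fagaceous plants. Samples with fewer than
#' `min_neighbors_with_data` data-bearing neighbours are excluded; the rest
#' are `fagaceous-adjacent` or `not-adjacent`.
#'
#' @param hosts Data frame of retained samples with `sample_id`, 0-based
#'   `row`/`col` and `host_family` (only positions with data are rows).
#' @param neighborhood `"rook4"` or `"moore8"`.
#' @param min_neighbors_with_data Minimum data-bearing neighbours (default 3).
#' @return Data frame for non-fagaceous samples: `sample_id`,
#'   `n_neighbors_with_data`, `n_fagaceous_neighbors` and `class` in
#'   `c("fagaceous-adjacent", "not-adjacent", "excluded")`.
#' @export
classify_adjacency <- function(hosts, neighborhood = c("rook4", "moore8"),
                               min_neighbors_with_data = 3L) {
  neighborhood <- match.arg(neighborhood)
  off <- neighbor_offsets(neighborhood)
  if (min_neighbors_with_data > nrow(off))
    stop("'min_neighbors_with_data' exceeds the neighbourhood size")
  key <- paste(hosts$row, hosts$col)
  if (anyDuplicated(key)) stop("duplicate grid positions in 'hosts'")
  fag <- stats::setNames(hosts$host_family == "Fagaceae", key)
  n_data <- integer(nrow(hosts)); n_fag <- integer(nrow(hosts))
  for (i in seq_len(nrow(off))) {
    nk <- paste(hosts$row + off[i, "dr"], hosts$col + off[i, "dc"])
    hit <- nk %in% key
    n_data <- n_data + hit
    n_fag <- n_fag + ifelse(hit, unname(fag[nk]), 0L)
  }
  nonfag <- hosts$host_family != "Fagaceae"
  cls <- ifelse(n_data < min_neighbors_with_data, "excluded",
                ifelse(n_fag > 0, "fagaceous-adjacent", "not-adjacent"))
  data.frame(sample_id = hosts$sample_id[nonfag],
             n_neighbors_with_data = n_data[nonfag],
             n_fagaceous_neighbors = n_fag[nonfag],
             class = cls[nonfag], stringsAsFactors = FALSE)
}

#' Fisher exact test of guild colonization vs fagaceous adjacency
#'
#' Builds the 2 x 2 table of (fagaceous-adjacent vs not-adjacent) x
#' (colonized by the guild vs not) over the non-excluded non-fagaceous
#' samples and applies a two-sided Fisher exact test. The odds ratio is
#' reported as the sample cross-product ratio, with the conditional MLE from
#' the exact test alongside.
#'
#' @param classification Output of [classify_adjacency()].
#' @param presence A `presence_matrix` containing the classified samples.
#' @param annotation OTU annotation with `otu_id` and `guild`.
#' @param guild Guild whose colonization is tested (default `"EcM"`).
#' @return Object of class `fisher_adjacency`: list with `table`,
#'   `odds_ratio` (cross-product), `odds_ratio_cmle`, `p`, `guild` and
#'   `degenerate` (TRUE when a margin is empty, in which case `p` is `NA`).
#' @export
fisher_adjacency_test <- function(classification, presence, annotation,
                                  guild = "EcM") {
  cl <- classification[classification$class != "excluded", , drop = FALSE]
  if (nrow(cl) == 0L) stop("no samples left after adjacency exclusion")
  pres <- unclass(presence)
  miss <- setdiff(cl$sample_id, rownames(pres))
  if (length(miss) > 0)
    stop(sprintf("classified sample(s) absent from presence matrix: %s",
                 paste(utils::head(miss, 5L), collapse = ", ")))
  g <- annotation$guild[match(colnames(pres), annotation$otu_id)]
  colon <- rowSums(pres[cl$sample_id, which(g == guild), drop = FALSE]) > 0
  adj <- cl$class == "fagaceous-adjacent"
  tab <- rbind(`fagaceous-adjacent` = c(sum(adj & colon), sum(adj & !colon)),
               `not-adjacent` = c(sum(!adj & colon), sum(!adj & !colon)))
  colnames(tab) <- c("colonized", "not-colonized")
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  if (degenerate) {
    p <- NA_real_; cmle <- NA_real_
  } else {
    ft <- stats::fisher.test(tab)
    p <- ft$p.value; cmle <- unname(ft$estimate)
  }
  structure(list(table = tab, odds_ratio = or, odds_ratio_cmle = cmle,
                 p = p, guild = guild, degenerate = degenerate),
            class = "fisher_adjacency")
}

#' @export
print.fisher_adjacency <- function(x, ...) {
  cat(sprintf("Fisher exact test: %s colonization vs fagaceous adjacency\n",
              x$guild))
  print(x$table)
  if (x$degenerate) {
    cat("  degenerate table: p undefined\n")
  } else {
    cat(sprintf("  odds ratio = %.3g (conditional MLE %.3g), two-sided p = %.3g\n",
                x$odds_ratio, x$odds_ratio_cmle, x$p))
  }
  invisible(x)
}
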