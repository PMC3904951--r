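#' Taxon or guild proportions of plant-fungal associations
#'
#' Sums association counts (`A`) by fungal taxon at the requested rank,
#' separately for fagaceous hosts, non-fagaceous hosts and all hosts, and
#' reports each taxon's share of the group's associations. OTUs without a
#' label at the rank are pooled into `"unidentified"`.
#'
#' @param pf A [build_plant_fungus_matrix()] result.
#' @param annotation Data frame with `otu_id` and columns `phylum`, `order`,
#'   `genus`, `guild`.
#' @param rank One of `"guild"`, `"phylum"`, `"order"`, `"genus"`.
#' @return Data frame with counts and proportions per taxon and host group,
#'   ordered by overall count.
#' @export
aggregate_proportions <- function(pf, annotation,
                                  rank = c("guild", "phylum", "order", "genus")) {
  rank <- match.arg(rank)
  stopifnot(inherits(pf, "plant_fungus_matrix"))
  otus <- colnames(pf$A_group)
  lab <- annotation[[rank]][match(otus, annotation$otu_id)]
  lab[is.na(lab) | lab == ""] <- "unidentified"
  agg <- function(x) tapply(x, lab, sum)
  cf <- agg(pf$A_group["fagaceous", ])
  cn <- agg(pf$A_group["non_fagaceous", ])
  ca <- cf + cn
  prop <- function(x) if (sum(x) > 0) x / sum(x) else x
  out <- data.frame(taxon = names(ca),
                    count_fagaceous = as.vector(cf),
                    count_non_fagaceous = as.vector(cn),
                    count_all = as.vector(ca),
                    prop_fagaceous = as.vector(prop(cf)),
                    prop_non_fagaceous = as.vector(prop(cn)),
                    prop_all = as.vector(prop(ca)),
                    stringsAsFactors = FALSE)
  out[order(-out$count_all), , drop = FALSE]
}

#' Log-likelihood-ratio (G) test of independence
#'
#' `G = 2 * sum(O * log(O / E))` over cells with positive observed counts,
#' with expectations from the independence margins and an upper-tail
#' chi-squared p-value on `(r - 1)(c - 1)` degrees of freedom. No Williams or
#' continuity correction is applied.
#'
#' @param observed An r x c matrix of non-negative counts with at least two
#'   rows and two columns and positive row/column sums.
#' @return Object of class `g_test` with elements `G`, `df`, `p`, `observed`
#'   and `expected`.
#' @examples
#' g_test(rbind(c(10, 0), c(0, 10)))  # G = 40 log 2
#' @export
g_test <- function(observed) {
  O <- as.matrix(observed)
  if (nrow(O) < 2L || ncol(O) < 2L)
    stop("degenerate table: need at least 2 rows and 2 columns")
  if (any(O < 0) || any(!is.finite(O))) stop("counts must be finite and >= 0")
  if (any(rowSums(O) <= 0) || any(colSums(O) <= 0))
    stop("all row and column sums must be positive")
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  G <- 2 * sum(O[O > 0] * log(O[O > 0] / E[O > 0]))
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  structure(list(G = G, df = df,
                 p = stats::pchisq(G, df, lower.tail = FALSE),
                 observed = O, expected = E),
            class = "g_test")
}

#' @export
print.g_test <- function(x, ...) {
  cat(sprintf("G-test of independence: G = %.4g, df = %d, p = %.4g\n",
              x$G, x$df, x$p))
  invisible(x)
}

# One-sided CLAM test statistic: is the focal group's coverage-corrected
# relative abundance significantly above u = K/(1-K) times the other
# group's? Zero counts are replaced by 1 (conservative), coverage correction
# applies only below the coverage limit.
clam_stat <- function(y_spec, y_other, m_spec, m_other, C_spec, C_other,
                      u, z, limit) {
  p1 <- ifelse(y_spec == 0, 1, y_spec) / m_spec
  p2 <- ifelse(y_other == 0, 1, y_other) / m_other
  c1 <- ifelse(y_spec < limit, C_spec, 1)
  c2 <- ifelse(y_other < limit, C_other, 1)
  v <- c1^2 * p1 * (1 - p1) / m_spec + u^2 * c2^2 * p2 * (1 - p2) / m_other
  c1 * p1 - u * c2 * p2 - z * sqrt(v)
}

# smallest integer count in 1:upper classifying a species as specialist when
# the other group's count is `other`; NA when even `upper` is not enough
clam_min_count <- function(other, m_spec, m_other, C_spec, C_other,
                           u, z, limit, upper) {
  if (upper < 1) return(NA_real_)
  y <- seq_len(upper)
  s <- clam_stat(y, rep(other, upper), m_spec, m_other, C_spec, C_other,
                 u, z, limit)
  hit <- which(s > 0)
  if (length(hit) == 0L) NA_real_ else hit[1L]
}

#' CLAM multinomial specialist/generalist classification
#'
#' Classifies each fungal OTU as a fagaceous-plant specialist, a
#' non-fagaceous-plant specialist, a generalist occurring on both host
#' groups, or too rare to classify, from its association counts in the two
#' host groups. An OTU is a specialist of a group when its coverage-corrected
#' relative abundance there exceeds `K / (1 - K)` times its relative
#' abundance in the other group by a one-sided normal test at level `alpha`
#' (supermajority threshold `K`, default 2/3). OTUs falling below the minimum
#' abundance boundary implied by `alpha` (the line joining the smallest
#' classifiable count in each group) are labelled too-rare.
#'
#' Sampling-effort correction: relative abundances are scaled by the group
#' totals, and counts below `coverage_limit` are additionally shrunk by the
#' group's estimated sample coverage (1 - singletons/total).
#'
#' @param counts Two-column matrix or data frame of per-OTU association
#'   counts `(fagaceous, non_fagaceous)`, or a [build_plant_fungus_matrix()]
#'   result (its group margins are used). Row names identify OTUs.
#' @param totals Group totals used to scale sampling effort; default the
#'   column sums of `counts`. Supply the full-community totals when
#'   classifying a subset of OTUs.
#' @param K Specialization (supermajority) threshold in (0.5, 1).
#' @param alpha Significance level of each one-sided test.
#' @param coverage_limit Counts below this receive the coverage correction.
#' @return Object of class `clam`: data frame with `otu_id`,
#'   `n_fagaceous`, `n_non_fagaceous`, `total` and `label` in
#'   `c("fagaceous-specialist", "non-fagaceous-specialist", "generalist",
#'   "too-rare")`; configuration and minimum-count boundary in attributes.
#' @examples
#' clam_classify(cbind(fagaceous = c(3, 20), non_fagaceous = c(110, 10)),
#'               totals = c(521, 2516))
#' @export
clam_classify <- function(counts, totals = NULL, K = 2 / 3, alpha = 0.005,
                          coverage_limit = 10L) {
  if (inherits(counts, "plant_fungus_matrix")) counts <- t(counts$A_group)
  counts <- as.matrix(counts)
  if (ncol(counts) != 2L) stop("'counts' must have exactly two columns")
  if (any(counts < 0)) stop("counts must be >= 0")
  if (K <= 0.5 || K >= 1) stop("'K' must be in (0.5, 1)")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  y1 <- counts[, 1L]; y2 <- counts[, 2L]
  if (is.null(totals)) totals <- c(sum(y1), sum(y2))
  m1 <- totals[1L]; m2 <- totals[2L]
  if (m1 <= 0 || m2 <= 0) stop("group totals must be > 0")
  u <- K / (1 - K)
  z <- stats::qnorm(alpha, lower.tail = FALSE)
  C1 <- 1 - sum(y1 == 1) / m1
  C2 <- 1 - sum(y2 == 1) / m2

  spec1 <- clam_stat(y1, y2, m1, m2, C1, C2, u, z, coverage_limit) > 0
  spec2 <- clam_stat(y2, y1, m2, m1, C2, C1, u, z, coverage_limit) > 0

  # minimum-abundance (too-rare) boundary: smallest classifiable count in
  # each group given a single occurrence in the other, joined linearly
  min1 <- clam_min_count(1, m1, m2, C1, C2, u, z, coverage_limit,
                         upper = max(y1, 1))
  min2 <- clam_min_count(1, m2, m1, C2, C1, u, z, coverage_limit,
                         upper = max(y2, 1))
  if (is.na(min1)) min1 <- 1
  if (is.na(min2)) min2 <- 1
  rare <- y1 < min1 & y2 < min2
  if (min1 > 1 && min2 > 1) {
    # boundary line from (y1, y2) = (min1, 1) to (1, min2)
    b1 <- stats::approx(c(min1, 1), c(1, min2), xout = seq_len(min1))$y
    b2 <- stats::approx(c(min2, 1), c(1, min1), xout = seq_len(min2))$y
    in1 <- y1 >= 1 & y1 <= min1
    rare[in1] <- y2[in1] < b1[y1[in1]]
    in2 <- y2 >= 1 & y2 <= min2
    rare[in2] <- y1[in2] < b2[y2[in2]]
  }

  label <- rep("generalist", length(y1))
  label[spec1] <- "fagaceous-specialist"
  label[spec2] <- "non-fagaceous-specialist"
  label[rare] <- "too-rare"
  ids <- rownames(counts)
  if (is.null(ids)) ids <- sprintf("OTU%04d", seq_along(y1))
  out <- data.frame(otu_id = ids, n_fagaceous = y1, n_non_fagaceous = y2,
                    total = y1 + y2,
                    label = factor(label,
                                   levels = c("fagaceous-specialist",
                                              "non-fagaceous-specialist",
                                              "generalist", "too-rare")),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("clam", "data.frame"),
            config = list(K = K, alpha = alpha,
                          coverage_limit = coverage_limit,
                          totals = c(fagaceous = m1, non_fagaceous = m2),
                          coverage = c(fagaceous = C1, non_fagaceous = C2),
                          min_counts = c(fagaceous = min1, non_fagaceous = min2)))
}

#' @export
print.clam <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("CLAM classification of %d OTUs (K = %.3f, alpha = %g):\n",
              nrow(x), cfg$K, cfg$alpha))
  print(table(x$label))
  invisible(x)
}

#' Number of fungal OTUs shared between plant species
#'
#' Counts, for every pair of plant species, the OTUs with at least one
#' association in both species, optionally restricted to a single guild.
#'
#' @param pf A [build_plant_fungus_matrix()] result.
#' @param annotation OTU annotation with `otu_id` and `guild` (required when
#'   `guild` is given).
#' @param guild Optional guild filter (e.g. `"EcM"` or `"AM"`).
#' @return Data frame edge list `species_a`, `species_b`, `guild`, `shared`
#'   (one row per unordered pair), with the full symmetric matrix in
#'   attribute `matrix`.
#' @export
shared_otu_counts <- function(pf, annotation = NULL, guild = NULL) {
  stopifnot(inherits(pf, "plant_fungus_matrix"))
  if (nrow(pf$A) < 2L) stop("need at least two plant species")
  B <- pf$A > 0
  if (!is.null(guild)) {
    if (is.null(annotation)) stop("'annotation' needed for a guild filter")
    keep <- annotation$otu_id[annotation$guild == guild]
    B <- B[, colnames(B) %in% keep, drop = FALSE]
  }
  M <- B %*% t(B)
  sp <- rownames(M)
  pairs <- which(upper.tri(M), arr.ind = TRUE)
  out <- data.frame(species_a = sp[pairs[, 1L]], species_b = sp[pairs[, 2L]],
                    guild = if (is.null(guild)) "all" else guild,
                    shared = M[pairs], stringsAsFactors = FALSE)
  attr(out, "matrix") <- M
  out
}

#' Per-root co-existence of fungal functional groups
#'
#' Flags, per root sample, the presence of ectomycorrhizal fungi, arbuscular
#' mycorrhizal fungi and fungi of unknown function, and tabulates the
#' distribution of the eight flag combinations for fagaceous hosts,
#' non-fagaceous hosts and all hosts.
#'
#' @param presence A `presence_matrix` (samples x OTUs).
#' @param annotation OTU annotation with `otu_id` and `guild`.
#' @param hosts Host metadata with `sample_id` and `host_family`.
#' @return Object of class `coexistence_profile`: list with `samples` (per
#'   sample flags) and `proportions` (8 combinations x 3 host groups; each
#'   column sums to 1).
#' @export
coexistence_profile <- function(presence, annotation, hosts) {
  pres <- unclass(presence)
  g <- annotation$guild[match(colnames(pres), annotation$otu_id)]
  has <- function(gl) rowSums(pres[, which(g == gl), drop = FALSE]) > 0
  flags <- data.frame(sample_id = rownames(pres),
                      has_EcM = has("EcM"), has_AM = has("AM"),
                      has_unknown = has("unknown"),
                      stringsAsFactors = FALSE)
  h <- hosts[match(flags$sample_id, hosts$sample_id), ]
  flags$host_group <- ifelse(h$host_family == "Fagaceae",
                             "fagaceous", "non_fagaceous")
  combos <- c("none", "EcM", "AM", "unknown", "EcM+AM", "EcM+unknown",
              "AM+unknown", "EcM+AM+unknown")
  lab <- apply(flags[, c("has_EcM", "has_AM", "has_unknown")], 1L, function(f) {
    x <- c("EcM", "AM", "unknown")[as.logical(f)]
    if (length(x) == 0L) "none" else paste(x, collapse = "+")
  })
  flags$combination <- factor(lab, levels = combos)
  prop_of <- function(idx) {
    if (sum(idx) == 0L) return(rep(NA_real_, length(combos)))
    as.vector(table(flags$combination[idx]) / sum(idx))
  }
  props <- cbind(fagaceous = prop_of(flags$host_group == "fagaceous"),
                 non_fagaceous = prop_of(flags$host_group == "non_fagaceous"),
                 all = prop_of(rep(TRUE, nrow(flags))))
  rownames(props) <- combos
  structure(list(samples = flags, proportions = props),
            class = "coexistence_profile")
}

#' @export
print.coexistence_profile <- function(x, ...) {
  cat("Co-existence of fungal functional groups (proportion of root samples):\n")
  print(round(x$proportions, 3))
  invisible(x)
}
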