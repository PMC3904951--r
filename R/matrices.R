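#' Sample-level presence/absence by relative-abundance cutoff
#'
#' An OTU is scored present in a sample iff its read count is strictly
#' greater than `frac` of the sample's total reads (default 5%), which
#' suppresses low-frequency contaminant reads without equalizing depth.
#'
#' @param counts Integer matrix of read counts (samples x OTUs) or a
#'   `myco_community` / `otu_table`, from which the count matrix is taken.
#' @param frac Relative-abundance threshold; presence requires
#'   `count > frac * sample_total` (strict inequality).
#' @return Binary matrix of the same shape, class `presence_matrix`, with
#'   attribute `provenance = "cutoff<frac>"`. Samples with zero reads give an
#'   all-absent row with a warning.
#' @examples
#' m <- rbind(s1 = c(a = 5, b = 95), s2 = c(a = 6, b = 94))
#' presence_by_cutoff(m)  # 5/100 absent, 6/100 present
#' @export
presence_by_cutoff <- function(counts, frac = 0.05) {
  counts <- as_count_matrix(counts)
  if (frac < 0 || frac >= 1) stop("'frac' must be in [0, 1)")
  tot <- rowSums(counts)
  if (any(tot == 0))
    warning(sprintf("%d sample(s) with zero reads: scored all-absent",
                    sum(tot == 0)))
  pres <- (counts > frac * tot) * 1L
  pres[tot == 0, ] <- 0L
  structure(pres, class = c("presence_matrix", class(pres)),
            provenance = sprintf("cutoff%g", frac))
}

#' Sample-level presence/absence by rarefaction
#'
#' Samples with fewer than `depth` reads are dropped; the rest are randomly
#' subsampled without replacement to exactly `depth` reads, and presence is
#' any non-zero count after subsampling.
#'
#' @param counts As in [presence_by_cutoff()].
#' @param depth Rarefaction depth (reads per sample, default 50; must be > 0).
#' @param seed Optional seed, recorded in the provenance attribute.
#' @return Binary `presence_matrix` with attribute
#'   `provenance = "rarefied(depth, seed)"`; dropped samples are recorded in
#'   attribute `dropped_samples`.
#' @export
presence_by_rarefaction <- function(counts, depth = 50L, seed = NULL) {
  counts <- as_count_matrix(counts)
  if (!is.finite(depth) || depth <= 0) stop("'depth' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  keep <- rowSums(counts) >= depth
  sub <- counts[keep, , drop = FALSE]
  # rrarefy's "smallest count is > 1" heuristic warning is spurious here:
  # inputs are validated integer read counts and shallow rows are pre-dropped
  rar <- suppressWarnings(vegan::rrarefy(sub, depth))
  pres <- (rar > 0) * 1L
  dimnames(pres) <- dimnames(sub)
  structure(pres, class = c("presence_matrix", class(pres)),
            provenance = sprintf("rarefied(%d, %s)", depth,
                                 if (is.null(seed)) "NA" else seed),
            dropped_samples = rownames(counts)[!keep])
}

as_count_matrix <- function(x) {
  if (inherits(x, "myco_community")) x <- x$counts
  if (inherits(x, "otu_table")) x <- x$counts
  m <- as.matrix(x)
  if (any(m < 0)) stop("counts must be >= 0")
  m
}

#' Plant-species x fungal-OTU association matrix
#'
#' Builds the association matrix `A` whose cell `A[i, j]` is the number of
#' root samples of plant species `i` in which OTU `j` is present, together
#' with the proportions `P = A / sum(A)`, and the fagaceous /
#' non-fagaceous group margins `A_group` and `P_group` (group proportions are
#' normalized within each host group). Fagaceous membership is decided by
#' `host_family == "Fagaceae"`.
#'
#' @param presence A `presence_matrix` (samples x OTUs).
#' @param hosts Data frame with `sample_id`, `host_species`, `host_family`
#'   covering every sample in `presence`.
#' @return Object of class `plant_fungus_matrix`: list with `A`, `P`,
#'   `A_group` (2 x OTUs, rows `fagaceous` / `non_fagaceous`), `P_group`,
#'   `n_samples_per_species` and `total_associations`.
#' @export
build_plant_fungus_matrix <- function(presence, hosts) {
  stopifnot(is.matrix(presence) || inherits(presence, "presence_matrix"))
  missing <- setdiff(rownames(presence), hosts$sample_id)
  if (length(missing) > 0)
    stop(sprintf("no host label for sample(s): %s",
                 paste(utils::head(missing, 5L), collapse = ", ")))
  h <- hosts[match(rownames(presence), hosts$sample_id), ]
  pres <- unclass(presence)
  A <- rowsum(pres, group = h$host_species)
  total <- sum(A)
  grp <- ifelse(h$host_family == "Fagaceae", "fagaceous", "non_fagaceous")
  A_group <- rbind(
    fagaceous = colSums(pres[grp == "fagaceous", , drop = FALSE]),
    non_fagaceous = colSums(pres[grp == "non_fagaceous", , drop = FALSE]))
  gt <- rowSums(A_group)
  structure(list(A = A,
                 P = if (total > 0) A / total else A,
                 A_group = A_group,
                 P_group = sweep(A_group, 1L, ifelse(gt > 0, gt, 1), `/`),
                 n_samples_per_species = table(h$host_species),
                 n_samples_per_group = table(factor(grp, levels = c("fagaceous", "non_fagaceous"))),
                 total_associations = total),
            class = "plant_fungus_matrix")
}

#' @export
print.plant_fungus_matrix <- function(x, ...) {
  cat(sprintf("Plant x fungus association matrix: %d species x %d OTUs\n",
              nrow(x$A), ncol(x$A)))
  cat(sprintf("  associations: %d total (%d fagaceous + %d non-fagaceous)\n",
              x$total_associations, sum(x$A_group["fagaceous", ]),
              sum(x$A_group["non_fagaceous", ])))
  invisible(x)
}
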