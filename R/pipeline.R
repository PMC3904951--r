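#' Pipeline configuration
#'
#' Bundles the per-stage settings of [run_pipeline()] into one serializable
#' object (see [write_pipeline_config()]). A single global `seed` drives
#' every stochastic stage: stage seeds are derived deterministically from it,
#' so re-running any stage on unchanged inputs is bit-for-bit reproducible.
#'
#' @param grid [grid_spec()] or plain list of its fields.
#' @param params [community_params()] or plain list.
#' @param cluster [cluster_config()] or plain list.
#' @param presence List: `method` (`"cutoff"` or `"rarefaction"`), `frac`
#'   (cutoff fraction), `depth` (rarefaction depth).
#' @param spatial List: `n_null` (Raup-Crick randomizations), `class_width`
#'   and `n_perm` (Mantel correlogram), `neighborhood`,
#'   `min_neighbors_with_data` (adjacency), `max_samples` (cap on the number
#'   of samples entering the Raup-Crick/Mantel step; `Inf` to disable).
#' @param input List of input paths (`counts`, `metadata`, `annotation`,
#'   `reads`) used for stages whose inputs are not simulated.
#' @param seed Global seed (integer).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(grid = grid_spec(), params = community_params(),
                            cluster = cluster_config(),
                            presence = list(),
                            spatial = list(),
                            input = list(),
                            seed = 1L) {
  if (!inherits(grid, "grid_spec")) grid <- do.call(grid_spec, grid)
  if (!inherits(params, "community_params")) {
    if (!is.null(params$base_occupancy))
      params$base_occupancy <- unlist(params$base_occupancy)
    params <- do.call(community_params, params)
  }
  if (!inherits(cluster, "cluster_config")) cluster <- do.call(cluster_config, cluster)
  presence <- utils::modifyList(list(method = "cutoff", frac = 0.05, depth = 50L),
                                as.list(presence))
  spatial <- utils::modifyList(list(n_null = 999L, class_width = 1,
                                    n_perm = 1000L, neighborhood = "rook4",
                                    min_neighbors_with_data = 3L,
                                    max_samples = 200L),
                               as.list(spatial))
  structure(list(grid = grid, params = params, cluster = cluster,
                 presence = presence, spatial = spatial,
                 input = as.list(input), seed = as.integer(seed)),
            class = "pipeline_config")
}

read_input_table <- function(path, what) {
  if (is.null(path)) stop(sprintf("no %s available: stage needs either the simulate stage or an input path", what))
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path))
  path
}

#' Run the analysis pipeline end-to-end (or any prefix)
#'
#' Stage order is `simulate` -> `cluster` -> `matrix` -> `guilds` ->
#' `spatial`. The simulate stage generates a synthetic community; without it,
#' counts/metadata/annotation (and reads, for the cluster stage) are loaded
#' from the paths in `config$input`. The cluster stage rebuilds the count
#' matrix from reads via [two_stage_otu_pipeline()]. When `out_dir` is given,
#' every stage writes its outputs as TSV/JSON files carrying a provenance
#' comment (package version + seed).
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector of stages to run (a prefix of the order
#'   above; later stages require the earlier ones' products).
#' @param out_dir Optional output directory (created if needed).
#' @return A result bundle (list, class `myco_pipeline`) with the products of
#'   each executed stage.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "matrix", "guilds", "spatial"),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  order_all <- c("simulate", "cluster", "matrix", "guilds", "spatial")
  stages <- match.arg(stages, order_all, several.ok = TRUE)
  stages <- order_all[order_all %in% stages]
  seed <- config$seed
  prov <- provenance_block(seed)
  res <- list(config = config)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(writer, obj, file, ...) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, file), ...)
  }

  counts <- NULL; meta <- NULL; ann <- NULL; reads <- NULL

  if ("simulate" %in% stages) {
    com <- simulate_community(config$grid, config$params, seed = seed)
    res$community <- com
    counts <- com$counts; meta <- com$meta; ann <- com$annotation
    emit(write_tsv_table, meta, "sample_metadata.tsv", provenance = prov)
    emit(write_tsv_matrix, counts, "otu_counts.tsv", id_col = "sample_id",
         provenance = prov)
    emit(write_tsv_table, ann, "otu_annotation.tsv", provenance = prov)
    if (!is.null(out_dir)) {
      jsonlite::write_json(
        list(provenance = prov,
             guild = as.list(com$truth$guild),
             depth = com$truth$depth,
             n_adj_fagaceous = com$truth$n_adj_fagaceous),
        file.path(out_dir, "truth.json"), auto_unbox = TRUE)
    }
  } else {
    if (any(c("matrix", "guilds", "spatial") %in% stages)) {
      meta <- read_tsv_table(read_input_table(config$input$metadata, "metadata"))
      if (!"cluster" %in% stages) {
        counts <- read_tsv_matrix(read_input_table(config$input$counts, "counts"))
      }
    }
  }

  if ("cluster" %in% stages) {
    if (is.null(reads)) {
      reads <- read_tsv_table(read_input_table(config$input$reads, "reads"))
    }
    otab <- two_stage_otu_pipeline(reads, config$cluster)
    res$otu_table <- otab
    counts <- otab$counts
    emit(write_tsv_matrix, counts, "otu_counts.tsv", id_col = "sample_id",
         provenance = prov)
    if (!is.null(out_dir))
      write_fasta(otab$consensus, file.path(out_dir, "otu_consensus.fasta"))
  }

  if (any(c("matrix", "guilds", "spatial") %in% stages)) {
    pres <- if (config$presence$method == "rarefaction") {
      presence_by_rarefaction(counts, depth = config$presence$depth,
                              seed = seed + 1L)
    } else {
      presence_by_cutoff(counts, frac = config$presence$frac)
    }
    keep <- rowSums(pres) > 0
    pres_nz <- pres[keep, , drop = FALSE]
    pf <- build_plant_fungus_matrix(pres, meta)
    res$presence <- pres; res$plant_fungus <- pf
    emit(write_tsv_matrix, unclass(pres), "presence_matrix.tsv",
         id_col = "sample_id", provenance = prov)
    emit(write_tsv_matrix, pf$A, "plant_fungus_matrix.tsv",
         id_col = "species", provenance = prov)
  }

  if (any(c("guilds", "spatial") %in% stages) && is.null(ann)) {
    ann <- read_tsv_table(read_input_table(config$input$annotation, "annotation"))
  }

  if ("guilds" %in% stages) {
    props <- lapply(stats::setNames(nm = c("guild", "phylum", "order", "genus")),
                    function(r) aggregate_proportions(pf, ann, r))
    gt <- lapply(props, function(p) {
      O <- rbind(fagaceous = p$count_fagaceous,
                 non_fagaceous = p$count_non_fagaceous)
      colnames(O) <- p$taxon
      O <- O[, colSums(O) > 0, drop = FALSE]
      if (ncol(O) < 2L || any(rowSums(O) == 0)) NULL else g_test(O)
    })
    clam <- clam_classify(pf)
    shared <- rbind(shared_otu_counts(pf, ann, "EcM"),
                    shared_otu_counts(pf, ann, "AM"))
    coex <- coexistence_profile(pres, ann, meta)
    res$proportions <- props; res$g_tests <- gt; res$clam <- clam
    res$shared <- shared; res$coexistence <- coex
    emit(write_tsv_table, props$guild, "proportions_guild.tsv", provenance = prov)
    emit(write_tsv_table, as.data.frame(clam), "clam_classification.tsv",
         provenance = prov)
    emit(write_tsv_table, shared, "shared_otus.tsv", provenance = prov)
    if (!is.null(out_dir)) {
      jsonlite::write_json(
        list(provenance = prov,
             g_tests = lapply(gt, function(g) if (is.null(g)) NULL else
               list(G = g$G, df = g$df, p = g$p))),
        file.path(out_dir, "g_tests.json"), auto_unbox = TRUE, digits = NA)
    }
  }

  if ("spatial" %in% stages) {
    sp <- config$spatial
    sub <- pres_nz
    if (nrow(sub) > sp$max_samples) {
      set.seed(seed + 2L)
      sub <- sub[sort(sample.int(nrow(sub), sp$max_samples)), , drop = FALSE]
    }
    msub <- meta[match(rownames(sub), meta$sample_id), ]
    grid_sp <- if (!is.null(attr(meta, "grid"))) attr(meta, "grid")$spacing else 1
    rc <- raup_crick(sub, n_null = sp$n_null, seed = seed + 3L)
    coords <- cbind(msub$row, msub$col) * grid_sp
    corr <- mantel_correlogram(rc, coords, class_width = sp$class_width,
                               n_perm = sp$n_perm, seed = seed + 4L)
    adj <- classify_adjacency(meta, neighborhood = sp$neighborhood,
                              min_neighbors_with_data = sp$min_neighbors_with_data)
    fish <- lapply(stats::setNames(nm = c("EcM", "AM")), function(g)
      fisher_adjacency_test(adj, pres, ann, g))
    res$raup_crick <- rc; res$correlogram <- corr
    res$adjacency <- adj; res$fisher <- fish
    emit(write_tsv_matrix, unclass(rc), "raup_crick.tsv", id_col = "sample_id",
         provenance = prov)
    emit(write_tsv_table, as.data.frame(corr), "mantel_correlogram.tsv",
         provenance = prov)
    emit(write_tsv_table, adj, "adjacency_classes.tsv", provenance = prov)
    if (!is.null(out_dir)) {
      jsonlite::write_json(
        list(provenance = prov,
             fisher = lapply(fish, function(f)
               list(guild = f$guild, odds_ratio = f$odds_ratio,
                    odds_ratio_cmle = f$odds_ratio_cmle, p = f$p,
                    table = as.data.frame(f$table), degenerate = f$degenerate))),
        file.path(out_dir, "fisher_adjacency.json"), auto_unbox = TRUE,
        digits = NA)
    }
  }

  structure(res, class = "myco_pipeline")
}

#' @export
print.myco_pipeline <- function(x, ...) {
  cat("mycoroot pipeline results; components:",
      paste(setdiff(names(x), "config"), collapse = ", "), "\n")
  invisible(x)
}
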