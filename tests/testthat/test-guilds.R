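toy_pf <- function() {
  pres <- rbind(s1 = c(o1 = 1L, o2 = 0L, o3 = 0L),
                s2 = c(o1 = 0L, o2 = 1L, o3 = 1L))
  hosts <- data.frame(sample_id = c("s1", "s2"),
                      host_species = c("fag_sp", "laur_sp"),
                      host_family = c("Fagaceae", "Lauraceae"))
  build_plant_fungus_matrix(pres, hosts)
}

toy_ann <- data.frame(otu_id = c("o1", "o2", "o3"),
                      phylum = c("Basidiomycota", "Glomeromycota", NA),
                      order = c("Russulales", "Glomerales", NA),
                      genus = c("Russula", NA, NA),
                      guild = c("EcM", "AM", "unknown"))

test_that("proportion aggregation pools by rank with an unidentified bucket", {
  pf <- toy_pf()
  ap <- aggregate_proportions(pf, toy_ann, "guild")
  expect_equal(ap$prop_fagaceous[ap$taxon == "EcM"], 1)
  expect_equal(ap$prop_non_fagaceous[ap$taxon == "EcM"], 0)
  expect_equal(sum(ap$prop_all), 1)
  ag <- aggregate_proportions(pf, toy_ann, "genus")
  expect_true("unidentified" %in% ag$taxon)
  expect_equal(ag$count_all[ag$taxon == "unidentified"], 2)
  expect_error(aggregate_proportions(pf, toy_ann, "species"))
})

test_that("guild proportions equal a brute-force grouping on synthetic data", {
  com <- small_community(seed = 12)
  pres <- suppressWarnings(presence_by_cutoff(com))
  pf <- build_plant_fungus_matrix(pres, com$meta)
  ap <- aggregate_proportions(pf, com$annotation, "guild")
  fag <- com$meta$host_family[match(rownames(pres), com$meta$sample_id)] == "Fagaceae"
  g <- com$annotation$guild[match(colnames(pres), com$annotation$otu_id)]
  for (gl in c("EcM", "AM", "unknown")) {
    want <- sum(pres[fag, g == gl])
    expect_equal(ap$count_fagaceous[ap$taxon == gl], want)
  }
})

test_that("G statistic follows its closed form", {
  expect_equal(g_test(rbind(c(10, 10), c(10, 10)))$G, 0)
  gt <- g_test(rbind(c(10, 0), c(0, 10)))
  expect_equal(gt$G, 40 * log(2), tolerance = 1e-12)
  expect_equal(gt$df, 1L)
  gt2 <- g_test(rbind(c(5, 10, 15), c(20, 10, 5)))
  expect_equal(gt2$df, 2L)
  expect_equal(gt2$p, pchisq(gt2$G, 2, lower.tail = FALSE))
  expect_error(g_test(matrix(1:3, 1)), "degenerate")
  expect_error(g_test(rbind(c(0, 0), c(1, 2))), "positive")
})

test_that("CLAM reproduces worked-example classifications", {
  counts <- cbind(fagaceous = c(3L, 20L, 13L, 0L),
                  non_fagaceous = c(110L, 10L, 25L, 0L))
  rownames(counts) <- c("OTU49", "OTU801", "OTU1159", "OTUempty")
  cl <- clam_classify(counts, totals = c(521, 2516))
  expect_equal(as.character(cl$label),
               c("non-fagaceous-specialist", "fagaceous-specialist",
                 "generalist", "too-rare"))
  expect_error(clam_classify(counts, K = 0.4), "K")
})

test_that("CLAM agrees with the vegan reference implementation", {
  for (seed in 1:5) {
    set.seed(seed)
    S <- 60
    y1 <- rnbinom(S, mu = 8, size = 0.5)
    y2 <- rnbinom(S, mu = 12, size = 0.5)
    ok <- (y1 + y2) > 0
    y1 <- y1[ok]; y2 <- y2[ok]
    comm <- rbind(fagaceous = y1, non_fagaceous = y2)
    colnames(comm) <- paste0("sp", seq_along(y1))
    ref <- vegan::clamtest(comm, alpha = 0.005, coverage.limit = 10,
                           specialization = 2 / 3)
    map <- c(Generalist = "generalist",
             Specialist_fagaceous = "fagaceous-specialist",
             Specialist_non_fagaceous = "non-fagaceous-specialist",
             Too_rare = "too-rare")
    got <- clam_classify(cbind(y1, y2), alpha = 0.005)
    expect_equal(as.character(got$label),
                 unname(map[as.character(ref$Classes)]))
  }
})

test_that("CLAM is symmetric under group exchange and monotone in alpha", {
  set.seed(4)
  y1 <- rnbinom(40, mu = 10, size = 0.7)
  y2 <- rnbinom(40, mu = 10, size = 0.7)
  a <- clam_classify(cbind(y1, y2))
  b <- clam_classify(cbind(y2, y1))
  swap <- c(`fagaceous-specialist` = "non-fagaceous-specialist",
            `non-fagaceous-specialist` = "fagaceous-specialist",
            generalist = "generalist", `too-rare` = "too-rare")
  expect_equal(as.character(b$label), unname(swap[as.character(a$label)]))

  lo <- clam_classify(cbind(y1, y2), alpha = 0.005)
  hi <- clam_classify(cbind(y1, y2), alpha = 0.05)
  spec <- grepl("specialist", as.character(lo$label))
  expect_true(all(grepl("specialist", as.character(hi$label)[spec])))
})

test_that("CLAM recovers designed specialists on synthetic communities", {
  # designed contrast: 20x occupancy odds either way, low baselines so the
  # contrast is not compressed by occupancy saturation or within-sample
  # read competition
  for (seed in c(31, 32)) {
    com <- simulate_community(
      grid_spec(30, 40),
      community_params(n_ecm_otus = 80L, n_am_otus = 40L,
                       n_unknown_otus = 150L,
                       base_occupancy = c(EcM = 0.006, AM = 0.003,
                                          unknown = 0.01),
                       abundance_sdlog = 0.5,
                       pref_ecm_on_fagaceous = 20,
                       pref_am_on_nonfagaceous = 20,
                       spillover_strength = 0, contaminant_rate = 0,
                       seed = seed))
    pres <- suppressWarnings(presence_by_cutoff(com))
    pf <- build_plant_fungus_matrix(pres, com$meta)
    cl <- clam_classify(pf, alpha = 0.05)
    g <- com$truth$guild[match(cl$otu_id, names(com$truth$guild))]
    adequate <- cl$total >= 25 & g %in% c("EcM", "AM")
    want <- ifelse(g[adequate] == "EcM",
                   "fagaceous-specialist", "non-fagaceous-specialist")
    expect_gte(mean(cl$label[adequate] == want), 0.9)
  }
})

test_that("shared-OTU counts match set intersections", {
  pf <- toy_pf()
  sh <- shared_otu_counts(pf)
  expect_equal(sh$shared, 0)

  com <- small_community(seed = 17)
  pres <- suppressWarnings(presence_by_cutoff(com))
  pf2 <- build_plant_fungus_matrix(pres, com$meta)
  sh2 <- shared_otu_counts(pf2, com$annotation, "EcM")
  ecm_ids <- com$annotation$otu_id[com$annotation$guild == "EcM"]
  for (r in sample(nrow(sh2), 10)) {
    a <- sh2$species_a[r]; b <- sh2$species_b[r]
    want <- length(intersect(
      intersect(colnames(pf2$A)[pf2$A[a, ] > 0], ecm_ids),
      colnames(pf2$A)[pf2$A[b, ] > 0]))
    expect_equal(sh2$shared[r], want)
  }
  M <- attr(sh2, "matrix")
  expect_true(isSymmetric(unname(M)))
  # identical OTU sets of size k share k OTUs
  pres3 <- rbind(s1 = c(o1 = 1L, o2 = 1L, o3 = 0L),
                 s2 = c(o1 = 1L, o2 = 1L, o3 = 0L))
  hosts3 <- data.frame(sample_id = c("s1", "s2"),
                       host_species = c("x", "y"),
                       host_family = c("Lauraceae", "Theaceae"))
  sh3 <- shared_otu_counts(build_plant_fungus_matrix(pres3, hosts3))
  expect_equal(sh3$shared, 2)
})

test_that("co-existence profiles count guild combinations per host group", {
  pres <- rbind(s1 = c(o1 = 1L, o2 = 1L, o3 = 0L),
                s2 = c(o1 = 1L, o2 = 0L, o3 = 0L),
                s3 = c(o1 = 1L, o2 = 0L, o3 = 0L))
  hosts <- data.frame(sample_id = c("s1", "s2", "s3"),
                      host_species = c("a", "b", "c"),
                      host_family = c("Lauraceae", "Fagaceae", "Fagaceae"))
  co <- coexistence_profile(pres, toy_ann, hosts)
  expect_equal(co$proportions["EcM+AM", "non_fagaceous"], 1)
  expect_equal(co$proportions["EcM", "fagaceous"], 1)   # all-EcM-only group
  expect_equal(colSums(co$proportions), c(fagaceous = 1, non_fagaceous = 1, all = 1))

  com <- small_community(seed = 19)
  pres2 <- suppressWarnings(presence_by_cutoff(com))
  co2 <- coexistence_profile(pres2, com$annotation, com$meta)
  # detected flags almost never contradict the generating truth
  g <- com$truth$guild
  for (gl in c("EcM", "AM", "unknown")) {
    true_flag <- rowSums(com$truth$occupancy[, g == gl, drop = FALSE] |
                           com$truth$contaminant_counts[, g == gl, drop = FALSE] > 0) > 0
    det <- co2$samples[[paste0("has_", gl)]]
    expect_lt(mean(det & !true_flag), 0.02)
  }
})
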