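# Independent reference implementations used as oracles. These deliberately
# re-derive each quantity with a different algorithm/data structure than the
# package code paths they check.

# Needleman-Wunsch DP in plain R: match = 1, mismatch = 0, each gap column
# -0.5; returns matches / alignment columns from a diagonal-preferring
# traceback.
dp_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -0.5 * (0:n); S[1, ] <- -0.5 * (0:m)
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(S[i, j] + (x[i] == y[j]),
                           S[i, j + 1] - 0.5,
                           S[i + 1, j] - 0.5)
  }
  i <- n; j <- m; matches <- 0L; cols <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        abs(S[i + 1, j + 1] - (S[i, j] + (x[i] == y[j]))) < 1e-9) {
      matches <- matches + (x[i] == y[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && abs(S[i + 1, j + 1] - (S[i, j + 1] - 0.5)) < 1e-9) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    cols <- cols + 1L
  }
  matches / cols
}

# Naive complete-linkage agglomeration: explicit cluster sets, inter-cluster
# distance recomputed from scratch each round as the max over member pairs,
# merge while the global minimum is within the radius, ties broken by the
# smallest head index. Returns the partition as a list of index sets.
naive_complete_linkage <- function(D, radius) {
  cl <- lapply(seq_len(nrow(D)), identity)
  eps <- 1e-9
  repeat {
    if (length(cl) < 2) break
    best <- NULL; bestd <- Inf
    for (i in seq_len(length(cl) - 1)) for (j in (i + 1):length(cl)) {
      d <- max(D[cl[[i]], cl[[j]]])
      if (d < bestd - eps) { bestd <- d; best <- c(i, j) }
    }
    if (bestd > radius + eps) break
    cl[[best[1]]] <- sort(c(cl[[best[1]]], cl[[best[2]]]))
    cl <- cl[-best[2]]
  }
  cl
}

# canonical form of a partition for comparison
partition_key <- function(groups) {
  s <- lapply(groups, sort)
  paste(sort(vapply(s, paste, "", collapse = ",")), collapse = ";")
}

# Exact Raup-Crick dissimilarity for one sample pair by exhaustive
# enumeration: all subsets of the requested richness, subset probabilities
# under successive frequency-weighted draws without replacement.
exact_raup_crick_pair <- function(pres, i, j) {
  freq <- colSums(pres)
  Svec <- seq_len(ncol(pres))
  subset_prob <- function(idx, w) {
    recur <- function(remaining, W) {
      if (length(remaining) == 0) return(1)
      s <- 0
      for (k in seq_along(remaining)) {
        s <- s + w[remaining[k]] / W * recur(remaining[-k], W - w[remaining[k]])
      }
      s
    }
    recur(idx, sum(w))
  }
  enum <- function(r) {
    subs <- utils::combn(Svec, r, simplify = FALSE)
    probs <- vapply(subs, subset_prob, 0, w = freq)
    list(subs = subs, probs = probs)
  }
  ri <- sum(pres[i, ]); rj <- sum(pres[j, ])
  obs <- sum(pres[i, ] & pres[j, ])
  ei <- enum(ri); ej <- enum(rj)
  p <- 0
  for (a in seq_along(ei$subs)) for (b in seq_along(ej$subs)) {
    if (length(intersect(ei$subs[[a]], ej$subs[[b]])) >= obs)
      p <- p + ei$probs[a] * ej$probs[b]
  }
  p
}

# Two-sided Fisher exact p by exhaustive hypergeometric tail summation.
fisher_enum_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  pobs <- dhyper(a, m, n, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# quick small synthetic community for downstream tests; the OTU pool is
# scaled down ~8x from the defaults, so baseline occupancy is scaled up by
# the same factor to keep per-sample richness realistic
small_params <- function(seed = 1, ...) {
  community_params(n_ecm_otus = 20L, n_am_otus = 10L, n_unknown_otus = 40L,
                   base_occupancy = c(EcM = 0.023, AM = 0.0025,
                                      unknown = 0.037),
                   seed = seed, ...)
}

small_community <- function(seed = 1, nr = 10, nc = 10, ...) {
  simulate_community(grid_spec(nr, nc), small_params(seed = seed, ...))
}
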