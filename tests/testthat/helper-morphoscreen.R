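# Shared fixtures and independent oracles for the test suite.
# Fixtures are generated in code; nothing is read from disk.

# A fast desk-scale screen configuration for unit tests (moderate
# dispersion so most guides have cells, few plates).
small_config <- function(seed, ...) {
  args <- list(...)
  defaults <- list(
    n_genes = 40, n_nontargeting = 24, n_plates = 2,
    cells_per_guide_mean = 30, cells_per_guide_dispersion = 2,
    effect_size = 1, seed = seed
  )
  defaults[names(args)] <- args
  do.call(screen_config, defaults)
}

quiet_screen <- function(cfg) suppressWarnings(generate_screen(cfg))

# Independent dynamic-programming Levenshtein oracle (full table).
lev_dp <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (x[i] == y[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L, d[i, j] + cost)
    }
  }
  d[n + 1, m + 1]
}

# Independent average-precision oracle: explicit sort then a plain loop over
# ranks accumulating precision at every sibling position.
ap_oracle <- function(query, siblings, controls) {
  cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sims <- c(apply(siblings, 1, cosv, a = query), apply(controls, 1, cosv, a = query))
  lab <- c(rep(TRUE, nrow(siblings)), rep(FALSE, nrow(controls)))
  ord <- order(-sims, method = "radix")
  lab <- lab[ord]
  tp <- 0; ap <- 0
  for (k in seq_along(lab)) {
    if (lab[k]) {
      tp <- tp + 1
      ap <- ap + tp / k
    }
  }
  ap / nrow(siblings)
}

# Exact Mann-Whitney two-sided p by full enumeration of all rank
# assignments (n1 + n2 choose n1 arrangements), no ties assumed.
mw_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  us <- apply(sets, 2, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  mid <- n1 * n2 / 2
  p <- if (u_obs > mid) 2 * mean(us >= u_obs) else 2 * mean(us <= u_obs)
  min(p, 1)
}

# One-sided hypergeometric enrichment p by direct tail summation.
fisher_tail_oracle <- function(a, hits_n, set_n, universe_n) {
  kmax <- min(hits_n, set_n)
  k <- a:kmax
  sum(choose(set_n, k) * choose(universe_n - set_n, hits_n - k)) /
    choose(universe_n, hits_n)
}

# Pipeline shorthand: cells -> hit table (plus intermediates).
run_pipeline <- function(scr, alpha = 0.001, fdr = 0.01) {
  pr <- build_profiles(scr$cells)
  sc <- score_screen(pr$guide)
  nulls <- intersect(scr$truth$gene[scr$truth$tpm == 0],
                     sc$gene[!is.na(sc$profile_score)])
  ht <- suppressWarnings(call_hits(sc, nulls, fdr = fdr))
  list(profiles = pr, scores = sc, hits = ht, nulls = nulls)
}
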