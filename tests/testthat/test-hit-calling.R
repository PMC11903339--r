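test_that("score_gene counts significant features and sums -log10 p", {
  p <- c(a = 0.0005, b = 0.5, c = 0.0009)
  sc <- score_gene(p, alpha = 0.001)
  expect_equal(sc$profile_score, 2)
  expect_equal(sc$signal_score, -log10(0.0005) - log10(0.0009), tolerance = 1e-9)
  expect_equal(sc$signal_score, 6.346787, tolerance = 1e-6)
  null <- score_gene(c(a = 1, b = 1), alpha = 0.001)
  expect_equal(null$profile_score, 0)
  expect_equal(null$signal_score, 0)
  expect_error(score_gene(p, alpha = 1.5), "0, 1")
  expect_error(score_gene(c(a = 0)), "0, 1")
})

test_that("profile score is non-increasing in alpha", {
  set.seed(61)
  p <- setNames(runif(200)^3, paste0("f", 1:200))
  alphas <- c(0.05, 0.01, 0.005, 0.001, 1e-4)
  scores <- vapply(alphas, function(a) score_gene(p, alpha = a)$profile_score, numeric(1))
  expect_true(all(diff(scores) <= 0))
})

test_that("per-channel scores use each channel's compartment subset", {
  meta <- parse_feature_names(c(
    "Cells_Intensity_MeanIntensity_Mito", "Cells_Texture_Contrast_Mito",
    "Cells_Intensity_MeanIntensity_DNA", "Cells_AreaShape_Area"
  ))
  p <- c(Cells_Intensity_MeanIntensity_Mito = 1e-5,
         Cells_Texture_Contrast_Mito = 1e-4,
         Cells_Intensity_MeanIntensity_DNA = 0.9,
         Cells_AreaShape_Area = 1e-6)
  sc <- score_gene(p, feature_meta = meta)
  expect_equal(sc$score_Mito, 2)
  expect_equal(sc$score_DNA, 0)
  expect_equal(sc$profile_score, 3) # area-shape feature counts whole-cell only
})

test_that("empirical threshold is the stated order statistic", {
  expect_equal(empirical_threshold(1:100, fdr = 0.01), 99)
  expect_equal(sum(1:100 > empirical_threshold(1:100, fdr = 0.01)), 1)
  expect_equal(empirical_threshold(1:100, fdr = 0.05), 95)
  expect_equal(empirical_threshold(rep(0, 150), fdr = 0.01), 0)
  expect_error(empirical_threshold(numeric(0)), "empty")
  expect_warning(empirical_threshold(1:20, fdr = 0.01), "coarse")
})

test_that("null-set flagging never exceeds the FDR, at any grid level", {
  set.seed(62)
  for (i in 1:20) {
    m <- sample(100:700, 1)
    null_scores <- sample(0:40, m, replace = TRUE)
    for (f in seq(0.01, 0.05, by = 0.01)) {
      thr <- empirical_threshold(null_scores, f)
      expect_lte(mean(null_scores > thr), f)
    }
  }
})

test_that("call_hits flags strictly-above scores and supports compartments", {
  nulls <- paste0("N", 1:100)
  scores <- tibble::tibble(
    gene = c(nulls, "GA", "GB"),
    profile_score = c(1:100, 150, 60),
    score_Mito = c(rep(0:4, 20), 1, 40),
    score_DNA = c(rep(0:4, 20), 1, 0)
  )
  ht <- call_hits(scores, nulls, fdr = 0.01)
  expect_true(ht$whole_cell_hit[ht$gene == "GA"])
  # GB: below the whole-cell threshold (99) but a Mito compartment hit
  expect_false(ht$whole_cell_hit[ht$gene == "GB"])
  expect_true(ht$hit_Mito[ht$gene == "GB"])
  expect_true(ht$compartment_hit[ht$gene == "GB"])
  # null contract
  expect_lte(mean(ht$whole_cell_hit[ht$is_null]), 0.01)
  expect_error(call_hits(scores, c(nulls, "MISSING")), "no score")
})

test_that("hit lists grow as the FDR is relaxed", {
  set.seed(63)
  nulls <- paste0("N", 1:300)
  scores <- tibble::tibble(
    gene = c(nulls, paste0("G", 1:100)),
    profile_score = c(rpois(300, 3), rpois(100, 10))
  )
  grid <- hit_counts_by_fdr(scores, nulls)
  expect_true(all(diff(grid$n_whole_cell) >= 0))      # larger lists at looser FDR
  expect_true(all(diff(grid$threshold) <= 0))
  expect_true(all(grid$null_flagged_frac <= grid$fdr))
})

test_that("channel fractions renormalize per gene and average", {
  meta <- parse_feature_names(c(
    "Cells_Intensity_MeanIntensity_DNA", "Cells_Intensity_MeanIntensity_ER",
    "Cells_Intensity_MeanIntensity_Actin", "Cells_Intensity_MeanIntensity_Mito",
    "Cells_Intensity_MeanIntensity_WGA", "Cells_Texture_Contrast_Mito"
  ))
  scores <- tibble::tibble(
    gene = c("GA", "GB"),
    score_DNA = c(0, 0), score_ER = c(0, 0), score_Actin = c(0, 0),
    score_Mito = c(2, 0), score_WGA = c(0, 1)
  )
  cf <- channel_fractions(scores, feature_meta = meta, genes = "GA")
  expect_equal(cf$fraction[cf$channel == "Mito"], 1)
  expect_equal(sum(cf$fraction), 1, tolerance = 1e-9)
  both <- channel_fractions(scores, feature_meta = meta)
  expect_equal(sum(both$fraction), 1, tolerance = 1e-9)
  scores$score_WGA[2] <- 0
  expect_warning(channel_fractions(scores, feature_meta = meta), "excluded")
})

test_that("a compartment-planted gene group concentrates signal there", {
  cfg <- small_config(seed = 64, n_genes = 100, n_nontargeting = 40,
                      cells_per_guide_mean = 60, frac_hit_genes = 0.25,
                      effect_size = 1.5)
  scr <- quiet_screen(cfg)
  res <- run_pipeline(scr)
  mito_genes <- scr$truth$gene[!is.na(scr$truth$primary_channel) &
                                 scr$truth$primary_channel == "Mito"]
  expect_gte(length(mito_genes), 2)
  cf <- suppressWarnings(channel_fractions(res$scores, genes = mito_genes))
  expect_equal(cf$channel[which.max(cf$fraction)], "Mito") # plurality, not totality
  expect_lt(max(cf$fraction), 1)
})

test_that("large planted effects are recalled and nulls controlled", {
  cfg <- small_config(seed = 65, n_genes = 80, n_nontargeting = 40,
                      cells_per_guide_mean = 80, effect_size = 2)
  scr <- quiet_screen(cfg)
  res <- run_pipeline(scr)
  hits <- scr$truth$gene[scr$truth$is_hit]
  called <- res$hits$whole_cell_hit | res$hits$compartment_hit
  expect_equal(mean(called[res$hits$gene %in% hits], na.rm = TRUE), 1)
  expect_lte(mean(res$hits$whole_cell_hit[res$hits$is_null]), 0.01)
})

test_that("score_screen reports NA for genes with too few guide profiles", {
  cfg <- small_config(seed = 66, n_genes = 30, cells_per_guide_mean = 3,
                      cells_per_guide_dispersion = 0.2)
  scr <- quiet_screen(cfg)
  res_profiles <- build_profiles(scr$cells)
  sc <- score_screen(res_profiles$guide)
  expect_true(anyNA(sc$profile_score))
  expect_true(all(sc$n_units[is.na(sc$profile_score)] < 2))
})
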