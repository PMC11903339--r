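test_that("top-N-plus lists extend through boundary ties", {
  pv <- tibble::tibble(gene = paste0("G", 1:25), p = (1:25) / 100)
  expect_equal(nrow(top_gene_list(pv, 20)), 20) # distinct p-values: exactly 20

  pv2 <- tibble::tibble(gene = paste0("G", 1:25),
                        p = c((1:17) / 100, rep(0.18, 5), (23:25) / 100))
  top2 <- top_gene_list(pv2, 20)
  expect_equal(nrow(top2), 22) # ranks 18-22 tied at the cut

  pv3 <- tibble::tibble(gene = paste0("G", 1:30), p = rep(0.5, 30))
  expect_equal(nrow(top_gene_list(pv3, 20)), 30) # total tie returns everything

  pv4 <- tibble::tibble(gene = paste0("G", 1:10), p = (1:10) / 10)
  expect_warning(all10 <- top_gene_list(pv4, 20), "returning all")
  expect_equal(nrow(all10), 10)
})

test_that("Fisher enrichment p matches exact hypergeometric tails", {
  # worked 2x2 table [[3,1],[1,5]]: one-sided p = 25/210
  universe <- paste0("G", 1:10)
  hits <- universe[1:4]
  sets <- list(s = universe[c(1:3, 5)])
  enr <- set_enrichment(hits, sets, universe)
  expect_equal(enr$n_hit_in, 3)
  expect_equal(enr$p, 25 / 210, tolerance = 1e-12)
  expect_equal(enr$p, fisher_tail_oracle(3, 4, 4, 10), tolerance = 1e-12)

  # random tables against the exhaustive tail oracle
  set.seed(91)
  for (i in 1:25) {
    nu <- sample(10:50, 1)
    universe <- paste0("G", seq_len(nu))
    hits <- sample(universe, sample(2:(nu - 1), 1))
    s <- sample(universe, sample(2:(nu - 1), 1))
    enr <- set_enrichment(hits, list(s = s), universe)
    expect_equal(enr$p,
                 fisher_tail_oracle(enr$n_hit_in, length(hits), length(s), nu),
                 tolerance = 1e-10)
  }
})

test_that("BH and Bonferroni corrections behave as the step procedures", {
  universe <- paste0("G", 1:40)
  hits <- universe[1:10]
  sets <- list(a = universe[1:8], b = universe[c(1:5, 21:25)], c = universe[31:40])
  enr <- set_enrichment(hits, sets, universe)
  expect_true(all(enr$p_bh >= enr$p - 1e-15))
  expect_true(all(enr$p_bonferroni >= enr$p_bh - 1e-15))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3)) # step-up by hand
  # degenerate: set = hits = universe cannot be enriched
  d <- set_enrichment(universe, list(all = universe), universe)
  expect_equal(d$p, 1)
  expect_error(set_enrichment(hits, sets, character(0)), "empty universe")
})

test_that("single-feature screens recover a planted perturber set", {
  cfg <- small_config(seed = 92, n_genes = 80, n_nontargeting = 40,
                      cells_per_guide_mean = 60, effect_size = 2,
                      frac_hit_genes = 0.2, spectrum_shift_module = FALSE)
  scr <- quiet_screen(cfg)
  ann <- generate_annotations(scr)
  pr <- build_profiles(scr$cells)
  # pick a feature strongly loaded by the first planted module
  mod_genes <- ann$complexes[[1]]
  load <- colMeans(abs(scr$effects[mod_genes, , drop = FALSE]))
  feat <- names(sort(load[names(load) %in% names(pr$guide)], decreasing = TRUE))[1]
  fs <- suppressWarnings(feature_screen(pr$guide, feat, ann$gene_sets, rank_cut = 10))
  expect_gte(nrow(fs$top), 10)
  expect_true(any(mod_genes %in% fs$top$gene))
  planted_set <- paste0("set_", sub("^complex_", "", names(ann$complexes)[1]))
  expect_equal(fs$enrichment$set[1], planted_set) # planted set ranks first
  expect_lt(fs$enrichment$p_bonferroni[1], 0.05)
})

test_that("granularity spectra show the planted acidification signature", {
  cfg <- small_config(seed = 93, n_genes = 80, n_nontargeting = 40,
                      cells_per_guide_mean = 60, effect_size = 1.5,
                      frac_hit_genes = 0.2)
  scr <- quiet_screen(cfg)
  pr <- build_profiles(scr$cells)
  shift_genes <- scr$truth$gene[scr$truth$spectrum_shift]
  expect_gte(length(shift_genes), 2)
  sp <- granularity_spectrum(pr$gene_all, channel = "WGA", object = "Cells",
                             gene_group = shift_genes)
  mt <- sp[sp$gene == ".mean", ]
  expect_lt(mt$value[mt$size == 1], 0)        # signal lost at the finest size
  expect_true(all(mt$value[mt$size >= 2] > 0)) # compensatory gain at larger sizes

  # null genes trace ~ 0 at every size
  null_genes <- head(scr$truth$gene[!scr$truth$is_hit & scr$truth$tpm > 0], 15)
  sp0 <- granularity_spectrum(pr$gene_all, gene_group = null_genes)
  m0 <- sp0[sp0$gene == ".mean", ]
  expect_true(all(abs(m0$value) < 0.5)) # in per-plate s.d. units

  expect_error(granularity_spectrum(pr$gene, channel = "WGA", object = "Nuclei",
                                    gene_group = shift_genes), "no granularity")
})

test_that("per-feature gene p-values come from the rank-test machinery", {
  scr <- quiet_screen(small_config(seed = 94, n_genes = 15, n_nontargeting = 10,
                                   cells_per_guide_mean = 40))
  pr <- build_profiles(scr$cells)
  feat <- setdiff(names(pr$guide), grep("^Metadata", names(pr$guide), value = TRUE))[1]
  pv <- feature_gene_pvalues(pr$guide, feat)
  g <- pv$gene[!is.na(pv$p)][1]
  ref <- feature_pvalues(
    pr$guide[pr$guide$Metadata_gene == g, c("Metadata_guide", feat)],
    pr$guide[!pr$guide$Metadata_targeting, c("Metadata_guide", feat)]
  )
  expect_equal(pv$p[pv$gene == g], ref$p, tolerance = 1e-12)
  expect_error(feature_gene_pvalues(pr$guide, "not_a_feature"), "unknown feature")
})
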