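# gene-level profile table built directly from planted effect vectors plus
# small noise: fast stand-in for the full pipeline in benchmark tests
profiles_from_effects <- function(scr, genes, noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  m <- scr$effects[genes, , drop = FALSE] +
    matrix(rnorm(length(genes) * ncol(scr$effects), sd = noise_sd), length(genes))
  as_profile_table(
    dplyr::bind_cols(tibble::tibble(Metadata_gene = genes), tibble::as_tibble(m)),
    level = "gene", normalized = TRUE, feature_selected = TRUE
  )
}

test_that("complex retention uses an exact fraction comparison", {
  prof <- as_profile_table(tibble::tibble(
    Metadata_gene = c("A", "B", "C"),
    f1 = c(1, 2, 0.5), f2 = c(0, 1, 2), f3 = c(2, 0, 1)
  ), level = "gene")
  cx <- list(
    two_of_six = c("A", "B", "x1", "x2", "x3", "x4"), # 2/6 passes 1/3 exactly
    one_of_four = c("C", "y1", "y2", "y3"),           # 1/4 fails
    single_hit = c("A", "z1", "z2")                   # 1/3 retained, no pairs
  )
  cc <- complex_correlations(prof, cx, min_frac = 1 / 3)
  expect_setequal(cc$retained, c("two_of_six", "single_hit"))
  expect_equal(nrow(cc$within), 1) # only the A-B pair
  expect_equal(nrow(cc$background), 3)
  # every within pair is also a background pair
  key <- function(d) paste(pmin(d$gene_a, d$gene_b), pmax(d$gene_a, d$gene_b))
  expect_true(all(key(cc$within) %in% key(cc$background)))
})

test_that("planted complexes correlate above background", {
  cfg <- small_config(seed = 81, n_genes = 120, frac_hit_genes = 0.3,
                      cells_per_guide_mean = 5, spectrum_shift_module = FALSE)
  scr <- quiet_screen(cfg)
  ann <- generate_annotations(scr)
  hits <- scr$truth$gene[scr$truth$is_hit]
  prof <- profiles_from_effects(scr, hits, noise_sd = 0.3, seed = 81)
  cc <- complex_correlations(prof, ann$complexes)
  expect_gt(median(cc$within$r), median(cc$background$r))
  p <- wilcox.test(cc$within$r, cc$background$r, alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("correlation bins are equal width, right-closed, and partition", {
  set.seed(82)
  genes <- paste0("G", 1:12)
  m <- matrix(rnorm(12 * 20), 12)
  prof <- as_profile_table(
    dplyr::bind_cols(tibble::tibble(Metadata_gene = genes),
                     tibble::as_tibble(`colnames<-`(m, paste0("f", 1:20)))),
    level = "gene"
  )
  cmb <- utils::combn(genes, 2)
  ps <- tibble::tibble(gene_a = cmb[1, ], gene_b = cmb[2, ],
                       score = sample(0:999, ncol(cmb), replace = TRUE))
  binned <- binned_pair_scores(prof, ps, n_bins = 8)
  expect_equal(nrow(binned), ncol(cmb)) # partitions all scored pairs
  expect_true(all(binned$bin_hi - binned$bin_lo - 0.25 < 1e-12))
  expect_true(all(binned$r > binned$bin_lo - 1e-12 & binned$r <= binned$bin_hi + 1e-12))
  # boundary rule: r = 1 (self-duplicate pair) goes to the last bin
  prof2 <- prof
  dup <- prof2[prof2$Metadata_gene == "G1", ]
  dup$Metadata_gene <- "G13"
  prof2 <- as_profile_table(dplyr::bind_rows(tibble::as_tibble(prof2),
                                             tibble::as_tibble(dup)), "gene")
  b2 <- binned_pair_scores(prof2, tibble::tibble(gene_a = "G1", gene_b = "G13", score = 999))
  expect_equal(b2$bin, 8L)
})

test_that("link scores rise with profile correlation for coherent effects", {
  set.seed(83)
  d <- rnorm(30); d <- d / sqrt(sum(d^2))
  genes <- paste0("G", 1:15)
  w <- seq(0, 1, length.out = 15) # how much each gene loads on the shared axis
  m <- t(sapply(w, function(wi) wi * d * 5 + rnorm(30, sd = sqrt(1 - wi^2 / 2))))
  colnames(m) <- paste0("f", 1:30)
  prof <- as_profile_table(
    dplyr::bind_cols(tibble::tibble(Metadata_gene = genes), tibble::as_tibble(m)),
    level = "gene"
  )
  cm <- correlation_matrix(prof)
  cmb <- utils::combn(genes, 2)
  r_truth <- cm[cbind(cmb[1, ], cmb[2, ])]
  ps <- tibble::tibble(gene_a = cmb[1, ], gene_b = cmb[2, ],
                       score = as.integer(round(999 * (r_truth + 1) / 2)))
  binned <- binned_pair_scores(prof, ps)
  med <- tapply(binned$score, binned$bin, median)
  expect_true(all(diff(med[order(as.integer(names(med)))]) >= 0))
})

test_that("essentiality splits strictly below the threshold", {
  sig <- tibble::tibble(gene = c("A", "B", "C", "D"), signal_score = c(10, 5, 2, 8))
  dep <- tibble::tibble(gene = c("A", "B", "C", "E"),
                        dependency = c(-0.7, -0.3, -0.5, -2))
  sp <- essentiality_split(sig, dep)
  expect_setequal(sp$gene, c("A", "B", "C")) # intersection only
  expect_true(sp$essential[sp$gene == "A"])   # -0.7 < -0.5
  expect_false(sp$essential[sp$gene == "B"])  # -0.3
  expect_false(sp$essential[sp$gene == "C"])  # boundary -0.5 is nonessential
})

test_that("similarity ranking is cosine-ordered with the query excluded", {
  prof <- as_profile_table(tibble::tibble(
    Metadata_gene = c("Q", "DUP", "ORTH", "NEG"),
    f1 = c(1, 1, 0, -1), f2 = c(0, 0, 1, 0)
  ), level = "gene")
  rk <- rank_by_similarity(prof, "Q")
  expect_false("Q" %in% rk$gene)
  expect_equal(rk$gene[1], "DUP")
  expect_equal(rk$cosine[1], 1, tolerance = 1e-12)
  expect_equal(rk$cosine[rk$gene == "ORTH"], 0, tolerance = 1e-12)
  expect_equal(rk$gene[nrow(rk)], "NEG")
  expect_equal(rk$cosine[rk$gene == "NEG"], -1, tolerance = 1e-12)
  expect_error(rank_by_similarity(prof, "NOPE"), "unknown query")
  path <- withr::local_tempfile(fileext = ".rnk")
  write_rnk(rk, path)
  lines <- readLines(path)
  expect_equal(length(lines), 3)
  expect_match(lines[1], "^DUP\t1")
})
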