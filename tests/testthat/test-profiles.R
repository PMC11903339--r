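make_cells <- function(df) tibble::as_tibble(df)

test_that("median aggregation is robust, exact for single cells, order-invariant", {
  cells <- make_cells(data.frame(
    Metadata_plate = "P01",
    Metadata_guide = rep(c("g1", "g2"), c(3, 1)),
    Metadata_gene = rep(c("GA", "GB"), c(3, 1)),
    Metadata_targeting = TRUE,
    Cells_AreaShape_Area = c(1, 3, 100, 7),
    Nuclei_AreaShape_Area = c(2, 2, 2, 5)
  ))
  pg <- aggregate_profiles(cells, "plate_guide")
  expect_equal(pg$Cells_AreaShape_Area[pg$Metadata_guide == "g1"], 3) # outlier-robust
  expect_equal(pg$Cells_AreaShape_Area[pg$Metadata_guide == "g2"], 7) # identity
  shuffled <- cells[sample(nrow(cells)), ]
  expect_equal(as.data.frame(aggregate_profiles(shuffled, "plate_guide")),
               as.data.frame(pg))
  expect_error(aggregate_profiles(cells[, -1], "plate_guide"), "Metadata_plate")
})

test_that("aggregation levels are monotone along the pipeline", {
  cells <- make_cells(data.frame(
    Metadata_plate = rep(c("P01", "P02"), each = 4),
    Metadata_guide = rep(c("g1", "g2"), 4),
    Metadata_gene = rep(c("GA", "GA"), 4),
    Metadata_targeting = TRUE,
    f1 = 1:8
  ))
  names(cells)[5] <- "Cells_AreaShape_Area"
  pg <- aggregate_profiles(cells, "plate_guide")
  g <- aggregate_profiles(pg, "guide")
  gn <- aggregate_profiles(g, "gene")
  expect_equal(nrow(pg), 4)
  expect_equal(nrow(g), 2)
  expect_equal(nrow(gn), 1)
  expect_error(aggregate_profiles(g, "plate_guide"), "cannot aggregate")
  expect_error(aggregate_profiles(gn, "gene"), "cannot aggregate")
})

test_that("per-plate standardization centers and scales exactly", {
  pg <- as_profile_table(tibble::tibble(
    Metadata_plate = rep(c("P01", "P02"), each = 3),
    Metadata_guide = rep(c("g1", "g2", "g3"), 2),
    Cells_AreaShape_Area = c(0, 2, 4, 100, 102, 104),
    Cells_AreaShape_Perimeter = c(5, 5, 5, 1, 2, 3)
  ), level = "plate_guide")
  nz <- normalize_profiles(pg)
  v <- nz$Cells_AreaShape_Area
  expect_equal(v[1:3], c(-1.224745, 0, 1.224745), tolerance = 1e-6) # population s.d.
  expect_equal(v[4:6], c(-1.224745, 0, 1.224745), tolerance = 1e-6) # per-plate centering
  # constant on one plate only: flagged and missing there, kept elsewhere
  expect_true(all(is.na(nz$Cells_AreaShape_Perimeter[1:3])))
  expect_false(anyNA(nz$Cells_AreaShape_Perimeter[4:6]))
  expect_true("Cells_AreaShape_Perimeter" %in% attr(nz, "flagged_features"))
})

test_that("normalization refuses single-profile plates and wrong levels", {
  one <- as_profile_table(tibble::tibble(
    Metadata_plate = "P01", Metadata_guide = "g1", Cells_AreaShape_Area = 1
  ), level = "plate_guide")
  expect_error(normalize_profiles(one), "cannot scale")
  guide_level <- as_profile_table(tibble::tibble(
    Metadata_guide = c("g1", "g2"), Cells_AreaShape_Area = 1:2
  ), level = "guide")
  expect_error(normalize_profiles(guide_level), "plate_guide")
})

test_that("normalization contract holds across a generated screen", {
  scr <- quiet_screen(small_config(seed = 41, n_genes = 20, n_nontargeting = 10))
  nz <- normalize_profiles(aggregate_profiles(scr$cells, "plate_guide"))
  m <- as.matrix(nz[, setdiff(names(nz), grep("^Metadata", names(nz), value = TRUE))])
  for (pl in unique(nz$Metadata_plate)) {
    sub <- m[nz$Metadata_plate == pl, ]
    ok <- colSums(is.na(sub)) == 0
    expect_true(all(abs(colMeans(sub[, ok])) < 1e-9))
    sd_pop <- sqrt(colMeans(sweep(sub[, ok], 2, colMeans(sub[, ok]))^2))
    expect_true(all(abs(sd_pop - 1) < 1e-9))
  }
})

test_that("feature selection enforces the correlation bound and is idempotent", {
  set.seed(42)
  n <- 120
  z <- rnorm(n)
  tbl <- tibble::tibble(
    Metadata_guide = paste0("g", 1:n),
    Cells_AreaShape_Area = z + rnorm(n, sd = 0.1),        # r ~ 0.99 with next
    Cells_AreaShape_Perimeter = z + rnorm(n, sd = 0.1),
    Cells_AreaShape_Eccentricity = rnorm(n),              # independent
    Cells_AreaShape_FormFactor = rnorm(n)
  )
  x <- as_profile_table(tbl, level = "guide", normalized = TRUE)
  sel <- select_features(x)
  feats <- setdiff(names(sel), "Metadata_guide")
  expect_equal(length(feats), 3) # exactly one of the correlated pair survives
  expect_true(all(c("Cells_AreaShape_Eccentricity", "Cells_AreaShape_FormFactor") %in% feats))
  again <- select_features(sel)
  expect_equal(names(again), names(sel))
})

test_that("retained features verified against exhaustive recomputation", {
  set.seed(43)
  n <- 100; blocks <- 12; per <- 5
  z <- matrix(rnorm(n * blocks), n)
  m <- do.call(cbind, lapply(seq_len(blocks), function(b) {
    sapply(seq_len(per), function(i) sqrt(0.95) * z[, b] + sqrt(0.05) * rnorm(n))
  }))
  colnames(m) <- sprintf("Cells_Intensity_MeanIntensity%02d_DNA", seq_len(ncol(m)))
  x <- as_profile_table(
    dplyr::bind_cols(tibble::tibble(Metadata_guide = paste0("g", 1:n)),
                     tibble::as_tibble(m)),
    level = "guide", normalized = TRUE
  )
  sel <- select_features(x, corr_threshold = 0.9)
  kept <- as.matrix(sel[, setdiff(names(sel), "Metadata_guide")])
  cm <- abs(cor(kept)); diag(cm) <- 0
  expect_lte(max(cm), 0.9)
  expect_lt(ncol(kept), ncol(m)) # redundancy actually removed
})

test_that("missing and constant features are dropped", {
  tbl <- tibble::tibble(
    Metadata_guide = paste0("g", 1:10),
    Cells_AreaShape_Area = c(NA, rnorm(9)),
    Cells_AreaShape_Perimeter = rep(2, 10),
    Cells_AreaShape_FormFactor = rnorm(10)
  )
  sel <- select_features(as_profile_table(tbl, "guide", normalized = TRUE))
  expect_equal(setdiff(names(sel), "Metadata_guide"), "Cells_AreaShape_FormFactor")
  d <- attr(sel, "dropped_features")
  expect_equal(d$missing, "Cells_AreaShape_Area")
  expect_equal(d$low_variance, "Cells_AreaShape_Perimeter")
})

test_that("PCA keeps the fewest components reaching the variance target", {
  # rank-1 data: one component carries everything
  set.seed(44)
  u <- rnorm(30); v <- rnorm(6)
  m1 <- outer(u, v)
  colnames(m1) <- paste0("PCin", 1:6)
  tbl1 <- dplyr::bind_cols(tibble::tibble(Metadata_gene = paste0("G", 1:30)),
                           tibble::as_tibble(m1))
  x1 <- as_profile_table(tbl1, "gene", normalized = TRUE, feature_selected = TRUE)
  r1 <- reduce_pca(x1)
  expect_equal(setdiff(names(r1), "Metadata_gene"), "PC1")
  expect_equal(sum(attr(r1, "explained_variance")), 1, tolerance = 1e-9)

  # isotropic 10-dim noise: equal eigenvalues force ceil(0.9 * 10) = 9
  m <- matrix(rnorm(4000 * 10), 4000)
  colnames(m) <- paste0("f", 1:10)
  tbl2 <- dplyr::bind_cols(tibble::tibble(Metadata_gene = paste0("G", 1:4000)),
                           tibble::as_tibble(m))
  x2 <- as_profile_table(tbl2, "gene", normalized = TRUE, feature_selected = TRUE)
  r2 <- reduce_pca(x2, var_fraction = 0.90)
  expect_equal(length(attr(r2, "explained_variance")), 9)

  # contract on arbitrary input
  expect_gte(sum(attr(r2, "explained_variance")), 0.90)
  expect_error(reduce_pca(x2, var_fraction = 1.5), "0, 1")
})

test_that("the composed pipeline is deterministic", {
  scr <- quiet_screen(small_config(seed = 45, n_genes = 12, n_nontargeting = 8))
  p1 <- build_profiles(scr$cells)
  p2 <- build_profiles(scr$cells)
  expect_equal(as.data.frame(p1$gene), as.data.frame(p2$gene))
  st <- profile_state(p1$gene)
  expect_equal(st$level, "gene")
  expect_true(st$normalized && st$feature_selected)
})
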