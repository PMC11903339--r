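#' Profile tables
#'
#' A profile table is a tibble with `Metadata_` columns describing each
#' profile unit (plate x guide, guide, or gene) and one numeric column per
#' morphological feature, plus processing-state attributes tracking the
#' aggregation level and whether the table has been normalized,
#' feature-selected and PCA-reduced. [as_profile_table()] wraps an existing
#' data frame for use with the pipeline verbs.
#'
#' @param x data frame with `Metadata_` columns and numeric feature columns.
#' @param level aggregation level of the rows.
#' @param normalized,feature_selected,pca_reduced processing-state flags.
#' @return a `profile_tbl`.
#' @export
as_profile_table <- function(x, level = c("plate_guide", "guide", "gene"),
                             normalized = FALSE, feature_selected = FALSE,
                             pca_reduced = FALSE) {
  level <- match.arg(level)
  x <- as_tibble(x)
  key <- switch(level,
                plate_guide = c("Metadata_plate", "Metadata_guide"),
                guide = "Metadata_guide",
                gene = "Metadata_gene")
  missing_key <- setdiff(key, names(x))
  if (length(missing_key)) {
    abort(sprintf("missing grouping column(s) for level '%s': %s",
                  level, paste(missing_key, collapse = ", ")))
  }
  if (anyDuplicated(x[, key])) abort("duplicate profile units for this level")
  new_profile_tbl(x, level = level, normalized = normalized,
                  feature_selected = feature_selected, pca_reduced = pca_reduced)
}

new_profile_tbl <- function(x, level, normalized = FALSE,
                            feature_selected = FALSE, pca_reduced = FALSE,
                            extra = list()) {
  x <- as_tibble(x)
  attr(x, "ms_state") <- list(level = level, normalized = normalized,
                              feature_selected = feature_selected,
                              pca_reduced = pca_reduced)
  for (nm in names(extra)) attr(x, nm) <- extra[[nm]]
  class(x) <- unique(c("profile_tbl", class(x)))
  x
}

#' @rdname as_profile_table
#' @export
profile_state <- function(x) {
  st <- attr(x, "ms_state")
  if (is.null(st)) abort("not a profile table (no processing state); see as_profile_table()")
  st
}

#' @export
print.profile_tbl <- function(x, ...) {
  st <- attr(x, "ms_state")
  cat(sprintf("<profile_tbl> level = %s | normalized: %s, feature-selected: %s, PCA: %s\n",
              st$level, st$normalized, st$feature_selected, st$pca_reduced))
  NextMethod()
}

#' Aggregate single-cell or profile tables by median
#'
#' Median-aggregates per-feature values within each profile unit. Single
#' cells aggregate to per-plate guide profiles (`"plate_guide"`), per-plate
#' guide profiles to per-screen guide profiles (`"guide"`), and guide
#' profiles to gene profiles (`"gene"`). Groups with no rows are absent
#' from the result.
#'
#' @param x a single-cell tibble (with `Metadata_plate`, `Metadata_guide`,
#'   `Metadata_gene` columns) or a `profile_tbl`.
#' @param level target aggregation level.
#' @return a `profile_tbl` at `level`, inheriting the input's
#'   normalization/selection flags.
#' @examples
#' cells <- tibble::tibble(
#'   Metadata_plate = "P01", Metadata_guide = "g1", Metadata_gene = "G1",
#'   Metadata_targeting = TRUE, Cells_AreaShape_Area = c(1, 3, 100)
#' )
#' aggregate_profiles(cells, "plate_guide")$Cells_AreaShape_Area # median 3
#' @export
aggregate_profiles <- function(x, level = c("plate_guide", "guide", "gene")) {
  level <- match.arg(level)
  st <- attr(x, "ms_state")
  group_cols <- switch(level,
                       plate_guide = c("Metadata_plate", "Metadata_guide"),
                       guide = "Metadata_guide",
                       gene = "Metadata_gene")
  carry <- intersect(c("Metadata_gene", "Metadata_targeting"), names(x))
  carry <- setdiff(carry, group_cols)
  if (level == "gene") carry <- setdiff(carry, "Metadata_guide")
  if (!is.null(st)) {
    order_lv <- c(plate_guide = 1L, guide = 2L, gene = 3L)
    if (order_lv[[level]] <= order_lv[[st$level]]) {
      abort(sprintf("cannot aggregate from level '%s' to '%s'", st$level, level))
    }
  }
  missing_cols <- setdiff(group_cols, names(x))
  if (length(missing_cols)) {
    abort(sprintf("missing grouping column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  feats <- feature_cols(x)
  feats <- setdiff(feats, c("Metadata_plate", "Metadata_guide"))

  dt <- data.table::as.data.table(x[, c(group_cols, carry, feats)])
  # plain lapply(.SD, median) so data.table's grouped-median optimization kicks in
  agg <- dt[, lapply(.SD, median), by = group_cols, .SDcols = feats]
  if (length(carry)) {
    key_map <- unique(dt[, c(group_cols, carry), with = FALSE], by = group_cols)
    agg <- key_map[agg, on = group_cols]
  }
  out <- as_tibble(agg)[, c(group_cols, carry, feats)]
  out <- arrange(out, across(all_of(group_cols)))
  new_profile_tbl(out, level = level,
                  normalized = isTRUE(st$normalized),
                  feature_selected = isTRUE(st$feature_selected),
                  extra = list(feature_meta = attr(x, "feature_meta")))
}

#' Standardize per-plate guide profiles
#'
#' Within each plate independently, centers every feature at its mean and
#' scales to its population standard deviation (denominator `n`) across
#' that plate's guide profiles. Features whose within-plate standard
#' deviation falls below `var_threshold` are set to missing on that plate
#' and recorded in the `flagged_features` attribute.
#'
#' @param x a `profile_tbl` at level `"plate_guide"`.
#' @param var_threshold s.d. below which a feature is treated as constant.
#' @return a normalized `profile_tbl`.
#' @export
normalize_profiles <- function(x, var_threshold = 1e-8) {
  st <- profile_state(x)
  if (st$level != "plate_guide") {
    abort("normalize_profiles() expects per-plate guide profiles (level 'plate_guide')")
  }
  feats <- feature_cols(x)
  plates <- unique(x$Metadata_plate)
  m <- feature_matrix(x)
  flagged <- character(0)
  for (pl in plates) {
    rows <- which(x$Metadata_plate == pl)
    if (length(rows) < 2) {
      abort(sprintf("plate '%s' has %d profile(s); cannot scale", pl, length(rows)))
    }
    sub <- m[rows, , drop = FALSE]
    mu <- colMeans(sub)
    sd_pop <- sqrt(colMeans(sweep(sub, 2, mu)^2))
    bad <- sd_pop < var_threshold
    sd_pop[bad] <- 1
    scaled <- sweep(sweep(sub, 2, mu), 2, sd_pop, "/")
    scaled[, bad] <- NA_real_
    m[rows, ] <- scaled
    flagged <- union(flagged, feats[bad])
  }
  out <- bind_cols(x[, metadata_cols(x)], as_tibble(m))
  new_profile_tbl(out, level = st$level, normalized = TRUE,
                  feature_selected = st$feature_selected,
                  extra = list(flagged_features = flagged,
                               feature_meta = attr(x, "feature_meta")))
}

#' Remove missing, low-variance and redundant features
#'
#' Drops features with missing values, features with near-zero variance,
#' then greedily removes redundant features until no retained pair has
#' absolute Pearson correlation above `corr_threshold`: within each
#' violating pair the feature with the larger mean absolute correlation to
#' all other features is dropped. The operation is idempotent.
#'
#' @param x a normalized `profile_tbl`.
#' @param corr_threshold maximum allowed pairwise |Pearson r| (default 0.9).
#' @param drop_missing drop features containing any missing value.
#' @param var_threshold s.d. below which a feature is dropped as constant.
#' @return a feature-selected `profile_tbl`; the `dropped_features`
#'   attribute records what was removed and why.
#' @export
select_features <- function(x, corr_threshold = 0.9, drop_missing = TRUE,
                            var_threshold = 1e-8) {
  st <- profile_state(x)
  if (nrow(x) < 2) abort("need at least 2 profiles to select features")
  m <- feature_matrix(x)
  feats <- colnames(m)
  dropped <- list()

  if (drop_missing) {
    has_na <- colSums(is.na(m)) > 0
    dropped$missing <- feats[has_na]
    m <- m[, !has_na, drop = FALSE]
  }
  sds <- apply(m, 2, sd)
  low <- sds < var_threshold | is.na(sds)
  dropped$low_variance <- colnames(m)[low]
  m <- m[, !low, drop = FALSE]

  cm <- abs(cor(m))
  diag(cm) <- 0
  keep <- colnames(m)
  while (length(keep) > 1) {
    mx <- max(cm)
    if (mx <= corr_threshold) break
    idx <- which(cm == mx, arr.ind = TRUE)[1, ]
    mean_abs <- rowMeans(cm)
    drop_i <- if (mean_abs[idx[1]] >= mean_abs[idx[2]]) idx[1] else idx[2]
    dropped$redundant <- c(dropped$redundant, keep[drop_i])
    keep <- keep[-drop_i]
    cm <- cm[-drop_i, -drop_i, drop = FALSE]
  }
  out <- bind_cols(x[, metadata_cols(x)], as_tibble(m[, keep, drop = FALSE]))
  new_profile_tbl(out, level = st$level, normalized = st$normalized,
                  feature_selected = TRUE,
                  extra = list(dropped_features = dropped,
                               feature_meta = attr(x, "feature_meta")))
}

#' Reduce profiles by PCA to a target explained-variance fraction
#'
#' Projects the feature matrix onto the smallest number of principal
#' components whose cumulative explained variance reaches `var_fraction`
#' (default 90%). Intended for feature-selected gene-level profiles prior
#' to correlation-based analyses.
#'
#' @param x a `profile_tbl`.
#' @param var_fraction target cumulative explained-variance fraction in
#'   (0, 1].
#' @return a `profile_tbl` whose feature columns are `PC1..PCk`; the
#'   `explained_variance` attribute holds the per-component fractions of
#'   the retained components and `explained_variance_full` all of them.
#' @export
reduce_pca <- function(x, var_fraction = 0.90) {
  st <- profile_state(x)
  if (!is.numeric(var_fraction) || length(var_fraction) != 1 ||
      var_fraction <= 0 || var_fraction > 1) {
    abort("`var_fraction` must be in (0, 1]")
  }
  m <- feature_matrix(x)
  if (anyNA(m)) abort("missing values present; run select_features() first")
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(ev) >= var_fraction - 1e-12)[1]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  out <- bind_cols(x[, metadata_cols(x)], as_tibble(scores))
  new_profile_tbl(out, level = st$level, normalized = st$normalized,
                  feature_selected = st$feature_selected, pca_reduced = TRUE,
                  extra = list(explained_variance = ev[seq_len(k)],
                               explained_variance_full = ev))
}

#' Run the full profile-processing pipeline on a single-cell table
#'
#' Convenience wrapper: median-aggregate cells to per-plate guide profiles,
#' standardize per plate, feature-select, then median-aggregate to
#' per-screen guide and gene profiles. The unselected (but normalized)
#' guide/gene profiles are also returned, as granularity-spectrum analyses
#' use normalized but not feature-selected data.
#'
#' @param cells single-cell tibble (`Metadata_plate`, `Metadata_guide`,
#'   `Metadata_gene`, `Metadata_targeting` plus feature columns).
#' @param corr_threshold redundancy threshold for [select_features()].
#' @return list of `profile_tbl`s: `plate_guide` (normalized), `guide` and
#'   `gene` (feature-selected), `guide_all` and `gene_all` (normalized
#'   only).
#' @export
build_profiles <- function(cells, corr_threshold = 0.9) {
  pg <- normalize_profiles(aggregate_profiles(cells, "plate_guide"))
  sel <- select_features(pg, corr_threshold = corr_threshold)
  guide <- aggregate_profiles(sel, "guide")
  gene <- aggregate_profiles(guide, "gene")
  guide_all <- aggregate_profiles(pg, "guide")
  gene_all <- aggregate_profiles(guide_all, "gene")
  list(plate_guide = pg, guide = guide, gene = gene,
       guide_all = guide_all, gene_all = gene_all)
}
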