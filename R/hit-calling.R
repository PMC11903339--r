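#' Score a gene from its per-feature p-values
#'
#' The profile score is the number of features whose p-value falls below
#' `alpha` (default 0.001); the morphological signal score is the sum of
#' `-log10(p)` over those significant features; per-channel scores count the
#' significant features among each channel's compartment subset (texture,
#' intensity, correlation, radial-distribution and granularity measures of
#' that channel; a correlation feature belongs to both of its channels).
#'
#' @param p_values named numeric vector of p-values in (0, 1], or a tibble
#'   with columns `feature` and `p` as from [feature_pvalues()].
#' @param alpha per-feature significance threshold in (0, 1).
#' @param feature_meta optional parsed feature metadata
#'   ([parse_feature_names()]); required for per-channel scores.
#' @param gene optional gene label carried into the output.
#' @return one-row tibble: `gene` (if given), `n_features`, `profile_score`,
#'   `signal_score` and one `score_<channel>` column per channel when
#'   `feature_meta` is supplied.
#' @examples
#' score_gene(c(a = 0.0005, b = 0.5, c = 0.0009)) # profile score 2
#' @export
score_gene <- function(p_values, alpha = 0.001, feature_meta = NULL, gene = NULL) {
  if (is.data.frame(p_values)) {
    p <- setNames(p_values$p, p_values$feature)
  } else {
    p <- p_values
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1)")
  }
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) abort("p-values must lie in (0, 1]")
  sig <- p < alpha
  out <- tibble(
    n_features = length(p),
    profile_score = sum(sig),
    signal_score = if (any(sig)) sum(-log10(p[sig])) else 0
  )
  if (!is.null(feature_meta)) {
    memb <- channel_membership(feature_meta)
    memb <- memb[match(names(p), rownames(memb)), , drop = FALSE]
    ch_scores <- colSums(memb & sig)
    for (ch in colnames(memb)) out[[paste0("score_", ch)]] <- ch_scores[[ch]]
  }
  if (!is.null(gene)) out <- bind_cols(tibble(gene = gene), out)
  out
}

#' Score every gene of a screen against nontargeting controls
#'
#' Runs the per-feature Mann-Whitney comparison ([feature_pvalues()]) of
#' each targeting gene's guide-level profiles against all nontargeting
#' guide profiles and summarises each gene with [score_gene()]. Genes with
#' fewer than `min_units` guide profiles are reported with `NA` scores.
#'
#' @param profiles a guide-level `profile_tbl` (typically normalized and
#'   feature-selected) containing both targeting and nontargeting guides,
#'   with `Metadata_gene` and `Metadata_targeting` columns.
#' @param alpha per-feature significance threshold.
#' @param feature_meta parsed feature metadata; defaults to parsing the
#'   profile's feature names.
#' @param min_units minimum guide profiles needed to score a gene.
#' @param keep_pvalues if `TRUE` (default), attach the gene x feature
#'   p-value matrix as the `p_matrix` attribute (used by single-feature
#'   screens).
#' @return a `gene_scores` tibble (one row per targeting gene) with
#'   attributes `alpha`, `feature_meta` and optionally `p_matrix`.
#' @export
score_screen <- function(profiles, alpha = 0.001, feature_meta = NULL,
                         min_units = 2L, keep_pvalues = TRUE) {
  if (!"Metadata_targeting" %in% names(profiles)) {
    abort("`profiles` needs a Metadata_targeting column")
  }
  feats <- feature_cols(profiles)
  if (is.null(feature_meta)) {
    feature_meta <- tryCatch(parse_feature_names(feats), error = function(e) NULL)
  }
  m <- feature_matrix(profiles)
  ctl <- m[!profiles$Metadata_targeting, , drop = FALSE]
  if (nrow(ctl) < 2) abort("need at least 2 nontargeting control profiles")
  genes <- unique(profiles$Metadata_gene[profiles$Metadata_targeting])
  memb <- if (!is.null(feature_meta)) channel_membership(feature_meta) else NULL
  if (!is.null(memb)) memb <- memb[match(feats, rownames(memb)), , drop = FALSE]

  rows_of <- split(seq_len(nrow(profiles)), profiles$Metadata_gene)
  sorted_ctl <- apply(ctl, 2, sort) # shared across genes; U via binary search
  p_mat <- if (keep_pvalues) {
    matrix(NA_real_, nrow = length(genes), ncol = length(feats),
           dimnames = list(genes, feats))
  } else NULL

  res <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    rows <- rows_of[[g]]
    if (length(rows) < min_units) {
      sc <- tibble(gene = g, n_units = length(rows), n_features = length(feats),
                   profile_score = NA_real_, signal_score = NA_real_)
      if (!is.null(memb)) for (ch in colnames(memb)) sc[[paste0("score_", ch)]] <- NA_real_
      res[[i]] <- sc
      next
    }
    p <- mw_pvalues_vs_sorted(m[rows, , drop = FALSE], sorted_ctl)
    if (keep_pvalues) p_mat[i, ] <- p
    sig <- p < alpha
    sc <- tibble(gene = g, n_units = length(rows), n_features = length(feats),
                 profile_score = sum(sig),
                 signal_score = if (any(sig)) sum(-log10(p[sig])) else 0)
    if (!is.null(memb)) {
      ch_scores <- colSums(memb & sig)
      for (ch in colnames(memb)) sc[[paste0("score_", ch)]] <- ch_scores[[ch]]
    }
    res[[i]] <- sc
  }
  out <- bind_rows(res)
  attr(out, "alpha") <- alpha
  attr(out, "feature_meta") <- feature_meta
  if (keep_pvalues) attr(out, "p_matrix") <- p_mat
  class(out) <- unique(c("gene_scores", class(out)))
  out
}

#' Empirical-null score threshold at a target FDR
#'
#' The hit threshold is the null score at ascending rank
#' `ceiling((1 - fdr) * m)` among the `m` empirical-null scores (an order
#' statistic, no interpolation); hits must be strictly greater, which
#' guarantees that at most a fraction `fdr` of the null set is flagged.
#'
#' @param null_scores numeric vector of null (zero-TPM gene) scores.
#' @param fdr target false discovery rate.
#' @return the threshold score (scalar).
#' @examples
#' empirical_threshold(1:100, fdr = 0.01) # 99
#' @export
empirical_threshold <- function(null_scores, fdr = 0.01) {
  null_scores <- null_scores[!is.na(null_scores)]
  if (length(null_scores) == 0) abort("empty null score set")
  check_fraction(fdr, "fdr", closed_left = FALSE, closed_right = FALSE)
  if (length(null_scores) < 1 / fdr) {
    warn(sprintf("only %d null scores for fdr = %g; threshold is coarse",
                 length(null_scores), fdr))
  }
  s <- sort(null_scores)
  s[ceiling((1 - fdr) * length(s))]
}

#' Call whole-cell and compartment hits at an empirical FDR
#'
#' Flags genes whose whole-cell profile score strictly exceeds the
#' [empirical_threshold()] of the zero-TPM null genes' profile scores, and
#' analogously per channel using each channel's own score and its own null
#' threshold. A gene can be a compartment hit without being a whole-cell
#' hit.
#'
#' @param scores a `gene_scores` tibble from [score_screen()] (nontargeting
#'   controls are not rows of this table).
#' @param null_genes character vector of empirical-null (zero-TPM) genes;
#'   must all be scored rows of `scores`.
#' @param fdr target false discovery rate (default 0.01).
#' @return a `hit_table`: `scores` plus `is_null`, `whole_cell_hit`,
#'   `hit_<channel>` flags and `compartment_hit`; attributes `fdr`,
#'   `thresholds` (named vector) and `null_genes`.
#' @export
call_hits <- function(scores, null_genes, fdr = 0.01) {
  if (!all(null_genes %in% scores$gene)) {
    missing <- setdiff(null_genes, scores$gene)
    abort(sprintf("null gene(s) with no score: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  null_rows <- scores$gene %in% null_genes
  null_sc <- scores$profile_score[null_rows]
  if (all(is.na(null_sc))) abort("no scored null genes")
  thr <- c(whole_cell = empirical_threshold(null_sc, fdr))
  out <- scores
  out$is_null <- null_rows
  out$whole_cell_hit <- !is.na(out$profile_score) & out$profile_score > thr[["whole_cell"]]
  ch_cols <- grep("^score_", names(scores), value = TRUE)
  for (sc_col in ch_cols) {
    ch <- sub("^score_", "", sc_col)
    t_ch <- empirical_threshold(scores[[sc_col]][null_rows], fdr)
    thr[[ch]] <- t_ch
    out[[paste0("hit_", ch)]] <- !is.na(out[[sc_col]]) & out[[sc_col]] > t_ch
  }
  hit_cols <- if (length(ch_cols)) paste0("hit_", sub("^score_", "", ch_cols)) else character(0)
  out$compartment_hit <- if (length(hit_cols)) {
    rowSums(as.matrix(out[, hit_cols])) > 0
  } else FALSE
  attr(out, "fdr") <- fdr
  attr(out, "thresholds") <- thr
  attr(out, "null_genes") <- null_genes
  attr(out, "alpha") <- attr(scores, "alpha")
  class(out) <- unique(c("hit_table", class(scores)))
  out
}

#' Hit counts across an FDR grid
#'
#' Re-thresholds the same scores at several FDR levels (the 1-5% grid by
#' default); less stringent FDRs produce larger hit lists.
#'
#' @inheritParams call_hits
#' @param fdr_grid FDR levels to evaluate.
#' @return tibble with one row per FDR level: threshold, whole-cell,
#'   compartment-only and total hit counts, and the fraction of null genes
#'   flagged.
#' @export
hit_counts_by_fdr <- function(scores, null_genes, fdr_grid = seq(0.01, 0.05, by = 0.01)) {
  bind_rows(lapply(fdr_grid, function(f) {
    ht <- call_hits(scores, null_genes, fdr = f)
    tibble(
      fdr = f,
      threshold = attr(ht, "thresholds")[["whole_cell"]],
      n_whole_cell = sum(ht$whole_cell_hit, na.rm = TRUE),
      n_compartment_only = sum(ht$compartment_hit & !ht$whole_cell_hit, na.rm = TRUE),
      n_total = sum(ht$whole_cell_hit | ht$compartment_hit, na.rm = TRUE),
      null_flagged_frac = mean(ht$whole_cell_hit[ht$is_null], na.rm = TRUE)
    )
  }))
}

#' Average normalized channel fractions of significant features
#'
#' For each gene in a set, divides its per-channel significant-feature
#' count by that channel's total feature count, renormalizes the five
#' values to sum to one, then averages over the gene set (the pie-chart
#' summary of where a gene group's morphological signal concentrates).
#' Genes with no significant features are excluded with a warning.
#'
#' @param scores a `gene_scores`/`hit_table` tibble with `score_<channel>`
#'   columns.
#' @param feature_meta parsed feature metadata (defaults to the attribute
#'   stored on `scores`).
#' @param genes optional subset of genes to average over.
#' @return tibble with columns `channel` and `fraction` (summing to 1).
#' @export
channel_fractions <- function(scores, feature_meta = attr(scores, "feature_meta"),
                              genes = NULL) {
  if (is.null(feature_meta)) abort("feature metadata required")
  if (!is.null(genes)) scores <- scores[scores$gene %in% genes, ]
  if (nrow(scores) == 0) abort("empty gene set")
  memb <- channel_membership(feature_meta)
  n_per_channel <- colSums(memb)
  channels <- names(n_per_channel)
  sc <- as.matrix(scores[, paste0("score_", channels), drop = FALSE])
  total_sig <- rowSums(sc)
  drop <- is.na(total_sig) | total_sig == 0
  if (any(drop)) {
    warn(sprintf("%d gene(s) with zero significant features excluded", sum(drop)))
    sc <- sc[!drop, , drop = FALSE]
  }
  if (nrow(sc) == 0) abort("no genes with significant features")
  norm <- sweep(sc, 2, n_per_channel, "/")
  norm <- norm / rowSums(norm)
  tibble(channel = channels, fraction = unname(colMeans(norm)))
}
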