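#' Within-complex versus background profile correlations
#'
#' Retains the complexes in which at least `min_frac` of the members are
#' profiled hit genes (the comparison is exact at the boundary: a complex
#' with 2 of 6 members profiled passes `min_frac = 1/3`), computes the
#' Pearson correlation between the profiles of every pair of profiled
#' members within each retained complex, and compares against the
#' background of all profiled-gene pairs.
#'
#' @param gene_profiles a gene-level `profile_tbl` (typically PCA-reduced,
#'   restricted to hit genes) with a `Metadata_gene` column.
#' @param complexes named list of complex member gene vectors.
#' @param min_frac minimum fraction of a complex's members that must be
#'   profiled (default 1/3).
#' @return list with `within` (tibble `complex`, `gene_a`, `gene_b`, `r`),
#'   `background` (tibble `gene_a`, `gene_b`, `r`) and `retained`
#'   (character vector of retained complex names).
#' @export
complex_correlations <- function(gene_profiles, complexes, min_frac = 1 / 3) {
  genes <- gene_profiles$Metadata_gene
  if (is.null(genes)) abort("`gene_profiles` needs a Metadata_gene column")
  m <- feature_matrix(gene_profiles)
  rownames(m) <- genes
  cm <- cor(t(m))
  eps <- sqrt(.Machine$double.eps)
  retained <- names(complexes)[vapply(complexes, function(mem) {
    sum(mem %in% genes) / length(mem) >= min_frac - eps
  }, logical(1))]
  within <- bind_rows(lapply(retained, function(nm) {
    mem <- intersect(complexes[[nm]], genes)
    if (length(mem) < 2) return(NULL)
    cmb <- utils::combn(mem, 2)
    tibble(complex = nm, gene_a = cmb[1, ], gene_b = cmb[2, ],
           r = cm[cbind(cmb[1, ], cmb[2, ])])
  }))
  if (nrow(cm) < 2) abort("need at least 2 profiled genes")
  cmb_all <- utils::combn(genes, 2)
  background <- tibble(gene_a = cmb_all[1, ], gene_b = cmb_all[2, ],
                       r = cm[cbind(cmb_all[1, ], cmb_all[2, ])])
  list(within = within, background = background, retained = retained)
}

#' Pair link scores binned by profile correlation
#'
#' Computes the Pearson correlation between the profiles of every scored
#' gene pair and bins the pairs into `n_bins` equal-width, right-closed
#' bins spanning [-1, 1]; returns the link-score distribution per bin.
#' Bins partition all scored pairs (r = 1 falls in the last bin).
#'
#' @param gene_profiles gene-level `profile_tbl` with `Metadata_gene`.
#' @param pair_scores tibble (`gene_a`, `gene_b`, `score`), symmetric pairs
#'   listed once.
#' @param n_bins number of correlation bins (default 8).
#' @return tibble with one row per scored pair present in the profiles:
#'   `gene_a`, `gene_b`, `r`, `score`, `bin` (integer), `bin_lo`, `bin_hi`.
#' @export
binned_pair_scores <- function(gene_profiles, pair_scores, n_bins = 8L) {
  check_count(n_bins, "n_bins")
  genes <- gene_profiles$Metadata_gene
  m <- feature_matrix(gene_profiles)
  rownames(m) <- genes
  keep <- pair_scores$gene_a %in% genes & pair_scores$gene_b %in% genes
  ps <- pair_scores[keep, ]
  if (nrow(ps) == 0) {
    return(tibble(gene_a = character(0), gene_b = character(0), r = numeric(0),
                  score = numeric(0), bin = integer(0),
                  bin_lo = numeric(0), bin_hi = numeric(0)))
  }
  cm <- cor(t(m))
  r <- cm[cbind(ps$gene_a, ps$gene_b)]
  breaks <- seq(-1, 1, length.out = n_bins + 1)
  bin <- findInterval(r, breaks, rightmost.closed = TRUE, left.open = TRUE)
  bin[bin == 0L] <- 1L # r = -1 belongs to the first bin
  tibble(gene_a = ps$gene_a, gene_b = ps$gene_b, r = r, score = ps$score,
         bin = bin, bin_lo = breaks[bin], bin_hi = breaks[bin + 1])
}

#' Split genes into essential and nonessential by dependency score
#'
#' A gene is essential when its dependency score is strictly below the
#' threshold (default -0.5); the boundary value itself is nonessential.
#'
#' @param signal_scores tibble (`gene`, `signal_score`).
#' @param dependency tibble (`gene`, `dependency`).
#' @param threshold dependency threshold (default -0.5).
#' @return tibble (`gene`, `signal_score`, `dependency`, `essential`)
#'   restricted to genes present in both inputs.
#' @export
essentiality_split <- function(signal_scores, dependency, threshold = -0.5) {
  out <- dplyr::inner_join(signal_scores[, c("gene", "signal_score")],
                           dependency[, c("gene", "dependency")], by = "gene")
  out$essential <- out$dependency < threshold
  out
}

#' Rank genes by cosine similarity to a query gene's profile
#'
#' Orders all other profiled genes by decreasing cosine similarity to the
#' query profile, the ranked-list input for preranked enrichment tools.
#'
#' @param gene_profiles gene-level `profile_tbl` with `Metadata_gene`.
#' @param query query gene (must be profiled).
#' @return tibble (`gene`, `cosine`, `rank`), query excluded.
#' @export
rank_by_similarity <- function(gene_profiles, query) {
  genes <- gene_profiles$Metadata_gene
  if (!query %in% genes) abort(sprintf("unknown query gene '%s'", query))
  m <- feature_matrix(gene_profiles)
  rownames(m) <- genes
  q <- m[query, ]
  others <- setdiff(genes, query)
  sims <- cosine_similarity(q, m[others, , drop = FALSE])
  out <- tibble(gene = others, cosine = unname(sims))
  out <- arrange(out, dplyr::desc(.data$cosine))
  out$rank <- seq_len(nrow(out))
  out
}

#' Write a two-column .rnk ranked-list file
#'
#' @param ranked tibble with `gene` and a numeric score column (second
#'   column used).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rnk <- function(ranked, path) {
  score_col <- setdiff(names(ranked), "gene")[1]
  readr::write_tsv(ranked[, c("gene", score_col)], path, col_names = FALSE)
  invisible(path)
}
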