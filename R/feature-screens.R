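#' Per-gene p-values for a single feature
#'
#' Reuses the hit-calling Mann-Whitney machinery on one feature: each
#' gene's guide-level values for that feature are compared with the
#' nontargeting control guides' values (two-sided).
#'
#' @param profiles guide-level `profile_tbl` with `Metadata_gene` and
#'   `Metadata_targeting`.
#' @param feature feature (column) name.
#' @param min_units minimum guide profiles needed to test a gene.
#' @return tibble (`gene`, `p`); untestable genes get `NA`.
#' @export
feature_gene_pvalues <- function(profiles, feature, min_units = 2L) {
  if (!feature %in% names(profiles)) abort(sprintf("unknown feature '%s'", feature))
  v <- profiles[[feature]]
  ctl <- v[!profiles$Metadata_targeting]
  genes <- unique(profiles$Metadata_gene[profiles$Metadata_targeting])
  vals <- split(v[profiles$Metadata_targeting],
                profiles$Metadata_gene[profiles$Metadata_targeting])
  Y <- matrix(ctl, ncol = 1)
  p <- vapply(genes, function(g) {
    x <- vals[[g]]
    if (length(x) < min_units) return(NA_real_)
    mw_pvalues_matrix(matrix(x, ncol = 1), Y)
  }, numeric(1))
  tibble(gene = genes, p = unname(p))
}

#' Top-N-plus gene list for one feature
#'
#' Sorts genes by p-value and returns every gene whose p-value is less than
#' or equal to that of the gene at `rank_cut` (default 20), so ties at the
#' boundary extend the list; the list size is therefore always at least
#' `rank_cut` when that many genes are available.
#'
#' @param feature_pvals tibble (`gene`, `p`) for one feature.
#' @param rank_cut list rank defining the threshold p-value.
#' @return tibble of the selected genes, sorted by `p`.
#' @export
top_gene_list <- function(feature_pvals, rank_cut = 20L) {
  check_count(rank_cut, "rank_cut")
  x <- feature_pvals[!is.na(feature_pvals$p), ]
  x <- arrange(x, .data$p)
  if (nrow(x) < rank_cut) {
    warn(sprintf("only %d genes available (< rank_cut = %d); returning all",
                 nrow(x), rank_cut))
    return(x)
  }
  p_cut <- x$p[rank_cut]
  x[x$p <= p_cut, ]
}

#' Gene-set enrichment of a hit list by Fisher's exact test
#'
#' For each gene set, builds the 2x2 table of hit/non-hit by in-set/out-set
#' over the tested universe and computes the one-sided (enrichment)
#' Fisher exact p-value, with Benjamini-Hochberg and Bonferroni adjusted
#' p-values across sets reported side by side.
#'
#' @param hits character vector of hit genes (a subset of `universe`).
#' @param sets named list of gene sets (restricted to the universe).
#' @param universe all tested genes.
#' @return tibble with one row per set: the 2x2 counts (`n_hit_in`,
#'   `n_hit_out`, `n_miss_in`, `n_miss_out`), `odds_ratio`, `p`, `p_bh`,
#'   `p_bonferroni`, sorted by `p`.
#' @export
set_enrichment <- function(hits, sets, universe) {
  if (length(universe) == 0) abort("empty universe")
  hits <- intersect(hits, universe)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    a <- length(intersect(hits, s))
    b <- length(hits) - a
    cc <- length(s) - a
    d <- length(universe) - a - b - cc
    ft <- fisher.test(matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE),
                      alternative = "greater")
    tibble(set = nm, n_hit_in = a, n_hit_out = b, n_miss_in = cc, n_miss_out = d,
           odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  out <- bind_rows(rows)
  out$p_bh <- p.adjust(out$p, method = "BH")
  out$p_bonferroni <- p.adjust(out$p, method = "bonferroni")
  arrange(out, .data$p)
}

#' Single-feature screen: top list plus enrichment
#'
#' Convenience composition: per-gene p-values for one feature, the
#' top-N-plus list, and gene-set enrichment of that list.
#'
#' @inheritParams feature_gene_pvalues
#' @inheritParams top_gene_list
#' @param sets named list of gene sets.
#' @return list with `pvals`, `top` and `enrichment`.
#' @export
feature_screen <- function(profiles, feature, sets, rank_cut = 20L) {
  pv <- feature_gene_pvalues(profiles, feature)
  top <- top_gene_list(pv, rank_cut = rank_cut)
  enr <- set_enrichment(top$gene, sets, universe = pv$gene[!is.na(pv$p)])
  list(pvals = pv, top = top, enrichment = enr)
}

#' Granularity spectrum traces for a gene group
#'
#' Extracts, for each gene in a group, the ordered granularity feature
#' values (size 1..G) of one object/channel from normalized (but not
#' feature-selected) gene-level profiles, together with the group mean
#' trace. A coordinated mass shift such as vacuolar-ATPase disruption shows
#' as a negative value at size 1 with compensatory positive values at
#' larger sizes.
#'
#' @param profiles gene-level normalized `profile_tbl` retaining all
#'   granularity features.
#' @param channel channel label (e.g. `"WGA"`).
#' @param object object label (e.g. `"Cells"`).
#' @param gene_group character vector of genes to trace.
#' @return tibble (`gene`, `size`, `value`); rows with `gene == ".mean"`
#'   hold the group mean trace.
#' @export
granularity_spectrum <- function(profiles, channel = "WGA", object = "Cells",
                                 gene_group) {
  feats <- feature_cols(profiles)
  pat <- sprintf("^%s_Granularity_(\\d+)_%s$", object, channel)
  hit_feats <- grep(pat, feats, value = TRUE)
  if (length(hit_feats) == 0) {
    abort(sprintf("no granularity features found for %s/%s", object, channel))
  }
  sizes <- as.integer(sub(pat, "\\1", hit_feats))
  ord <- order(sizes)
  hit_feats <- hit_feats[ord]
  sizes <- sizes[ord]
  if (!identical(sizes, seq_len(max(sizes)))) {
    abort(sprintf("missing granularity size index for %s/%s (found: %s)",
                  object, channel, paste(sizes, collapse = ",")))
  }
  missing_genes <- setdiff(gene_group, profiles$Metadata_gene)
  if (length(missing_genes)) {
    warn(sprintf("%d gene(s) not profiled: %s", length(missing_genes),
                 paste(head(missing_genes, 5), collapse = ", ")))
  }
  sub <- profiles[profiles$Metadata_gene %in% gene_group, c("Metadata_gene", hit_feats)]
  if (nrow(sub) == 0) abort("none of the group's genes are profiled")
  long <- tidyr::pivot_longer(sub, cols = all_of(hit_feats),
                              names_to = "feature", values_to = "value")
  long$size <- sizes[match(long$feature, hit_feats)]
  traces <- long[, c("Metadata_gene", "size", "value")]
  names(traces)[1] <- "gene"
  mean_trace <- traces |>
    group_by(.data$size) |>
    summarise(value = mean(.data$value), .groups = "drop") |>
    mutate(gene = ".mean") |>
    select("gene", "size", "value")
  bind_rows(arrange(traces, .data$gene, .data$size), mean_trace)
}
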