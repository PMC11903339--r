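# broom-style summaries for fitted/derived result objects.

#' Tidy a hit table
#'
#' @param x a `hit_table` from [call_hits()].
#' @param ... unused.
#' @return the underlying tibble (one row per gene).
#' @export
tidy.hit_table <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), c("hit_table", "gene_scores"))
  as_tibble(out)
}

#' One-row summary of a hit table
#'
#' @param x a `hit_table`.
#' @param ... unused.
#' @return tibble with the FDR level, whole-cell threshold and hit counts.
#' @export
glance.hit_table <- function(x, ...) {
  tibble(
    fdr = attr(x, "fdr"),
    alpha = attr(x, "alpha") %||% NA_real_,
    threshold_whole_cell = attr(x, "thresholds")[["whole_cell"]],
    n_genes = sum(!x$is_null),
    n_whole_cell_hits = sum(x$whole_cell_hit, na.rm = TRUE),
    n_compartment_hits = sum(x$compartment_hit & !x$whole_cell_hit, na.rm = TRUE),
    n_null_genes = sum(x$is_null),
    null_flagged_frac = mean(x$whole_cell_hit[x$is_null], na.rm = TRUE)
  )
}
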