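#' Generate synthetic functional annotations for a screen
#'
#' Builds an annotation set matched to a synthetic screen's planted truth:
#' protein-complex-style groupings of genes that share an effect direction,
#' pairwise link scores (integer 0-999) that are a monotone noisy transform
#' of the absolute cosine similarity between planted effect vectors,
#' GMT-style gene sets, per-gene expression (TPM) and a gene-dependency
#' score negatively associated with effect magnitude for an "essential"
#' subset.
#'
#' @param screen a `screen_dataset` from [generate_screen()].
#' @param config the [screen_config()] used to generate it.
#' @param noise_sd standard deviation of the noise added to |cosine| before
#'   rescaling to the 0-999 link-score range. With `noise_sd = 0` the score
#'   ranking reproduces the truth |cosine| ranking (up to integer rounding
#'   ties).
#' @param frac_essential fraction of genes marked essential; essential genes
#'   are sampled with probability increasing in planted effect magnitude and
#'   receive dependency scores below -0.5.
#' @param n_background_pairs number of random gene pairs (beyond
#'   within-module pairs) given a link score.
#' @param n_random_sets number of additional random gene sets in the GMT
#'   collection.
#' @return An object of class `annotation_set`: list with `complexes`
#'   (named list of member vectors), `pair_scores` (tibble `gene_a`,
#'   `gene_b`, `score`), `gene_sets` (named list), `expression` (tibble
#'   `gene`, `tpm`) and `dependency` (tibble `gene`, `dependency`).
#' @export
generate_annotations <- function(screen, config = screen$config, noise_sd = 0.05,
                                 frac_essential = 0.2, n_background_pairs = 2000,
                                 n_random_sets = 10) {
  if (!inherits(screen, "screen_dataset")) abort("`screen` must be a screen_dataset")
  if (is.null(screen$effects)) abort("screen carries no truth effect vectors")
  check_fraction(frac_essential, "frac_essential")
  set.seed(config$seed + 1L)

  truth <- screen$truth
  genes <- truth$gene
  effects <- screen$effects

  ## complexes: planted modules (>= 2 members) plus random decoys --------
  module_ids <- sort(unique(truth$module[!is.na(truth$module)]))
  complexes <- lapply(module_ids, function(m) truth$gene[!is.na(truth$module) & truth$module == m])
  names(complexes) <- paste0("complex_", module_ids)
  complexes <- complexes[lengths(complexes) >= 2]
  n_decoys <- max(3L, length(complexes) %/% 2L)
  nonhits <- truth$gene[!truth$is_hit]
  if (length(nonhits) >= 4) {
    decoys <- lapply(seq_len(n_decoys), function(i) {
      sample(nonhits, min(length(nonhits), sample(3:6, 1)))
    })
    names(decoys) <- sprintf("complex_decoy_%02d", seq_along(decoys))
    complexes <- c(complexes, decoys)
  }

  ## pairwise link scores ------------------------------------------------
  within_pairs <- bind_rows(lapply(complexes, function(mem) {
    if (length(mem) < 2) return(NULL)
    cmb <- utils::combn(sort(mem), 2)
    tibble(gene_a = cmb[1, ], gene_b = cmb[2, ])
  }))
  n_bg <- min(n_background_pairs, choose(length(genes), 2))
  bg <- tibble(gene_a = sample(genes, n_bg * 2, replace = TRUE),
               gene_b = sample(genes, n_bg * 2, replace = TRUE)) |>
    filter(.data$gene_a != .data$gene_b)
  swap <- bg$gene_a > bg$gene_b
  tmpa <- bg$gene_a
  bg$gene_a[swap] <- bg$gene_b[swap]
  bg$gene_b[swap] <- tmpa[swap]
  pairs <- distinct(bind_rows(within_pairs, head(bg, n_bg)),
                    .data$gene_a, .data$gene_b)

  abs_cos <- map_dbl(seq_len(nrow(pairs)), function(i) {
    a <- effects[pairs$gene_a[i], ]
    b <- effects[pairs$gene_b[i], ]
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    abs(sum(a * b) / (na * nb))
  })
  score_raw <- pmin(1, pmax(0, abs_cos + rnorm(length(abs_cos), sd = noise_sd)))
  pairs$score <- as.integer(round(999 * score_raw))

  ## gene sets (GMT-style): modules plus random sets ---------------------
  gene_sets <- complexes[grep("decoy", names(complexes), invert = TRUE)]
  names(gene_sets) <- sub("^complex_", "set_", names(gene_sets))
  if (n_random_sets > 0) {
    rs <- lapply(seq_len(n_random_sets), function(i) {
      sample(genes, min(length(genes), sample(5:15, 1)))
    })
    names(rs) <- sprintf("set_random_%02d", seq_len(n_random_sets))
    gene_sets <- c(gene_sets, rs)
  }

  ## dependency: essential subset enriched for strong effects ------------
  n_ess <- round(frac_essential * length(genes))
  w <- 0.5 + truth$effect_mag
  essential <- sample(genes, n_ess, prob = w)
  dep <- rnorm(length(genes), mean = 0, sd = 0.15)
  names(dep) <- genes
  dep[essential] <- -0.5 - runif(n_ess, 0.05, 0.6) -
    0.5 * truth$effect_mag[match(essential, genes)]

  structure(list(
    complexes = complexes,
    pair_scores = pairs,
    gene_sets = gene_sets,
    expression = tibble(gene = genes, tpm = truth$tpm),
    dependency = tibble(gene = genes, dependency = unname(dep))
  ), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set>\n")
  cat(sprintf("  %d complexes, %d scored pairs, %d gene sets, %d genes annotated\n",
              length(x$complexes), nrow(x$pair_scores), length(x$gene_sets),
              nrow(x$expression)))
  invisible(x)
}
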