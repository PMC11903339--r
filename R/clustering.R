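#' Gene-by-gene Pearson correlation matrix
#'
#' @param gene_profiles gene-level `profile_tbl` (typically PCA-reduced)
#'   with a `Metadata_gene` column.
#' @return symmetric correlation matrix with unit diagonal, gene names as
#'   dimnames.
#' @export
correlation_matrix <- function(gene_profiles) {
  genes <- gene_profiles$Metadata_gene
  if (is.null(genes)) abort("`gene_profiles` needs a Metadata_gene column")
  if (length(genes) < 2) abort("need at least 2 genes")
  m <- feature_matrix(gene_profiles)
  sds <- apply(m, 1, sd)
  if (any(sds == 0 | is.na(sds))) {
    abort(sprintf("zero-variance profile for gene(s): %s",
                  paste(genes[sds == 0 | is.na(sds)], collapse = ", ")))
  }
  cm <- cor(t(m))
  dimnames(cm) <- list(genes, genes)
  cm
}

#' Ward leaf order of genes
#'
#' Agglomerative Ward (variance-minimisation) clustering on Euclidean
#' distances between the rows of the gene correlation matrix; returns the
#' dendrogram leaf order. Deterministic for a fixed input (ties resolved by
#' input order).
#'
#' @param x a gene-level `profile_tbl` (correlations computed first) or a
#'   correlation matrix with gene dimnames.
#' @return character vector: gene permutation (leaf order), with the
#'   `hclust` object as attribute `hclust`.
#' @export
ward_order <- function(x) {
  cm <- if (is.matrix(x)) x else correlation_matrix(x)
  if (any(!is.finite(cm))) abort("non-finite values in correlation matrix")
  if (nrow(cm) == 2) {
    out <- rownames(cm)
    return(out)
  }
  hc <- hclust(dist(cm, method = "euclidean"), method = "ward.D2")
  out <- rownames(cm)[hc$order]
  attr(out, "hclust") <- hc
  out
}

#' Diagonally merged comparative heatmap of two screens
#'
#' Restricts both correlation matrices to their shared genes, derives the
#' gene order by Ward clustering of one screen, and merges both into one
#' square matrix: the lower triangle holds screen A and the upper triangle
#' screen B, both indexed by the same gene order, with unit diagonal.
#'
#' @param corrA,corrB gene correlation matrices sharing gene names.
#' @param order_from which screen's Ward clustering sets the gene order.
#' @return a `merged_heatmap`: list with `order` (gene permutation),
#'   `matrix` (merged square matrix) and `order_from`.
#' @export
diagonal_merge <- function(corrA, corrB, order_from = c("A", "B")) {
  order_from <- match.arg(order_from)
  shared <- intersect(rownames(corrA), rownames(corrB))
  if (length(shared) == 0) abort("no shared genes between the two screens")
  if (length(shared) < 2) abort("need at least 2 shared genes")
  A <- corrA[shared, shared]
  B <- corrB[shared, shared]
  ord <- as.character(ward_order(if (order_from == "A") A else B))
  A <- A[ord, ord]
  B <- B[ord, ord]
  M <- diag(1, length(ord))
  dimnames(M) <- list(ord, ord)
  M[lower.tri(M)] <- A[lower.tri(A)]
  M[upper.tri(M)] <- B[upper.tri(B)]
  structure(list(order = ord, matrix = M, order_from = order_from),
            class = "merged_heatmap")
}

#' @export
print.merged_heatmap <- function(x, ...) {
  cat(sprintf("<merged_heatmap> %d shared genes, order set by screen %s\n",
              length(x$order), x$order_from))
  invisible(x)
}
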