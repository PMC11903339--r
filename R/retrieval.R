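#' Average precision of one query profile against its siblings
#'
#' From a group of M query profiles (e.g. the guides targeting one gene)
#' and N control profiles: for the given query, the remaining M-1 sibling
#' profiles and the N controls are ranked by decreasing cosine similarity
#' to the query, and non-interpolated average precision is accumulated as
#' `AP = sum over sibling ranks k of P_k * dR_k`, with precision
#' `P_k = TP_k / k`, recall `R_k = TP_k / (M - 1)` and recall increment
#' `dR_k = 1/(M-1)` at sibling ranks. Ties in similarity are broken by
#' stable input order (siblings before controls).
#'
#' @param query numeric profile vector.
#' @param siblings matrix (M-1 rows) of the query's sibling profiles.
#' @param controls matrix (N rows) of control profiles.
#' @return the AP value, with the per-rank bookkeeping
#'   (`k`, `similarity`, `is_sibling`, `TP_k`, `P_k`, `R_k`) in the
#'   `ranks` attribute.
#' @examples
#' average_precision(c(1, 0), matrix(c(1, 0), 1), matrix(c(0, 1), 1)) # 1
#' @export
average_precision <- function(query, siblings, controls) {
  if (is.null(dim(siblings))) siblings <- matrix(siblings, nrow = 1)
  if (is.null(dim(controls))) controls <- matrix(controls, nrow = 1)
  m1 <- nrow(siblings)
  if (m1 < 1) abort("need at least one sibling (M >= 2)")
  sims <- c(cosine_similarity(query, siblings), cosine_similarity(query, controls))
  is_sib <- rep(c(TRUE, FALSE), c(m1, nrow(controls)))
  ord <- order(-sims, method = "radix") # stable: ties keep input order, siblings first
  tp <- cumsum(is_sib[ord])
  p_k <- tp / seq_along(tp)
  r_k <- tp / m1
  ap <- sum(p_k[is_sib[ord]]) / m1
  attr(ap, "ranks") <- tibble(
    k = seq_along(tp), similarity = sims[ord], is_sibling = is_sib[ord],
    TP_k = tp, P_k = p_k, R_k = r_k
  )
  ap
}

#' Mean average precision for a replicate group
#'
#' Each of the M group members serves once as the query against its M-1
#' siblings and the N controls; mAP is the mean of the M per-query AP
#' values. Used as a profile-strength metric: how highly a gene's replicate
#' guide profiles rank against negative-control profiles.
#'
#' @param group matrix of M >= 2 query profiles (rows; row names label the
#'   queries) or a data frame of numeric columns.
#' @param controls matrix of N >= 1 control profiles.
#' @return a `retrieval_result`: list with `M`, `N`, `per_query` (tibble
#'   `query`, `ap`), `mAP` and per-query rank bookkeeping in `ranks`.
#' @export
map_score <- function(group, controls) {
  group <- as.matrix(group)
  controls <- as.matrix(controls)
  M <- nrow(group)
  if (M < 2) abort("need M >= 2 query profiles")
  if (nrow(controls) < 1) abort("need N >= 1 control profiles")
  qnames <- rownames(group)
  if (is.null(qnames)) qnames <- paste0("query_", seq_len(M))
  aps <- numeric(M)
  ranks <- vector("list", M)
  for (i in seq_len(M)) {
    ap <- average_precision(group[i, ], group[-i, , drop = FALSE], controls)
    aps[i] <- as.numeric(ap)
    ranks[[i]] <- attr(ap, "ranks")
  }
  names(ranks) <- qnames
  structure(list(M = M, N = nrow(controls),
                 per_query = tibble(query = qnames, ap = aps),
                 mAP = mean(aps), ranks = ranks),
            class = "retrieval_result")
}

#' @export
print.retrieval_result <- function(x, ...) {
  cat(sprintf("<retrieval_result> M = %d queries, N = %d controls, mAP = %.4f\n",
              x$M, x$N, x$mAP))
  invisible(x)
}

#' @export
tidy.retrieval_result <- function(x, ...) x$per_query

#' @export
glance.retrieval_result <- function(x, ...) tibble(mAP = x$mAP, M = x$M, N = x$N)

#' Per-gene mAP across a guide-level profile table
#'
#' Computes [map_score()] for every targeting gene with at least two guide
#' profiles, using the nontargeting guide profiles as the control group.
#'
#' @param profiles guide-level `profile_tbl` with `Metadata_gene` and
#'   `Metadata_targeting` columns.
#' @return tibble with columns `gene`, `M`, `mAP`.
#' @export
map_screen <- function(profiles) {
  m <- feature_matrix(profiles)
  ctl <- m[!profiles$Metadata_targeting, , drop = FALSE]
  if (nrow(ctl) < 1) abort("no nontargeting control profiles")
  genes <- unique(profiles$Metadata_gene[profiles$Metadata_targeting])
  rows_of <- split(seq_len(nrow(profiles)), profiles$Metadata_gene)
  res <- lapply(genes, function(g) {
    rows <- rows_of[[g]]
    if (length(rows) < 2) return(tibble(gene = g, M = length(rows), mAP = NA_real_))
    rs <- map_score(m[rows, , drop = FALSE], ctl)
    tibble(gene = g, M = rs$M, mAP = rs$mAP)
  })
  bind_rows(res)
}
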