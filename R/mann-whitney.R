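# Vectorized two-sided Mann-Whitney U tests, one per feature column.
#
# Policy (matching the hit-calling contract): the exact null distribution is
# used when the smaller group has at most `exact_limit` observations and the
# feature has no ties; otherwise the tie-corrected normal approximation with
# continuity correction is used. The exact U distribution is computed once
# per (n1, n2) pair by a Gaussian-binomial dynamic program and cached, so
# thousands of small-vs-large comparisons (e.g. 4 guides vs 601 controls)
# stay fast.

the_mw_cache <- new.env(parent = emptyenv())

# P(U <= u), u = 0..n1*n2, under the exact Mann-Whitney null.
# Counts c(u; n1, n2) satisfy c(u, m, n) = c(u - n, m - 1, n) + c(u, m, n - 1):
# iterate n upward holding an (n1+1) x (U+1) table.
mw_exact_cdf <- function(n1, n2) {
  key <- paste(n1, n2, sep = "_")
  hit <- the_mw_cache[[key]]
  if (!is.null(hit)) return(hit)
  U <- n1 * n2
  C <- matrix(0, nrow = n1 + 1, ncol = U + 1)
  C[1, 1] <- 1 # m = 0: only u = 0
  if (n1 >= 1) C[2:(n1 + 1), 1] <- 1 # n = 0 start: all mass at u = 0
  if (n2 >= 1) {
    for (nn in seq_len(n2)) {
      for (m in seq_len(n1)) {
        shifted <- c(rep(0, min(nn, U + 1)), C[m, seq_len(max(0, U + 1 - nn))])
        C[m + 1, ] <- C[m + 1, ] + shifted
      }
    }
  }
  probs <- C[n1 + 1, ] / sum(C[n1 + 1, ])
  cdf <- cumsum(probs)
  the_mw_cache[[key]] <- cdf
  cdf
}

# Two-sided exact p from the cached CDF, mirroring stats::wilcox.test:
# double the smaller tail (U counted inclusively on the observed side).
mw_exact_p <- function(u, n1, n2) {
  cdf <- mw_exact_cdf(n1, n2)
  mid <- n1 * n2 / 2
  lower <- cdf[u + 1]
  upper <- 1 - ifelse(u >= 1, cdf[u], 0)
  p <- ifelse(u > mid, 2 * upper, 2 * lower)
  pmin(p, 1)
}

# X: n1 x p matrix (one group), Y: n2 x p matrix (other group).
# Returns a numeric vector of two-sided p-values, one per column.
mw_pvalues_matrix <- function(X, Y, exact_limit = 8L) {
  n1 <- nrow(X); n2 <- nrow(Y)
  if (n1 < 1 || n2 < 1) abort("both groups need at least one observation")
  p <- ncol(X)
  if (ncol(Y) != p) abort("feature mismatch between the two groups")
  n <- n1 + n2
  use_exact_size <- min(n1, n2) <= exact_limit

  u_stat <- numeric(p)
  tie_term <- numeric(p)
  has_ties <- logical(p)
  for (j in seq_len(p)) {
    v <- c(X[, j], Y[, j])
    r <- rank(v)
    u_stat[j] <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    if (anyDuplicated(v)) {
      has_ties[j] <- TRUE
      nt <- rle(sort(v))$lengths
      nt <- nt[nt > 1]
      tie_term[j] <- sum(nt^3 - nt)
    }
  }

  out <- numeric(p)
  exact_cols <- use_exact_size & !has_ties
  if (any(exact_cols)) {
    out[exact_cols] <- mw_exact_p(u_stat[exact_cols], n1, n2)
  }
  if (any(!exact_cols)) {
    idx <- which(!exact_cols)
    z <- u_stat[idx] - n1 * n2 / 2
    sigma <- sqrt((n1 * n2 / 12) * ((n + 1) - tie_term[idx] / (n * (n - 1))))
    z <- (z - sign(z) * 0.5) / sigma
    pp <- 2 * pmin(pnorm(z), pnorm(z, lower.tail = FALSE))
    out[idx] <- pmin(pp, 1)
  }
  out
}

# Fast path for many small gene groups tested against one fixed control
# set: per feature, U comes from binary searches against pre-sorted control
# values instead of re-ranking the pooled sample. Features with ties fall
# back to the general tie-corrected path.
mw_pvalues_vs_sorted <- function(X, sortedY, exact_limit = 8L) {
  n1 <- nrow(X); n2 <- nrow(sortedY); p <- ncol(X); n <- n1 + n2
  u <- numeric(p)
  tie <- logical(p)
  for (j in seq_len(p)) {
    x <- X[, j]
    ys <- sortedY[, j]
    a <- findInterval(x, ys)                   # #{y <= x_i}
    b <- findInterval(x, ys, left.open = TRUE) # #{y <  x_i}
    u[j] <- sum(b) + 0.5 * sum(a - b)
    # cross ties, ties within the gene units, or ties among the controls
    # (the last matter for the approximation's variance correction)
    tie[j] <- any(a != b) || anyDuplicated(x) > 0 || any(ys[-1] == ys[-n2])
  }
  out <- numeric(p)
  clean <- !tie
  if (any(clean)) {
    if (min(n1, n2) <= exact_limit) {
      out[clean] <- mw_exact_p(u[clean], n1, n2)
    } else {
      z <- u[clean] - n1 * n2 / 2
      sigma <- sqrt((n1 * n2 / 12) * (n + 1))
      z <- (z - sign(z) * 0.5) / sigma
      out[clean] <- pmin(2 * pmin(pnorm(z), pnorm(z, lower.tail = FALSE)), 1)
    }
  }
  if (any(tie)) {
    idx <- which(tie)
    out[idx] <- mw_pvalues_matrix(X[, idx, drop = FALSE],
                                  sortedY[, idx, drop = FALSE],
                                  exact_limit = exact_limit)
  }
  out
}

#' Per-feature Mann-Whitney p-values for one gene versus controls
#'
#' Compares, feature by feature, the profile values of the guide units
#' targeting one gene with the nontargeting control units, using the
#' two-sided Mann-Whitney U test. The exact null distribution is used when
#' the smaller group has at most 8 units and the feature has no ties; the
#' tie-corrected normal approximation (with continuity correction)
#' otherwise.
#'
#' @param gene_units profile rows (data frame) for one gene's guides.
#' @param control_units profile rows for the nontargeting control guides;
#'   must carry exactly the same feature columns.
#' @return tibble with columns `feature` and `p`.
#' @examples
#' g <- tibble::tibble(f = c(1, 2, 3))
#' ctl <- tibble::tibble(f = c(4, 5, 6))
#' feature_pvalues(g, ctl)$p # exact two-sided p = 0.1
#' @export
feature_pvalues <- function(gene_units, control_units) {
  fg <- feature_cols(gene_units)
  fc <- feature_cols(control_units)
  if (!identical(fg, fc)) abort("feature mismatch between gene and control units")
  if (nrow(gene_units) < 2) abort("need at least 2 gene units")
  if (nrow(control_units) < 1) abort("need at least 1 control unit")
  X <- as.matrix(gene_units[, fg, drop = FALSE])
  Y <- as.matrix(control_units[, fc, drop = FALSE])
  tibble(feature = fg, p = mw_pvalues_matrix(X, Y))
}
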