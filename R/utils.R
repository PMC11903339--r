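# Internal helpers shared across modules.

# Metadata columns follow the image-based profiling convention: every
# non-feature column is prefixed "Metadata_".
metadata_cols <- function(x) grep("^Metadata_", names(x), value = TRUE)

feature_cols <- function(x) setdiff(names(x), metadata_cols(x))

feature_matrix <- function(x) {
  fc <- feature_cols(x)
  m <- as.matrix(x[, fc, drop = FALSE])
  if (!is.numeric(m)) abort("feature columns must be numeric")
  m
}

#' Cosine similarity between a vector and the rows of a matrix
#'
#' @param x numeric vector.
#' @param m numeric matrix with `length(x)` columns (or a vector).
#' @return numeric vector of cosine similarities.
#' @keywords internal
cosine_similarity <- function(x, m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  nx <- sqrt(sum(x^2))
  nm <- sqrt(rowSums(m^2))
  if (nx == 0 || any(nm == 0)) abort("cosine similarity undefined for zero-norm profile")
  as.numeric(m %*% x) / (nm * nx)
}

check_fraction <- function(x, name, closed_left = TRUE, closed_right = TRUE) {
  lo_ok <- if (closed_left) x >= 0 else x > 0
  hi_ok <- if (closed_right) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || !lo_ok || !hi_ok) {
    abort(sprintf("`%s` must be a fraction in %s0, 1%s, got %s",
                  name, if (closed_left) "[" else "(",
                  if (closed_right) "]" else ")", format(x)))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be an integer count >= %d", name, min))
  }
  invisible(as.integer(x))
}

# use data.table semantics inside [.data.table without attaching data.table
.datatable.aware <- TRUE
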