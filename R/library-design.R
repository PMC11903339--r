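#' Levenshtein edit distance
#'
#' Standard edit distance (substitutions, insertions and deletions all cost
#' 1), computed by `utils::adist()`. Symmetric and satisfies the triangle
#' inequality. Barcode libraries whose 12-base prefixes are pairwise at
#' distance >= 2 support single-error detection during in situ sequencing.
#'
#' @param a,b character vectors (recycled against each other elementwise).
#' @return integer vector of distances.
#' @examples
#' levenshtein("ACGT", "AGGT") # 1
#' levenshtein("ACGT", "CGTA") # 2
#' @export
levenshtein <- function(a, b) {
  d <- utils::adist(a, b)
  if (length(a) == length(b) || length(a) == 1 || length(b) == 1) {
    # elementwise (with recycling) rather than the full cross matrix
    n <- max(length(a), length(b))
    ai <- rep_len(seq_along(a), n)
    bi <- rep_len(seq_along(b), n)
    return(as.integer(d[cbind(ai, bi)]))
  }
  d
}

#' Design a barcode library under deconvolution and error-detection constraints
#'
#' Greedy first-fit selection from a candidate pool (in seeded-shuffled
#' order): a candidate is accepted if the Levenshtein distance between its
#' first `prefix_len_detect` bases and those of every previously accepted
#' barcode is at least `min_distance` (which also forces distinct
#' `prefix_len_unique`-base prefixes), and if accepting it keeps the
#' per-position base composition of the accepted set within the configured
#' band (checked softly: only the upper bound, only for bases the candidate
#' contributes to, and only once at least 25 barcodes are accepted).
#'
#' @param pool character vector of candidate barcodes, uniform length >=
#'   `prefix_len_detect`.
#' @param n_select number of barcodes to select.
#' @param genes optional gene labels for the selected barcodes.
#' @param prefix_len_detect prefix length over which the pairwise distance
#'   constraint is enforced (default 12, the number of sequencing cycles).
#' @param prefix_len_unique prefix length within which all barcodes must be
#'   distinct (default 11, complete library deconvolution depth).
#' @param min_distance minimum pairwise prefix Levenshtein distance
#'   (default 2, single-error detection).
#' @param composition_band allowed per-position base-frequency band.
#' @param seed optional seed for the pool shuffle; `NULL` keeps pool order.
#' @return a `barcode_library`: tibble (`barcode`, `gene`, `targeting`)
#'   with the constraint parameters as attributes. If the pool is exhausted
#'   first, an error of class `morphoscreen_pool_exhausted` is signalled
#'   whose `n_selected` field reports how many barcodes were accepted.
#' @export
design_library <- function(pool, n_select, genes = NULL,
                           prefix_len_detect = 12L, prefix_len_unique = 11L,
                           min_distance = 2L, composition_band = c(0.15, 0.40),
                           seed = NULL) {
  check_count(n_select, "n_select")
  lens <- unique(nchar(pool))
  if (length(lens) != 1) abort("candidate barcodes must have uniform length")
  if (lens < prefix_len_detect) {
    abort(sprintf("barcode length %d below prefix_len_detect = %d", lens, prefix_len_detect))
  }
  if (n_select > length(pool)) abort("n_select exceeds pool size")
  if (!is.null(seed)) {
    set.seed(seed)
    pool <- sample(pool)
  }
  bases <- c("A", "C", "G", "T")
  prefixes <- substr(pool, 1L, prefix_len_detect)
  accepted <- integer(0)
  counts <- matrix(0L, nrow = 4, ncol = lens, dimnames = list(bases, NULL))
  base_mat <- function(bc) {
    s <- strsplit(bc, "", fixed = TRUE)[[1]]
    matrix(as.integer(outer(bases, s, "==")), nrow = 4)
  }
  for (i in seq_along(pool)) {
    if (length(accepted) >= n_select) break
    if (length(accepted) > 0) {
      d <- utils::adist(prefixes[i], prefixes[accepted])
      if (min(d) < min_distance) next
      if (anyDuplicated(c(substr(pool[i], 1, prefix_len_unique),
                          substr(pool[accepted], 1, prefix_len_unique)))) next
    }
    inc <- base_mat(pool[i])
    if (length(accepted) >= 25) {
      # soft upper-band rule: skip a candidate only where it would push a
      # base it contributes to above the band (bases it does not touch are
      # diluted by accepting, so this cannot deadlock)
      freq <- (counts + inc) / (length(accepted) + 1)
      if (any(freq > composition_band[2] & inc == 1L)) next
    }
    counts <- counts + inc
    accepted <- c(accepted, i)
  }
  if (length(accepted) < n_select) {
    abort(
      sprintf("candidate pool exhausted: selected %d of %d requested barcodes",
              length(accepted), n_select),
      class = "morphoscreen_pool_exhausted",
      n_selected = length(accepted)
    )
  }
  bc <- pool[accepted]
  if (is.null(genes)) genes <- sprintf("G%04d", seq_along(bc))
  out <- tibble(barcode = bc, gene = genes, targeting = TRUE)
  attr(out, "prefix_len_detect") <- as.integer(prefix_len_detect)
  attr(out, "prefix_len_unique") <- as.integer(prefix_len_unique)
  attr(out, "min_distance") <- as.integer(min_distance)
  class(out) <- unique(c("barcode_library", class(out)))
  out
}

#' Verify a barcode library's distance and composition guarantees
#'
#' Exhaustively recomputes all pairwise Levenshtein distances over the
#' detection prefixes, finds the smallest prefix length at which all
#' barcodes are pairwise distinct, and tabulates the per-position base
#' composition over the full barcode length.
#'
#' @param lib a `barcode_library`, or any data frame with a `barcode`
#'   column.
#' @param prefix_len_detect detection prefix length (default: the library's
#'   attribute, else 12).
#' @return a `library_report`: list with `n_barcodes`,
#'   `min_pairwise_levenshtein` (over detection prefixes),
#'   `min_unique_prefix_len` and `per_position_base_fractions` (4 x L).
#' @export
verify_library <- function(lib, prefix_len_detect = NULL) {
  bc <- if (is.data.frame(lib)) lib$barcode else lib
  if (length(bc) == 0) abort("empty library")
  lens <- unique(nchar(bc))
  if (length(lens) != 1) abort("mixed barcode lengths")
  if (is.null(prefix_len_detect)) {
    prefix_len_detect <- attr(lib, "prefix_len_detect") %||% 12L
  }
  L <- lens
  prefixes <- substr(bc, 1, prefix_len_detect)
  min_d <- if (length(bc) > 1) {
    dm <- utils::adist(prefixes)
    min(dm[upper.tri(dm)])
  } else NA_integer_
  min_unique <- NA_integer_
  for (k in seq_len(L)) {
    if (!anyDuplicated(substr(bc, 1, k))) { min_unique <- k; break }
  }
  if (length(bc) == 1) min_unique <- 1L
  chars <- do.call(rbind, strsplit(bc, "", fixed = TRUE))
  comp <- sapply(seq_len(L), function(j) {
    tab <- table(factor(chars[, j], levels = c("A", "C", "G", "T")))
    as.numeric(tab) / length(bc)
  })
  rownames(comp) <- c("A", "C", "G", "T")
  structure(list(
    n_barcodes = length(bc),
    barcode_length = L,
    prefix_len_detect = as.integer(prefix_len_detect),
    min_pairwise_levenshtein = min_d,
    min_unique_prefix_len = min_unique,
    per_position_base_fractions = comp
  ), class = "library_report")
}

#' @export
print.library_report <- function(x, ...) {
  cat("<library_report>\n")
  cat(sprintf("  %d barcodes of length %d\n", x$n_barcodes, x$barcode_length))
  cat(sprintf("  min pairwise Levenshtein over %d-base prefixes: %s\n",
              x$prefix_len_detect, format(x$min_pairwise_levenshtein)))
  cat(sprintf("  smallest all-distinct prefix length: %s\n",
              format(x$min_unique_prefix_len)))
  invisible(x)
}

#' @export
glance.library_report <- function(x, ...) {
  tibble(n_barcodes = x$n_barcodes,
         min_pairwise_levenshtein = x$min_pairwise_levenshtein,
         min_unique_prefix_len = x$min_unique_prefix_len)
}

#' @export
tidy.library_report <- function(x, ...) {
  comp <- x$per_position_base_fractions
  tidyr::pivot_longer(
    mutate(as_tibble(t(comp)), position = seq_len(ncol(comp))),
    cols = all_of(rownames(comp)), names_to = "base", values_to = "fraction"
  )
}

#' Decode reads against a barcode library (error detection, no correction)
#'
#' A read is assigned if and only if its first `prefix_len_detect` bases
#' exactly match a library barcode's prefix; anything else is rejected
#' (there is no nearest-neighbour rescue). With a library of minimum prefix
#' distance >= 2, a read corrupted by a single substitution can never be
#' silently assigned to the wrong barcode.
#'
#' @param read a single read sequence.
#' @param reads a character vector of reads.
#' @param lib a `barcode_library`.
#' @return `decode_read()`: one-row tibble (`read`, `assigned_barcode`,
#'   `status` in `exact`/`rejected`); `decode_reads()` is the vectorised
#'   version.
#' @export
decode_read <- function(read, lib) {
  if (length(read) != 1) abort("`read` must be a single string; see decode_reads()")
  decode_reads(read, lib)
}

#' @rdname decode_read
#' @export
decode_reads <- function(reads, lib) {
  plen <- attr(lib, "prefix_len_detect") %||% 12L
  if (any(nchar(reads) < plen)) {
    abort(sprintf("read(s) shorter than the %d-base detection prefix", plen))
  }
  lib_prefix <- substr(lib$barcode, 1, plen)
  idx <- match(substr(reads, 1, plen), lib_prefix)
  tibble(
    read = reads,
    assigned_barcode = ifelse(is.na(idx), NA_character_, lib$barcode[idx]),
    status = ifelse(is.na(idx), "rejected", "exact")
  )
}

#' Simulate sequencing reads from a library with substitution errors
#'
#' Draws reads uniformly from the library's barcodes and corrupts each base
#' independently with probability `error_rate` (substituting one of the
#' other three bases). The expected fraction of reads decodable exactly is
#' `(1 - error_rate)^prefix_len_detect`.
#'
#' @param lib a `barcode_library`.
#' @param n number of reads.
#' @param error_rate per-base substitution probability.
#' @param seed optional seed.
#' @return tibble (`read`, `true_barcode`).
#' @export
simulate_reads <- function(lib, n, error_rate = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  src <- sample(lib$barcode, n, replace = TRUE)
  L <- nchar(src[1])
  chars <- matrix(unlist(strsplit(src, "", fixed = TRUE)), nrow = n, byrow = TRUE)
  err <- matrix(runif(n * L) < error_rate, nrow = n)
  if (any(err)) {
    idx <- which(err)
    cur <- chars[idx]
    bases <- c("A", "C", "G", "T")
    sub <- vapply(cur, function(b) sample(setdiff(bases, b), 1), character(1))
    chars[idx] <- sub
  }
  tibble(read = apply(chars, 1, paste, collapse = ""), true_barcode = src)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
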