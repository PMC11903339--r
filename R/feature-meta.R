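#' Parse CellProfiler-style feature names
#'
#' Feature names follow the `Object_Class_Params_Channel` convention used by
#' CellProfiler measurement tables, e.g. `"Cells_Granularity_1_WGA"` or
#' `"Cells_Correlation_Pearson_DNA_Mito"`. `Correlation` features carry
#' exactly two channel labels, `AreaShape` and `Neighbors` features none,
#' all other channel-linked classes exactly one.
#'
#' @param name a single feature name (underscore-delimited).
#' @param names character vector of feature names.
#' @param channels character vector of valid channel labels used to
#'   recognise the trailing channel tokens.
#' @return `parse_feature_name()` returns a one-row tibble; vectorised
#'   `parse_feature_names()` returns one row per name. Columns: `feature`,
#'   `object`, `feature_class`, `params` (list of token vectors),
#'   `channel1`, `channel2` (NA where absent).
#' @examples
#' parse_feature_name("Cells_Granularity_1_WGA")
#' parse_feature_name("Nuclei_AreaShape_Area")
#' @export
parse_feature_name <- function(name, channels = c("DNA", "ER", "Actin", "Mito", "WGA")) {
  if (!is.character(name) || length(name) != 1) abort("`name` must be a single string")
  parse_feature_names(name, channels)
}

#' @rdname parse_feature_name
#' @export
parse_feature_names <- function(names, channels = c("DNA", "ER", "Actin", "Mito", "WGA")) {
  objects <- c("Cells", "Cytoplasm", "Nuclei", "Image")
  classes <- c("AreaShape", "Correlation", "Granularity", "Intensity",
               "Neighbors", "RadialDistribution", "Texture", "Location")
  channel_free <- c("AreaShape", "Neighbors")

  parse_one <- function(nm) {
    tok <- strsplit(nm, "_", fixed = TRUE)[[1]]
    if (length(tok) < 2) abort(sprintf("malformed feature name '%s': need at least Object_Class", nm))
    if (!tok[1] %in% objects) {
      abort(sprintf("malformed feature name '%s': unknown object token '%s'", nm, tok[1]))
    }
    if (!tok[2] %in% classes) {
      abort(sprintf("malformed feature name '%s': unknown feature-class token '%s'", nm, tok[2]))
    }
    obj <- tok[1]; cls <- tok[2]; rest <- tok[-(1:2)]
    # channels are trailing tokens drawn from the channel set
    n_ch <- 0L
    while (n_ch < length(rest) && rest[length(rest) - n_ch] %in% channels) n_ch <- n_ch + 1L
    n_ch <- min(n_ch, 2L)
    if (cls %in% channel_free) n_ch <- 0L
    if (cls == "Correlation" && n_ch != 2L) {
      abort(sprintf("malformed feature name '%s': Correlation features need exactly 2 channel tokens", nm))
    }
    if (!cls %in% c(channel_free, "Correlation")) n_ch <- min(n_ch, 1L)
    chs <- if (n_ch > 0) rest[(length(rest) - n_ch + 1L):length(rest)] else character(0)
    params <- if (n_ch > 0) rest[seq_len(length(rest) - n_ch)] else rest
    list(object = obj, feature_class = cls, params = params,
         channel1 = if (n_ch >= 1) chs[1] else NA_character_,
         channel2 = if (n_ch >= 2) chs[2] else NA_character_)
  }

  parsed <- lapply(names, parse_one)
  out <- tibble(
    feature = names,
    object = map_chr(parsed, "object"),
    feature_class = map_chr(parsed, "feature_class"),
    params = map(parsed, "params"),
    channel1 = map_chr(parsed, "channel1"),
    channel2 = map_chr(parsed, "channel2")
  )
  attr(out, "channels") <- channels
  out
}

# Channel-linked compartment feature classes: the subset of classes used to
# define per-compartment scores (texture, intensity, correlation, radial
# distribution and granularity measures of that channel).
compartment_classes <- c("Texture", "Intensity", "Correlation",
                         "RadialDistribution", "Granularity")

# Logical matrix (features x channels): does a feature belong to a channel's
# compartment subset? Correlation features belong to both of their channels.
channel_membership <- function(meta, channels = attr(meta, "channels")) {
  if (is.null(channels)) channels <- c("DNA", "ER", "Actin", "Mito", "WGA")
  m <- sapply(channels, function(ch) {
    meta$feature_class %in% compartment_classes &
      (!is.na(meta$channel1) & meta$channel1 == ch |
         !is.na(meta$channel2) & meta$channel2 == ch)
  })
  m <- matrix(m, nrow = nrow(meta), dimnames = list(meta$feature, channels))
  m
}
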