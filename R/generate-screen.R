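#' Generate a synthetic optical pooled screen
#'
#' Simulates a single-cell morphological feature table with the statistical
#' structure the downstream analysis assumes: per-guide cell counts drawn
#' from an overdispersed negative binomial, additive per-plate offsets,
#' block-correlated feature noise within each channel, planted effect
#' vectors for hit genes concentrated in one compartment, co-functional
#' modules whose members share an effect direction (a configurable fraction
#' sign-flipped), Bernoulli guide activity emulating incomplete Cas9
#' editing, and compositional granularity features that sum to a fixed
#' per-channel total in every cell.
#'
#' @param config a [screen_config()].
#' @return An object of class `screen_dataset`: a list with elements
#'   * `cells`: tibble, one row per cell (`Metadata_plate`, `Metadata_well`,
#'     `Metadata_guide`, `Metadata_gene`, `Metadata_targeting` plus one
#'     column per feature);
#'   * `library`: tibble (`guide`, `barcode`, `gene`, `targeting`, `active`);
#'   * `truth`: tibble of per-gene planted truth (`gene`, `is_hit`,
#'     `module`, `primary_channel`, `spectrum_shift`, `effect_mag`, `tpm`);
#'   * `effects`: numeric matrix (gene x feature) of planted effect vectors
#'     (granularity entries are in logit space);
#'   * `feature_meta`: parsed feature metadata (see [parse_feature_names()]);
#'   * `config`: the generating configuration.
#' @examples
#' scr <- generate_screen(screen_config(
#'   n_genes = 20, n_nontargeting = 10, cells_per_guide_mean = 20,
#'   n_plates = 2, seed = 1
#' ))
#' nrow(scr$library)
#' @export
generate_screen <- function(config) {
  if (!inherits(config, "screen_config")) abort("`config` must be a screen_config")
  set.seed(config$seed)

  meta <- build_feature_set(config)
  feats <- meta$feature
  p <- length(feats)
  channels <- config$channels
  gran <- meta$feature_class == "Granularity"
  gran_by_channel <- lapply(channels, function(ch) which(gran & meta$channel1 == ch))
  names(gran_by_channel) <- channels
  n_gran_sizes <- config$features_per_channel_by_class[["Granularity"]]

  ## gene universe, nulls and planted hits ------------------------------
  width <- max(4L, nchar(as.character(config$n_genes)))
  genes <- sprintf(paste0("G%0", width, "d"), seq_len(config$n_genes))
  n_zero <- round(config$frac_zero_tpm * config$n_genes)
  zero_tpm <- sort(sample(genes, n_zero))
  expressed <- setdiff(genes, zero_tpm)
  n_hits <- min(round(config$frac_hit_genes * config$n_genes), length(expressed))
  hit_genes <- sort(sample(expressed, n_hits))

  ## co-functional modules and effect vectors ---------------------------
  modules <- assign_modules(hit_genes)
  effects <- matrix(0, nrow = config$n_genes, ncol = p,
                    dimnames = list(genes, feats))
  truth_module <- setNames(rep(NA_character_, config$n_genes), genes)
  truth_channel <- setNames(rep(NA_character_, config$n_genes), genes)
  truth_shift <- setNames(rep(FALSE, config$n_genes), genes)
  memb <- channel_membership(meta, channels)

  spectrum_module <- if (config$spectrum_shift_module && length(modules) > 0) 1L else 0L
  for (mi in seq_along(modules)) {
    members <- modules[[mi]]
    is_spectrum <- mi == spectrum_module
    primary <- if (is_spectrum) "WGA" else channels[(mi - 1L) %% length(channels) + 1L]
    d <- module_direction(p, memb[, primary], config$compartment_specificity,
                          is_spectrum, gran_by_channel[[primary]], n_gran_sizes)
    signs <- rep(1, length(members))
    if (!is_spectrum && length(members) > 1) {
      n_flip <- floor(config$anticorrelated_frac * length(members))
      if (n_flip > 0) signs[sample(length(members), n_flip)] <- -1
    }
    for (k in seq_along(members)) {
      g <- members[k]
      jitter <- rnorm(p) * 0.15 / sqrt(p)
      u <- d + jitter
      u <- u / sqrt(sum(u^2))
      mag <- config$effect_size * rlnorm(1, 0, 0.3)
      effects[g, ] <- signs[k] * u * mag * sqrt(p)
      truth_module[g] <- sprintf("module_%02d", mi)
      truth_channel[g] <- primary
      truth_shift[g] <- is_spectrum
    }
  }

  ## optional flat cutting effect on every targeting gene ---------------
  if (config$cutting_effect > 0) {
    cut_dir <- rnorm(p)
    cut_dir <- cut_dir / sqrt(sum(cut_dir^2))
    cut_vec <- cut_dir * config$cutting_effect * sqrt(p)
    # every targeting gene (the matrix rows), including zero-TPM nulls
    effects <- sweep(effects, 2, cut_vec, "+")
  }

  ## guide library ------------------------------------------------------
  n_t_guides <- config$n_genes * config$guides_per_gene
  n_guides <- n_t_guides + config$n_nontargeting
  lib <- tibble(
    guide = c(paste0(rep(genes, each = config$guides_per_gene), "_g",
                     rep(seq_len(config$guides_per_gene), config$n_genes)),
              sprintf("NT_%03d", seq_len(config$n_nontargeting))),
    barcode = random_barcode_pool(n_guides, length = 20L),
    gene = c(rep(genes, each = config$guides_per_gene),
             rep("nontargeting", config$n_nontargeting)),
    targeting = rep(c(TRUE, FALSE), c(n_t_guides, config$n_nontargeting))
  )
  lib$active <- lib$targeting & (runif(n_guides) < config$guide_activity_prob)

  ## cells per guide and plate assignment -------------------------------
  n_cells <- rnbinom(n_guides, size = config$cells_per_guide_dispersion,
                     mu = config$cells_per_guide_mean)
  if (any(n_cells == 0)) {
    warn(sprintf("%d of %d guides drew 0 cells; kept in library with 0 rows",
                 sum(n_cells == 0), n_guides))
  }
  plate_of <- function(n) sample.int(config$n_plates, n, replace = TRUE)
  cell_guide <- rep.int(seq_len(n_guides), n_cells)
  cell_plate <- plate_of(length(cell_guide))

  ## per-plate offsets (also applied to granularity logits) -------------
  plate_offsets <- matrix(rnorm(config$n_plates * p, sd = config$plate_effect_sd),
                          nrow = config$n_plates, ncol = p)

  gauss_idx <- which(!gran)
  blocks <- noise_blocks(meta, channels)
  base_logits <- seq(1.5, -1.5, length.out = n_gran_sizes)
  gene_idx_of_guide <- match(lib$gene, genes) # NA for nontargeting

  plate_tables <- vector("list", config$n_plates)
  for (pl in seq_len(config$n_plates)) {
    rows <- which(cell_plate == pl)
    gi <- cell_guide[rows]
    n <- length(rows)
    X <- matrix(0, nrow = n, ncol = p, dimnames = list(NULL, feats))
    if (n > 0) {
      # block-correlated gaussian noise for non-granularity features
      Z <- matrix(rnorm(n * length(gauss_idx)), nrow = n)
      colnames(Z) <- feats[gauss_idx]
      rho <- config$noise_correlation
      for (b in blocks) {
        cols <- match(feats[b], colnames(Z))
        cols <- cols[!is.na(cols)]
        if (length(cols) > 1 && rho > 0) {
          common <- rnorm(n)
          Z[, cols] <- sqrt(1 - rho) * Z[, cols] + sqrt(rho) * common
        }
      }
      X[, gauss_idx] <- Z

      # planted effects for cells of active guides
      eff_row <- gene_idx_of_guide[gi]
      act <- lib$active[gi] & !is.na(eff_row)
      if (any(act)) {
        X[act, ] <- X[act, ] + effects[eff_row[act], , drop = FALSE]
      }

      # plate offset on every feature (logit scale for granularity)
      X <- sweep(X, 2, plate_offsets[pl, ], "+")

      # compositional granularity: per channel, total * softmax(logits)
      for (ch in channels) {
        idx <- gran_by_channel[[ch]]
        L <- X[, idx, drop = FALSE] +
          matrix(base_logits, nrow = n, ncol = length(idx), byrow = TRUE) +
          matrix(rnorm(n * length(idx), sd = 0.5), nrow = n)
        rmax <- L[, 1]
        for (j in seq_along(idx)[-1]) rmax <- pmax(rmax, L[, j])
        E <- exp(L - rmax)
        X[, idx] <- config$granularity_total * E / rowSums(E)
      }
    }
    plate_tables[[pl]] <- bind_cols(
      tibble(
        Metadata_plate = sprintf("P%02d", pl),
        Metadata_well = sprintf("W%d", sample.int(6L, n, replace = TRUE)),
        Metadata_guide = lib$guide[gi],
        Metadata_gene = lib$gene[gi],
        Metadata_targeting = lib$targeting[gi]
      ),
      as_tibble(X)
    )
  }
  cells <- bind_rows(plate_tables)

  ## expression ---------------------------------------------------------
  tpm <- setNames(rlnorm(config$n_genes, meanlog = 3, sdlog = 1.5), genes)
  tpm[zero_tpm] <- 0

  truth <- tibble(
    gene = genes,
    is_hit = genes %in% hit_genes,
    module = unname(truth_module),
    primary_channel = unname(truth_channel),
    spectrum_shift = unname(truth_shift),
    effect_mag = sqrt(rowSums(effects^2)) / sqrt(p),
    tpm = unname(tpm)
  )

  structure(list(cells = cells, library = lib, truth = truth,
                 effects = effects, feature_meta = meta, config = config),
            class = "screen_dataset")
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat("<screen_dataset>\n")
  cat(sprintf("  %s cells, %d guides (%d nontargeting), %d genes, %d features\n",
              format(nrow(x$cells), big.mark = ","), nrow(x$library),
              sum(!x$library$targeting), nrow(x$truth), nrow(x$feature_meta)))
  cat(sprintf("  %d hit genes planted, %d zero-TPM null genes\n",
              sum(x$truth$is_hit), sum(x$truth$tpm == 0)))
  invisible(x)
}

# Partition hit genes into co-functional modules of size 2-6 (remainder
# becomes singletons). Order of `hit_genes` is already randomised upstream
# only through sampling; keep deterministic given the RNG state.
assign_modules <- function(hit_genes) {
  if (length(hit_genes) == 0) return(list())
  pool <- sample(hit_genes)
  modules <- list()
  while (length(pool) > 0) {
    size <- min(length(pool), sample(2:6, 1))
    modules[[length(modules) + 1L]] <- pool[seq_len(size)]
    pool <- pool[-seq_len(size)]
  }
  modules
}

# A module's shared effect direction (unit norm): `spec` of the squared mass
# on the primary channel's compartment features, the rest elsewhere. The
# designated spectrum-shift module instead concentrates 70% of its mass on
# a down-at-size-1 / up-at-larger-sizes pattern over the primary channel's
# granularity logits.
module_direction <- function(p, primary_mask, spec, is_spectrum, gran_idx, n_sizes) {
  z <- rnorm(p)
  if (is_spectrum) {
    pattern <- c(-1, rep(1 / (n_sizes - 1), n_sizes - 1))
    pattern <- pattern / sqrt(sum(pattern^2))
    rest <- setdiff(seq_len(p), gran_idx)
    z[gran_idx] <- pattern * sqrt(0.7)
    z[rest] <- z[rest] * sqrt(0.3 / sum(z[rest]^2))
  } else {
    inm <- which(primary_mask)
    out <- which(!primary_mask)
    z[inm] <- z[inm] * sqrt(spec / sum(z[inm]^2))
    z[out] <- z[out] * sqrt((1 - spec) / sum(z[out]^2))
  }
  z
}

# Noise blocks: per channel the channel-linked non-granularity features
# (correlation features sit in their first channel's block), plus one block
# for channel-free features.
noise_blocks <- function(meta, channels) {
  blocks <- lapply(channels, function(ch) {
    which(meta$feature_class != "Granularity" &
            !is.na(meta$channel1) & meta$channel1 == ch)
  })
  free <- which(is.na(meta$channel1))
  c(blocks, list(free))
}

#' Random DNA barcode pool
#'
#' Uniform random distinct DNA barcodes, e.g. as a candidate pool for
#' [design_library()].
#'
#' @param n number of barcodes.
#' @param length barcode length in bases.
#' @return character vector of `n` distinct barcodes over A/C/G/T.
#' @examples
#' set.seed(1)
#' random_barcode_pool(3, length = 12)
#' @export
random_barcode_pool <- function(n, length = 20L) {
  check_count(n, "n")
  check_count(length, "length")
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    new <- vapply(seq_len(need * 1.05 + 1), function(i) {
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
    }, character(1))
    out <- unique(c(out, new))
  }
  out[seq_len(n)]
}
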