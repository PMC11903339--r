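#' Configuration for a synthetic optical pooled screen
#'
#' Collects the generative parameters for [generate_screen()]. Defaults
#' describe a desk-scale screen with the structure of a genome-wide optical
#' pooled CRISPR knockout screen read out by five-channel morphological
#' profiling: ~4 guides per gene, 601 nontargeting control guides, strongly
#' overdispersed cells-per-guide counts, a subset of unexpressed (zero-TPM)
#' genes providing an empirical null, planted compartment-concentrated
#' effects for hit genes, incomplete guide activity modelling Cas9
#' efficiency, additive plate effects, and compositional granularity
#' features.
#'
#' @param n_genes number of targeting genes.
#' @param guides_per_gene guides designed per gene.
#' @param n_nontargeting number of nontargeting control guides.
#' @param frac_zero_tpm fraction of genes with zero expression (TPM = 0);
#'   these genes carry no planted effect and serve as the empirical null for
#'   hit-calling FDR control.
#' @param n_plates number of plates cells are spread across.
#' @param cells_per_guide_mean negative-binomial mean of cells per guide.
#' @param cells_per_guide_dispersion negative-binomial size parameter; the
#'   per-guide count variance is `mu + mu^2/size`, so smaller values mean
#'   stronger overdispersion. The default 0.15 reproduces per-guide counts
#'   with mean 125 and standard deviation ~330.
#' @param channels ordered labels of the five phenotyping channels.
#' @param features_per_channel_by_class named integer vector giving, per
#'   channel, the number of features of each channel-linked feature class
#'   (`Intensity`, `Texture`, `Correlation`, `RadialDistribution`,
#'   `Granularity`).
#' @param effect_size root-mean-square per-feature magnitude (in units of
#'   the single-cell noise standard deviation) of a hit gene's planted
#'   effect vector.
#' @param frac_hit_genes fraction of genes with a planted (nonzero) effect.
#' @param compartment_specificity fraction of a hit gene's squared effect
#'   mass confined to the channel-linked features of its primary channel.
#' @param guide_activity_prob probability that a targeting guide is active
#'   (models Cas9 editing efficiency); inactive guides yield exactly the
#'   null cell distribution.
#' @param plate_effect_sd standard deviation of additive per-plate,
#'   per-feature offsets.
#' @param noise_correlation within-channel (block) correlation of the
#'   single-cell feature noise.
#' @param anticorrelated_frac fraction of the members of a planted
#'   co-functional module whose effect vector is sign-flipped (inhibitory
#'   members of a complex).
#' @param cutting_effect magnitude of an optional flat effect added to all
#'   targeting guides (including those against zero-TPM genes), emulating
#'   nonspecific morphological consequences of CRISPR cutting. Off (0) by
#'   default.
#' @param spectrum_shift_module if `TRUE`, one planted module shifts mass in
#'   the WGA granularity spectrum (down at size 1, up at larger sizes), the
#'   signature of lysosome-acidification perturbations.
#' @param granularity_total per-cell total to which each channel's
#'   granularity features sum (compositional constraint).
#' @param seed integer seed; all randomness in [generate_screen()] and
#'   [generate_annotations()] derives from it.
#' @return An object of class `screen_config` (a named list, validated).
#' @examples
#' cfg <- screen_config(n_genes = 50, n_nontargeting = 20, seed = 7)
#' cfg$n_genes
#' @export
screen_config <- function(n_genes = 200,
                          guides_per_gene = 4,
                          n_nontargeting = 601,
                          frac_zero_tpm = 0.25,
                          n_plates = 3,
                          cells_per_guide_mean = 125,
                          cells_per_guide_dispersion = 0.15,
                          channels = c("DNA", "ER", "Actin", "Mito", "WGA"),
                          features_per_channel_by_class = c(
                            Intensity = 3, Texture = 4, Correlation = 1,
                            RadialDistribution = 2, Granularity = 8
                          ),
                          effect_size = 0.5,
                          frac_hit_genes = 0.1,
                          compartment_specificity = 0.55,
                          guide_activity_prob = 0.9,
                          plate_effect_sd = 0.2,
                          noise_correlation = 0.3,
                          anticorrelated_frac = 0.10,
                          cutting_effect = 0,
                          spectrum_shift_module = TRUE,
                          granularity_total = 1,
                          seed = 1L) {
  check_count(n_genes, "n_genes")
  check_count(guides_per_gene, "guides_per_gene")
  check_count(n_nontargeting, "n_nontargeting")
  check_count(n_plates, "n_plates")
  check_count(cells_per_guide_mean, "cells_per_guide_mean")
  check_fraction(frac_zero_tpm, "frac_zero_tpm")
  check_fraction(frac_hit_genes, "frac_hit_genes")
  check_fraction(compartment_specificity, "compartment_specificity")
  check_fraction(guide_activity_prob, "guide_activity_prob")
  check_fraction(anticorrelated_frac, "anticorrelated_frac")
  check_fraction(noise_correlation, "noise_correlation")
  if (!is.numeric(cells_per_guide_dispersion) || cells_per_guide_dispersion <= 0) {
    abort("`cells_per_guide_dispersion` must be a positive real")
  }
  if (length(channels) != 5 || anyDuplicated(channels) || !is.character(channels)) {
    abort("`channels` must be exactly 5 distinct labels")
  }
  cls <- names(features_per_channel_by_class)
  allowed <- c("Intensity", "Texture", "Correlation", "RadialDistribution", "Granularity")
  if (is.null(cls) || !all(cls %in% allowed)) {
    abort(paste0("`features_per_channel_by_class` must be named with classes in: ",
                 paste(allowed, collapse = ", ")))
  }
  if (any(features_per_channel_by_class < 1)) abort("feature counts must be >= 1")
  if (effect_size < 0) abort("`effect_size` must be nonnegative")
  if (plate_effect_sd < 0) abort("`plate_effect_sd` must be nonnegative")
  if (cutting_effect < 0) abort("`cutting_effect` must be nonnegative")
  if (granularity_total <= 0) abort("`granularity_total` must be positive")
  seed <- check_count(seed, "seed", min = 0L)

  structure(list(
    n_genes = as.integer(n_genes),
    guides_per_gene = as.integer(guides_per_gene),
    n_nontargeting = as.integer(n_nontargeting),
    frac_zero_tpm = frac_zero_tpm,
    n_plates = as.integer(n_plates),
    cells_per_guide_mean = cells_per_guide_mean,
    cells_per_guide_dispersion = cells_per_guide_dispersion,
    channels = channels,
    features_per_channel_by_class = features_per_channel_by_class,
    effect_size = effect_size,
    frac_hit_genes = frac_hit_genes,
    compartment_specificity = compartment_specificity,
    guide_activity_prob = guide_activity_prob,
    plate_effect_sd = plate_effect_sd,
    noise_correlation = noise_correlation,
    anticorrelated_frac = anticorrelated_frac,
    cutting_effect = cutting_effect,
    spectrum_shift_module = isTRUE(spectrum_shift_module),
    granularity_total = granularity_total,
    seed = seed
  ), class = "screen_config")
}

#' @export
print.screen_config <- function(x, ...) {
  cat("<screen_config>\n")
  cat(sprintf("  %d genes x %d guides + %d nontargeting guides, %d plates\n",
              x$n_genes, x$guides_per_gene, x$n_nontargeting, x$n_plates))
  cat(sprintf("  cells/guide ~ NegBin(mean = %g, size = %g)\n",
              x$cells_per_guide_mean, x$cells_per_guide_dispersion))
  cat(sprintf("  hits: %.0f%% of genes, effect size %g, compartment specificity %g\n",
              100 * x$frac_hit_genes, x$effect_size, x$compartment_specificity))
  cat(sprintf("  zero-TPM nulls: %.0f%%; guide activity %g; seed %d\n",
              100 * x$frac_zero_tpm, x$guide_activity_prob, x$seed))
  invisible(x)
}

# Build the feature catalogue for a config: a tibble of feature names plus
# parsed metadata, following the Object_Class_Params_Channel convention.
build_feature_set <- function(config) {
  ch <- config$channels
  per <- config$features_per_channel_by_class
  param_pool <- list(
    Intensity = c("MeanIntensity", "IntegratedIntensity", "MaxIntensity",
                  "StdIntensity", "MinIntensity", "MedianIntensity"),
    Texture = c("Contrast", "Entropy", "Variance", "Correlation5",
                "SumAverage", "InfoMeas1"),
    RadialDistribution = c("FracAtD1", "FracAtD2", "FracAtD3", "FracAtD4",
                           "MeanFrac1", "MeanFrac2"),
    Correlation = c("Pearson", "Overlap", "K", "Manders", "RWC", "Costes")
  )
  names_out <- character(0)
  for (cl in names(per)) {
    k <- per[[cl]]
    if (cl == "Granularity") {
      for (c1 in ch) names_out <- c(names_out, sprintf("Cells_Granularity_%d_%s", seq_len(k), c1))
    } else if (cl == "Correlation") {
      if (k > length(param_pool$Correlation)) abort("too many Correlation features requested")
      # pair each channel with the next one (cyclically) per parameter token
      for (j in seq_len(k)) {
        for (i in seq_along(ch)) {
          c1 <- ch[i]; c2 <- ch[if (i == length(ch)) 1L else i + 1L]
          names_out <- c(names_out, sprintf("Cells_Correlation_%s_%s_%s", param_pool$Correlation[j], c1, c2))
        }
      }
    } else {
      if (k > length(param_pool[[cl]])) abort(sprintf("too many %s features requested", cl))
      for (c1 in ch) {
        names_out <- c(names_out, sprintf("Cells_%s_%s_%s", cl, param_pool[[cl]][seq_len(k)], c1))
      }
    }
  }
  # channel-free classes, fixed small set
  names_out <- c(names_out,
                 paste0("Cells_AreaShape_", c("Area", "Perimeter", "Eccentricity", "FormFactor")),
                 paste0("Nuclei_AreaShape_", c("Area", "Perimeter")),
                 paste0("Cells_Neighbors_", c("NumberOfNeighbors_Adjacent", "PercentTouching_Adjacent")))
  parse_feature_names(names_out, channels = ch)
}
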