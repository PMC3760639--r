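# Synthetic-data generator: arrays with known compartment structure so every
# downstream stage can be scored against ground truth.

#' Simulation configuration
#'
#' Collects and validates all parameters of the synthetic study. Defaults
#' mirror the profiled experiment: three two-channel slides with four
#' replicate spots per probe (miRNA side) and two groups of four
#' single-channel arrays (mRNA side), on an array where most probes sit at
#' background in both compartments so the slide-median detectability limit
#' is a low bar, as on a real small-RNA array.
#'
#' @param n_probes number of probes on the array.
#' @param n_slides number of two-channel slides (biological replicates).
#' @param replicates_per_slide replicate spots per probe on each slide.
#' @param n_arrays_per_group single-channel arrays per compartment group.
#' @param fraction_exosome_only fraction of probes expressed only in exosomes.
#' @param fraction_cell_only fraction expressed only in donor cells.
#' @param fraction_neither fraction expressed in neither compartment
#'   (background probes filling out the array). The remainder after the three
#'   floors is shared (expressed in both).
#' @param fraction_enriched fraction of shared probes given a non-zero
#'   compartment enrichment; the rest are balanced (log2 ratio 0).
#' @param enrichment_sd standard deviation of the normal draw (truncated at
#'   +/-3) for enriched shared probes' true log2(exosome/cell) ratio. A free
#'   simulation parameter, not an experimentally derived one.
#' @param enrichment_values optional numeric vector; when supplied, enriched
#'   shared probes draw their true log2 ratio uniformly from these discrete
#'   values instead of the truncated normal (used for recovery scoring with
#'   known effect levels).
#' @param dye_bias_amplitude peak-to-trough scale (log2 units) of the smooth
#'   intensity-dependent dye bias injected between the Hy3 and Hy5 channels.
#' @param background_level mean additive background fluorescence.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   measurement noise (0 = noiseless).
#' @param base_intensity_meanlog,base_intensity_sdlog lognormal parameters of
#'   expressed probes' true abundance; draws are floored at
#'   `20 * background_level` so expressed probes sit firmly inside the
#'   detectable regime.
#' @param seed integer seed; all randomness in the generator flows from it.
#' @return a validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_probes = 100, seed = 7)
#' truth <- generate_truth(cfg)
#' table(truth$compartment_class)
sim_config <- function(n_probes = 850L,
                       n_slides = 3L,
                       replicates_per_slide = 4L,
                       n_arrays_per_group = 4L,
                       fraction_exosome_only = 0.03,
                       fraction_cell_only = 0.05,
                       fraction_neither = 0.80,
                       fraction_enriched = 0.60,
                       enrichment_sd = 2.5,
                       enrichment_values = NULL,
                       dye_bias_amplitude = 0.5,
                       background_level = 100,
                       noise_cv = 0.10,
                       base_intensity_meanlog = log(5000),
                       base_intensity_sdlog = 1,
                       seed = 1L) {
  cfg <- list(
    n_probes = as.integer(n_probes),
    n_slides = as.integer(n_slides),
    replicates_per_slide = as.integer(replicates_per_slide),
    n_arrays_per_group = as.integer(n_arrays_per_group),
    fraction_exosome_only = fraction_exosome_only,
    fraction_cell_only = fraction_cell_only,
    fraction_neither = fraction_neither,
    fraction_enriched = fraction_enriched,
    enrichment_sd = enrichment_sd,
    enrichment_values = enrichment_values,
    dye_bias_amplitude = dye_bias_amplitude,
    background_level = background_level,
    noise_cv = noise_cv,
    base_intensity_meanlog = base_intensity_meanlog,
    base_intensity_sdlog = base_intensity_sdlog,
    seed = as.integer(seed)
  )
  for (f in c("fraction_exosome_only", "fraction_cell_only", "fraction_neither",
              "fraction_enriched")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop_config("'", f, "' must be a single value in [0, 1]")
    }
  }
  if (cfg$fraction_exosome_only + cfg$fraction_cell_only + cfg$fraction_neither > 1 + 1e-12) {
    stop_config("'fraction_exosome_only' + 'fraction_cell_only' + ",
                "'fraction_neither' must not exceed 1")
  }
  if (cfg$n_probes < 0L) stop_config("'n_probes' must be non-negative")
  for (f in c("n_slides", "replicates_per_slide", "n_arrays_per_group")) {
    if (cfg[[f]] < 1L) stop_config("'", f, "' must be a positive integer")
  }
  for (f in c("enrichment_sd", "background_level")) {
    if (cfg[[f]] < 0) stop_config("'", f, "' must be non-negative")
  }
  if (cfg$noise_cv < 0) stop_config("'noise_cv' must be non-negative")
  class(cfg) <- "sim_config"
  cfg
}

truth_columns <- c("probe_id", "compartment_class", "true_log2fc",
                   "base_intensity", "exo_abundance", "cell_abundance")

empty_truth <- function() {
  data.frame(
    probe_id = character(), compartment_class = character(),
    true_log2fc = numeric(), base_intensity = numeric(),
    exo_abundance = numeric(), cell_abundance = numeric(),
    stringsAsFactors = FALSE
  )
}

#' Generate a ground-truth table of probe compartment classes
#'
#' Assigns each probe a compartment class (`exosome_only`, `cell_only`,
#' `shared`, `neither`), a true abundance in each compartment, and the implied
#' true log2(exosome/cell) ratio. Class counts are `floor(n_probes * fraction)`
#' for the exosome-only, cell-only and neither classes; the remainder is
#' shared. Compartment-restricted probes are not hard zeros on the silent
#' side: their abundance there is drawn well below background, so detection
#' rules — not the simulator — decide set membership downstream.
#'
#' @param config a [sim_config()].
#' @return a data.frame with columns `probe_id`, `compartment_class`,
#'   `true_log2fc`, `base_intensity` (geometric mean of the two compartment
#'   abundances), `exo_abundance`, `cell_abundance`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_probes
  if (n == 0L) return(empty_truth())

  n_exo <- floor(n * config$fraction_exosome_only)
  n_cell <- floor(n * config$fraction_cell_only)
  n_bg <- floor(n * config$fraction_neither)
  n_shared <- n - n_exo - n_cell - n_bg
  cls <- rep(c("exosome_only", "cell_only", "neither", "shared"),
             c(n_exo, n_cell, n_bg, n_shared))

  with_rng(config$seed, {
    bright <- pmax(
      stats::rlnorm(n, config$base_intensity_meanlog, config$base_intensity_sdlog),
      20 * config$background_level
    )
    # silent-side abundances: below background, never exactly zero
    dark_exo <- pmax(config$background_level, 1e-8) * stats::runif(n, 0.02, 0.30)
    dark_cell <- pmax(config$background_level, 1e-8) * stats::runif(n, 0.02, 0.30)
    enriched <- stats::runif(n) < config$fraction_enriched
    fc <- if (is.null(config$enrichment_values)) {
      pmin(pmax(stats::rnorm(n, 0, config$enrichment_sd), -3), 3)
    } else {
      sample(config$enrichment_values, n, replace = TRUE)
    }
    fc[!enriched] <- 0

    exo_ab <- numeric(n)
    cell_ab <- numeric(n)
    i <- cls == "shared"
    exo_ab[i] <- bright[i] * 2^(fc[i] / 2)
    cell_ab[i] <- bright[i] * 2^(-fc[i] / 2)
    i <- cls == "exosome_only"
    exo_ab[i] <- bright[i]
    cell_ab[i] <- dark_cell[i]
    i <- cls == "cell_only"
    exo_ab[i] <- dark_exo[i]
    cell_ab[i] <- bright[i]
    i <- cls == "neither"
    exo_ab[i] <- dark_exo[i]
    cell_ab[i] <- dark_cell[i]

    data.frame(
      probe_id = sprintf("probe_%05d", seq_len(n)),
      compartment_class = cls,
      true_log2fc = log2(exo_ab / cell_ab),
      base_intensity = sqrt(exo_ab * cell_ab),
      exo_abundance = exo_ab,
      cell_abundance = cell_ab,
      stringsAsFactors = FALSE
    )
  })
}

# Smooth intensity-dependent dye bias, in log2 units, as a low-order
# polynomial of the probe's true mean log2 intensity rescaled to [-1, 1].
# Split half-and-half between the channels so A is untouched and M gains
# exactly the bias — the situation global lowess normalization corrects.
dye_bias_log2 <- function(a_true, amplitude) {
  if (amplitude == 0 || length(a_true) == 0L) return(rep(0, length(a_true)))
  rng <- range(a_true)
  u <- if (diff(rng) == 0) rep(0, length(a_true)) else {
    2 * (a_true - rng[1]) / diff(rng) - 1
  }
  amplitude * (0.5 * u + (u^2 - 1 / 3))
}

#' Simulate a two-channel slide set from a truth table
#'
#' Emulates quantified two-channel array output: for every probe, slide and
#' replicate spot, each channel's foreground is the compartment abundance
#' times a smooth intensity-dependent dye-bias factor times multiplicative
#' lognormal noise, plus an additive background draw; an independently drawn
#' spot background is emitted alongside. Hy3 carries the exosome sample and
#' Hy5 the donor-cell sample.
#'
#' @param truth a truth table from [generate_truth()] (or hand-built with the
#'   same columns).
#' @param config a [sim_config()].
#' @return a `slide_set` data.frame with columns `probe_id`, `slide`,
#'   `replicate`, `hy3_fg`, `hy3_bg`, `hy5_fg`, `hy5_bg`.
#' @export
simulate_two_channel_slides <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(truth) == 0L) return(empty_slide_set())

  a_true <- 0.5 * log2(truth$exo_abundance * truth$cell_abundance)
  bias <- dye_bias_log2(a_true, config$dye_bias_amplitude)
  hy3_mean <- truth$exo_abundance * 2^(bias / 2)
  hy5_mean <- truth$cell_abundance * 2^(-bias / 2)

  np <- nrow(truth)
  grid <- expand.grid(
    replicate = seq_len(config$replicates_per_slide),
    probe = seq_len(np),
    slide = seq_len(config$n_slides),
    KEEP.OUT.ATTRS = FALSE
  )
  nspot <- nrow(grid)
  bg <- config$background_level
  cv <- config$noise_cv

  with_rng(config$seed + 1L, {
    out <- data.frame(
      probe_id = truth$probe_id[grid$probe],
      slide = grid$slide,
      replicate = grid$replicate,
      hy3_fg = hy3_mean[grid$probe] * rlnorm_cv(nspot, cv) + bg * rlnorm_cv(nspot, cv),
      hy3_bg = bg * rlnorm_cv(nspot, cv),
      hy5_fg = hy5_mean[grid$probe] * rlnorm_cv(nspot, cv) + bg * rlnorm_cv(nspot, cv),
      hy5_bg = bg * rlnorm_cv(nspot, cv),
      stringsAsFactors = FALSE
    )
    as_slide_set(out)
  })
}

#' Simulate a single-channel expression study from a truth table
#'
#' Builds two groups of arrays (exosome, cell), each sample measuring the
#' probe's abundance in that compartment with multiplicative lognormal noise
#' plus an additive background draw. Detection calls follow the stated rule on
#' the background-corrected intensity (the noisy abundance component):
#' `P` if it exceeds 3x the nominal background, `A` if at or below background,
#' `M` otherwise. Ground-truth per-group presence is attached for recovery
#' scoring.
#'
#' @param truth a truth table from [generate_truth()].
#' @param config a [sim_config()].
#' @return an `expression_study` list (`signals`, `calls`, `groups`) with a
#'   `truth_present` attribute: list of the probe ids truly expressed in each
#'   group's compartment.
#' @export
simulate_expression_study <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  samples <- c(sprintf("exosome_%d", seq_len(config$n_arrays_per_group)),
               sprintf("cell_%d", seq_len(config$n_arrays_per_group)))
  groups <- data.frame(
    sample = samples,
    group = rep(c("exosome", "cell"), each = config$n_arrays_per_group),
    stringsAsFactors = FALSE
  )
  np <- nrow(truth)
  if (np == 0L) {
    m <- matrix(numeric(0), nrow = 0, ncol = length(samples),
                dimnames = list(NULL, samples))
    cl <- matrix(character(0), nrow = 0, ncol = length(samples),
                 dimnames = list(NULL, samples))
    st <- expression_study(m, cl, groups)
    attr(st, "truth_present") <- list(exosome = character(), cell = character())
    return(st)
  }

  ab <- cbind(
    matrix(truth$exo_abundance, np, config$n_arrays_per_group),
    matrix(truth$cell_abundance, np, config$n_arrays_per_group)
  )
  bg <- config$background_level
  cv <- config$noise_cv
  with_rng(config$seed + 2L, {
    core <- ab * matrix(rlnorm_cv(length(ab), cv), np)
    signals <- core + bg * matrix(rlnorm_cv(length(ab), cv), np)
    calls <- matrix("M", np, ncol(ab))
    calls[core > 3 * bg] <- "P"
    calls[core <= bg] <- "A"
    dimnames(signals) <- dimnames(calls) <- list(truth$probe_id, samples)
    st <- expression_study(signals, calls, groups)
    attr(st, "truth_present") <- list(
      exosome = truth$probe_id[truth$compartment_class %in% c("exosome_only", "shared")],
      cell = truth$probe_id[truth$compartment_class %in% c("cell_only", "shared")]
    )
    st
  })
}
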