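#' Default element panel
#'
#' Fifteen isotope channels routinely profiled along single hair strands,
#' ordered so that the elements reported to carry case-attenuated periodic
#' dynamics (zinc, copper, lithium) come first and are therefore present in
#' any truncated panel.
#'
#' @return Character vector of element labels.
#' @export
element_panel <- function() {
  c("Zn", "Cu", "Li", "Mg", "Ca", "Fe", "Mn", "Sr",
    "Pb", "Al", "Ba", "Co", "Ni", "Cr", "Sn")
}

#' Cohort generator configuration
#'
#' Parameters of the synthetic cohort: subjects with binary diagnosis, sex,
#' age and study site, and one strand per subject carrying quasi-periodic
#' (circadian-like) elemental dynamics on a slowly drifting baseline, with
#' multiplicative lognormal measurement noise and per-site multiplicative
#' batch effects. In cases, the sinusoidal amplitude of the perturbed
#' elements is multiplied by `1 - effect_size`, so the case signature is an
#' attenuation of periodic dynamics rather than a concentration shift.
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param case_fraction Fraction of cases, strictly inside (0, 1). The cohort
#'   contains exactly `round(case_fraction * n_subjects)` cases.
#' @param n_sites Number of study sites; batch labels coincide with sites.
#' @param points_per_strand Sampling points along each strand. A 10 mm scan
#'   yields over 650 points, i.e. roughly one point per 1.1 h of growth; the
#'   default keeps that resolution.
#' @param n_elements Panel size; the first `n_elements` of [element_panel()].
#' @param perturbed_elements Elements whose periodic amplitude is attenuated
#'   in cases. Must be a subset of the panel.
#' @param effect_size Attenuation in \[0, 1\]: 0 leaves cases identical in law
#'   to controls, 1 removes the periodic component entirely.
#' @param noise_sd Standard deviation of the multiplicative lognormal
#'   measurement noise on each channel (log scale).
#' @param batch_shift_sd Log-scale sd of the per-site, per-element
#'   multiplicative batch factor.
#' @param period_range Range (in samples) from which each element's dominant
#'   period is drawn. A 10 mm strand spans roughly one month of growth, so
#'   660 points put one sample every ~1.1 h and a circadian cycle at ~22
#'   samples; the default 18-26 covers circadian periods with subject and
#'   element variation.
#' @param amp_range Range of the relative amplitude of the periodic component
#'   in controls.
#' @param confound_sex_age If `TRUE`, cases are drawn preferentially male and
#'   slightly younger so covariate adjustment can be exercised under
#'   confounding; by default sex and age are independent of diagnosis.
#' @param seed Integer seed; a fixed seed yields a bit-identical cohort.
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 100, case_fraction = 0.5, n_sites = 3,
                          points_per_strand = 660, n_elements = 15,
                          perturbed_elements = c("Zn", "Cu", "Li"),
                          effect_size = 0, noise_sd = 0.01,
                          batch_shift_sd = 0.15, period_range = c(18, 26),
                          amp_range = c(0.3, 0.6),
                          confound_sex_age = FALSE, seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              case_fraction = case_fraction, n_sites = as.integer(n_sites),
              points_per_strand = as.integer(points_per_strand),
              n_elements = as.integer(n_elements),
              perturbed_elements = as.character(perturbed_elements),
              effect_size = effect_size, noise_sd = noise_sd,
              batch_shift_sd = batch_shift_sd, period_range = period_range,
              amp_range = amp_range, confound_sex_age = isTRUE(confound_sex_age),
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_subjects < 4L)
    stop("n_subjects must be at least 4")
  if (!is.finite(cfg$case_fraction) ||
      cfg$case_fraction <= 0 || cfg$case_fraction >= 1)
    stop("case_fraction must lie strictly inside (0, 1)")
  if (cfg$points_per_strand < 2L)
    stop("points_per_strand must be at least 2")
  if (cfg$points_per_strand < 650L)
    warning("points_per_strand below the 650-point single-strand floor; ",
            "embedding statistics may be unstable", call. = FALSE)
  if (cfg$n_elements < 1L || cfg$n_elements > length(element_panel()))
    stop("n_elements must be between 1 and ", length(element_panel()))
  panel <- element_panel()[seq_len(cfg$n_elements)]
  if (!all(cfg$perturbed_elements %in% panel))
    stop("perturbed_elements must be a subset of the element panel: ",
         paste(setdiff(cfg$perturbed_elements, panel), collapse = ", "))
  if (cfg$effect_size < 0 || cfg$effect_size > 1)
    stop("effect_size must lie in [0, 1]")
  if (cfg$noise_sd < 0 || cfg$batch_shift_sd < 0)
    stop("noise scales must be non-negative")
  if (cfg$n_sites < 1L) stop("n_sites must be positive")
  invisible(cfg)
}

#' Strand profile constructor
#'
#' @param subject_id Subject identifier.
#' @param channels Numeric matrix, one column per element (named), one row
#'   per sampling point; raw intensities, all non-negative.
#' @param sulfur Numeric vector of sulfur intensities, same length.
#' @param scan_length_mm Scanned path length in mm.
#' @param latent Optional list of latent generative parameters (kept so a
#'   replicate strand can share the subject's dynamics).
#'
#' @return An object of class `strand_profile`.
#' @export
strand_profile <- function(subject_id, channels, sulfur, scan_length_mm = 10,
                           latent = NULL) {
  channels <- as.matrix(channels)
  if (is.null(colnames(channels)))
    stop("channels must have element names as column names")
  if (length(sulfur) != nrow(channels))
    stop("sulfur series length differs from channel length")
  if (any(channels < 0, na.rm = TRUE))
    stop("negative intensity in channels of subject ", subject_id)
  if (any(sulfur < 0, na.rm = TRUE))
    stop("negative sulfur intensity for subject ", subject_id)
  structure(list(subject_id = as.character(subject_id),
                 points = seq_len(nrow(channels)) - 1L,
                 channels = channels, sulfur = as.numeric(sulfur),
                 scan_length_mm = scan_length_mm, latent = latent),
            class = "strand_profile")
}

# Age ranges (months) by site: a birth-cohort site sampled near 1 month, a
# twin registry sampled in adolescence, a specialist clinic in childhood.
site_age_range <- function(site) {
  ranges <- list(c(0.5, 3), c(96, 220), c(36, 160))
  ranges[[(site - 1L) %% length(ranges) + 1L]]
}

# Draw the latent generative parameters of one subject's strand.
draw_latent <- function(cfg, panel, diagnosis, batch_mult) {
  ne <- length(panel)
  attn <- ifelse(panel %in% cfg$perturbed_elements & diagnosis == "case",
                 1 - cfg$effect_size, 1)
  latent <- list(
    panel = panel,
    level = exp(runif(ne, log(50), log(5000))),
    amp = runif(ne, cfg$amp_range[1], cfg$amp_range[2]) * attn,
    period = runif(ne, cfg$period_range[1], cfg$period_range[2]),
    phase = runif(ne, 0, 2 * pi),
    phase2 = runif(ne, 0, 2 * pi),
    slow_period = runif(ne, 200, 400),
    slow_phase = runif(ne, 0, 2 * pi),
    slow_amp = runif(ne, 0.05, 0.12),
    drift = runif(ne, -0.05, 0.05),
    density_period = runif(1, 150, 300),
    density_phase = runif(1, 0, 2 * pi),
    sulfur_level = exp(runif(1, log(2e4), log(6e4))),
    sulfur_slow_amp = runif(1, 0.02, 0.06),
    sulfur_slow_period = runif(1, 200, 400),
    sulfur_slow_phase = runif(1, 0, 2 * pi),
    batch_mult = batch_mult,
    noise_sd = cfg$noise_sd)
  latent
}

# Render a strand from latent parameters; only the lognormal noise draws
# consume randomness, so a replicate with the same latent state shares the
# clean signal exactly.
render_strand <- function(subject_id, latent, n_points) {
  t <- seq_len(n_points) - 1L
  density <- 1 + 0.05 * sin(2 * pi * t / latent$density_period +
                              latent$density_phase)
  ne <- length(latent$panel)
  channels <- matrix(0, n_points, ne, dimnames = list(NULL, latent$panel))
  for (e in seq_len(ne)) {
    slow <- 1 + latent$slow_amp[e] *
      sin(2 * pi * t / latent$slow_period[e] + latent$slow_phase[e]) +
      latent$drift[e] * t / n_points
    periodic <- 1 +
      latent$amp[e] * sin(2 * pi * t / latent$period[e] + latent$phase[e]) +
      0.3 * latent$amp[e] * sin(4 * pi * t / latent$period[e] +
                                  latent$phase2[e])
    noise <- exp(rnorm(n_points, 0, latent$noise_sd))
    channels[, e] <- latent$level[e] * latent$batch_mult[e] * slow * density *
      periodic * noise
  }
  s_slow <- 1 + latent$sulfur_slow_amp *
    sin(2 * pi * t / latent$sulfur_slow_period + latent$sulfur_slow_phase)
  sulfur <- latent$sulfur_level * density * s_slow *
    exp(rnorm(n_points, 0, 0.4 * latent$noise_sd))
  strand_profile(subject_id, channels, sulfur, latent = latent)
}

#' Generate a synthetic cohort
#'
#' Draws subject metadata and one strand profile per subject under the model
#' described in [cohort_config()]. Deterministic under a fixed config seed.
#'
#' @param config A [cohort_config()].
#'
#' @return List with `subjects` (data.frame: subject_id, diagnosis, sex,
#'   age_months, site, batch) and `profiles` (named list of
#'   [strand_profile()] objects).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  panel <- element_panel()[seq_len(config$n_elements)]

  n_cases <- round(config$case_fraction * n)
  diagnosis <- sample(rep(c("case", "control"), c(n_cases, n - n_cases)))
  site <- sample(seq_len(config$n_sites), n, replace = TRUE)
  if (config$confound_sex_age) {
    p_male <- ifelse(diagnosis == "case", 0.8, 0.5)
  } else {
    p_male <- rep(0.5, n)
  }
  sex <- ifelse(runif(n) < p_male, "male", "female")
  age <- vapply(seq_len(n), function(i) {
    r <- site_age_range(site[i])
    a <- runif(1, r[1], r[2])
    if (config$confound_sex_age && diagnosis[i] == "case") a <- a * 0.9
    a
  }, numeric(1))

  # per-site, per-element multiplicative batch factors (log-normal)
  batch_mult <- matrix(exp(rnorm(config$n_sites * length(panel),
                                 0, config$batch_shift_sd)),
                       nrow = config$n_sites,
                       dimnames = list(NULL, panel))

  subjects <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    diagnosis = diagnosis, sex = sex, age_months = age,
    site = paste0("site", site), batch = paste0("B", site),
    stringsAsFactors = FALSE)

  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    latent <- draw_latent(config, panel, diagnosis[i], batch_mult[site[i], ])
    profiles[[i]] <- render_strand(subjects$subject_id[i], latent,
                                   config$points_per_strand)
  }
  names(profiles) <- subjects$subject_id
  list(subjects = subjects, profiles = profiles, config = config)
}

#' Generate a replicate strand for the same subject
#'
#' Returns a second strand that shares the subject's latent dynamical
#' parameters. Measurement noise is regenerated, and with
#' `replicate_noise_sd > 0` the per-element periodic amplitudes and baseline
#' levels are jittered multiplicatively (log-scale sd `replicate_noise_sd`),
#' emulating two hairs sampled from the same head at one time point.
#'
#' @param profile A [strand_profile()] carrying latent parameters.
#' @param replicate_noise_sd Log-scale sd of the between-strand jitter on
#'   amplitudes and levels; 0 means the latent signal is identical and only
#'   the noise draws differ.
#' @param seed Integer seed; the same seed reproduces the replicate exactly.
#'
#' @return A [strand_profile()] for the replicate strand.
#' @export
generate_replicate_pair <- function(profile, replicate_noise_sd = 0.01,
                                    seed = 1L) {
  if (is.null(profile$latent))
    stop("profile carries no latent parameters; cannot form a replicate")
  if (replicate_noise_sd < 0) stop("replicate_noise_sd must be >= 0")
  set.seed(as.integer(seed))
  latent <- profile$latent
  ne <- length(latent$panel)
  latent$amp <- latent$amp * exp(rnorm(ne, 0, replicate_noise_sd))
  latent$level <- latent$level * exp(rnorm(ne, 0, replicate_noise_sd))
  render_strand(profile$subject_id, latent, length(profile$sulfur))
}
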