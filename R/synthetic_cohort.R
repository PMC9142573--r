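#' Configuration for a synthetic STN-DBS cohort
#'
#' Describes the generative model the cohort simulator draws from: active
#' contacts are Gaussian clouds around a per-hemisphere STN-region centroid;
#' for each measure the clinical change score is a linear gradient along a
#' planted 3D direction plus Gaussian noise,
#' `delta = slope * <contact - centroid, direction> + N(0, noise_sd)`,
#' with optional subgroup-specific modulation for subjects carrying a
#' psychiatric-history flag. Defaults reproduce the study conditions of the
#' motivating cohort: n = 42 bilaterally implanted subjects with history
#' flags at 12/42 (depression), 15/42 (anxiety), 11/42 (visual
#' hallucinations) and 6/42 (impulse control behaviors), and a planted
#' inferiosuperior (z) gradient whose slope/noise give a theoretical
#' projection-outcome correlation of 0.7.
#'
#' Contact clouds are deliberately Gaussian rather than atlas-constrained:
#' the analysis consumes coordinates only, and group-space normalization in
#' real cohorts itself displaces contacts relative to atlas boundaries.
#' History flags are drawn independently of one another and of location.
#'
#' @param n_subjects Number of subjects (default 42).
#' @param centroids List with unit `left`/`right` 3-vectors, MNI mm. Defaults
#'   (+/-12, -13, -6) are conventional STN-region coordinates, not derived
#'   from any specific cohort.
#' @param covariances List with `left`/`right` 3x3 SPD matrices (mm^2)
#'   describing contact scatter; default isotropic with 1.5 mm SD.
#' @param planted_direction Unit 3-vector of the planted outcome gradient
#'   (normalized internally); default the z axis.
#' @param slope Clinical change units per mm along the direction (default
#'   4: combined with the default 1.5 mm contact spread and the r = 0.7
#'   noise calibration this gives a total change-score SD of ~8.6, in line
#'   with the roughly one-SD spread of T-scored change in DBS cohorts, and
#'   populates all three outcome classes under the +/-5 band).
#' @param noise_sd SD of the additive outcome noise; default calibrated via
#'   [noise_sd_for_r()] so the theoretical correlation is 0.7.
#' @param subgroup_fractions Named probabilities for the four history flags.
#' @param flag_sampling `"bernoulli"` (default): each subject's flags are
#'   independent Bernoulli draws, so subgroup sizes fluctuate binomially.
#'   `"exact"`: exactly `round(fraction * n)` subjects carry each flag
#'   (flags still independent across subjects), reproducing a cohort with
#'   fixed subgroup counts.
#' @param subgroup_effects List of modulations, each a list with `flag`
#'   (`"depression"`, `"anxiety"`, `"vh"`, `"icb"`), `direction`, `slope`,
#'   and `mode` (`"add"`: added to the base gradient for flagged subjects;
#'   `"replace"`: supplants it).
#' @param measures Measure ids to simulate (default: the full 18-measure
#'   battery).
#' @param pre_sd SD of baseline scores (default 10, the T-score SD; the same
#'   spread is used for the raw/index psychiatric scales so the +/-5
#'   unchanged band spans the same fraction of an SD on every scale).
#' @param bipolar_fraction Probability a lead is programmed bipolar
#'   (default 33/84, the observed lead-level rate).
#' @param class_band Half-width of the unchanged outcome band (default 5).
#' @param seed RNG seed used by [simulate_cohort()].
#' @return An `"stnlda_synth_config"` list.
#' @export
synthetic_config <- function(n_subjects = 42,
                             centroids = list(left = c(-12, -13, -6),
                                              right = c(12, -13, -6)),
                             covariances = list(left = diag(1.5^2, 3),
                                                right = diag(1.5^2, 3)),
                             planted_direction = c(0, 0, 1),
                             slope = 4,
                             noise_sd = NULL,
                             subgroup_fractions = c(depression = 12 / 42,
                                                    anxiety = 15 / 42,
                                                    vh = 11 / 42,
                                                    icb = 6 / 42),
                             subgroup_effects = list(),
                             flag_sampling = c("bernoulli", "exact"),
                             measures = measure_ids(),
                             pre_sd = 10,
                             bipolar_fraction = 33 / 84,
                             class_band = 5,
                             seed = 1L) {
  norm <- sqrt(sum(planted_direction^2))
  if (!is.finite(norm) || norm == 0) {
    abort("planted_direction must be a nonzero 3-vector",
          class = "stnlda_config_error")
  }
  planted_direction <- planted_direction / norm
  for (h in hemispheres) {
    sig <- covariances[[h]]
    if (is.null(sig) || !isTRUE(all.equal(sig, t(sig))) ||
        inherits(try(chol(sig), silent = TRUE), "try-error")) {
      abort(paste0(h, " covariance must be symmetric positive definite"),
            class = "stnlda_config_error")
    }
  }
  if (any(subgroup_fractions < 0 | subgroup_fractions > 1)) {
    abort("subgroup fractions must lie in [0, 1]",
          class = "stnlda_config_error")
  }
  if (is.null(noise_sd)) {
    noise_sd <- if (slope == 0) {
      # pure-noise cohorts: one class-band half-width per SD keeps all three
      # outcome classes populated
      5
    } else {
      noise_sd_for_r(slope,
                     sigma_along(covariances$left, planted_direction), 0.7)
    }
  }
  subgroup_effects <- lapply(subgroup_effects, function(eff) {
    eff$direction <- eff$direction / sqrt(sum(eff$direction^2))
    eff$mode <- match.arg(eff$mode %||% "add", c("add", "replace"))
    eff
  })
  flag_sampling <- match.arg(flag_sampling)
  structure(list(n_subjects = n_subjects, centroids = centroids,
                 covariances = covariances,
                 planted_direction = planted_direction, slope = slope,
                 noise_sd = noise_sd,
                 subgroup_fractions = subgroup_fractions,
                 subgroup_effects = subgroup_effects,
                 flag_sampling = flag_sampling, measures = measures,
                 pre_sd = pre_sd, bipolar_fraction = bipolar_fraction,
                 class_band = class_band, seed = as.integer(seed)),
            class = "stnlda_synth_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohort configuration matching the motivating study's conditions
#'
#' Convenience wrapper around [synthetic_config()] with its defaults: 42
#' subjects, history-flag fractions 12/42, 15/42, 11/42, 6/42, STN-region
#' centroids, and a planted z-axis gradient at theoretical r = 0.7.
#'
#' @param ... Overrides passed to [synthetic_config()].
#' @return An `"stnlda_synth_config"`.
#' @export
default_paper_like_config <- function(...) synthetic_config(...)

#' SD of contact positions along a direction
#'
#' @param covariance 3x3 covariance matrix (mm^2).
#' @param direction Unit 3-vector.
#' @return `sqrt(t(v) %*% Sigma %*% v)` in mm.
#' @export
sigma_along <- function(covariance, direction) {
  drop(sqrt(t(direction) %*% covariance %*% direction))
}

#' Theoretical projection-outcome correlation of the linear-Gaussian model
#'
#' With `delta = slope * s + noise`, `s ~ N(0, sigma_along^2)` the contact
#' offset along the planted direction and independent `noise ~
#' N(0, noise_sd^2)`, the population Pearson correlation between `s` and
#' `delta` is `slope * sigma_along / sqrt(slope^2 sigma_along^2 +
#' noise_sd^2)`.
#'
#' @param slope Gradient slope (change units per mm).
#' @param sigma_along SD of contact offsets along the direction (mm).
#' @param noise_sd Outcome noise SD.
#' @return Population correlation in (0, 1).
#' @export
theoretical_r <- function(slope, sigma_along, noise_sd) {
  s <- abs(slope) * sigma_along
  s / sqrt(s^2 + noise_sd^2)
}

#' Noise SD achieving a target theoretical correlation
#'
#' Inverts [theoretical_r()] for `noise_sd`.
#'
#' @inheritParams theoretical_r
#' @param r Target correlation in (0, 1).
#' @return Noise SD.
#' @export
noise_sd_for_r <- function(slope, sigma_along, r) {
  stopifnot(r > 0, r < 1)
  abs(slope) * sigma_along * sqrt(1 / r^2 - 1)
}

# conventional baseline means per scale: T scores centre at 50; the raw/index
# psychiatric scales at mid-range values typical of a presurgical PD cohort
baseline_mean <- function(measure_id, battery) {
  info <- battery[battery$measure_id == measure_id, ]
  switch(info$scale, T_score = 50,
         index = 45,
         raw = if (measure_id == "cesd") 15 else 30)
}

#' Simulate a synthetic STN-DBS cohort
#'
#' Draws a cohort from the generative model described by
#' [synthetic_config()]. For each subject, hemisphere and measure, the
#' clinical change score is the planted linear gradient along the configured
#' direction evaluated at that hemisphere's contact offset, plus independent
#' Gaussian noise; the baseline score is drawn around the scale's
#' conventional mean and the postoperative score is baseline plus the change
#' (sign-flipped for lower-is-better scales so the planted gradient is
#' always on the clinical-improvement scale). Scores are generated
#' independently per hemisphere, so each hemisphere's geometry-outcome
#' relationship can be recovered separately. Fully reproducible from
#' `config$seed`.
#'
#' @param config An `"stnlda_synth_config"`.
#' @param seed Optional override of `config$seed`.
#' @return An `"stnlda_cohort"` with generation metadata (seed, config hash).
#' @export
simulate_cohort <- function(config = synthetic_config(), seed = NULL) {
  stopifnot(inherits(config, "stnlda_synth_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  set.seed(config$seed)
  n <- config$n_subjects
  battery <- measure_battery()
  ids <- sprintf("S%03d", seq_len(n))

  flags <- lapply(config$subgroup_fractions, function(p) {
    if (identical(config$flag_sampling, "exact")) {
      idx <- sample.int(n, round(p * n))
      seq_len(n) %in% idx
    } else {
      stats::rbinom(n, 1L, p) == 1L
    }
  })
  contacts <- lapply(hemispheres, function(h) {
    MASS::mvrnorm(n, mu = config$centroids[[h]],
                  Sigma = config$covariances[[h]])
  })
  names(contacts) <- hemispheres
  modes <- lapply(hemispheres, function(h) {
    ifelse(stats::runif(n) < config$bipolar_fraction, "bipolar", "monopolar")
  })
  names(modes) <- hemispheres

  subjects <- tibble::tibble(
    subject_id = ids,
    history_depression = flags$depression,
    history_anxiety = flags$anxiety,
    history_vh = flags$vh,
    history_icb = flags$icb,
    left_x_mm = contacts$left[, 1], left_y_mm = contacts$left[, 2],
    left_z_mm = contacts$left[, 3], left_mode = modes$left,
    right_x_mm = contacts$right[, 1], right_y_mm = contacts$right[, 2],
    right_z_mm = contacts$right[, 3], right_mode = modes$right
  )

  # per-subject planted signal for one hemisphere: base gradient plus any
  # flag-specific modulation (additive or replacing)
  planted_signal <- function(offsets) {
    base <- config$slope * drop(offsets %*% config$planted_direction)
    eff_total <- base
    for (eff in config$subgroup_effects) {
      flagged <- flags[[eff$flag]]
      contrib <- eff$slope * drop(offsets %*% eff$direction)
      if (eff$mode == "replace") {
        eff_total[flagged] <- contrib[flagged]
      } else {
        eff_total[flagged] <- eff_total[flagged] + contrib[flagged]
      }
    }
    eff_total
  }

  m_ids <- config$measures
  nm <- length(m_ids)
  bmeans <- vapply(m_ids, baseline_mean, numeric(1), battery = battery)
  signs <- ifelse(battery$polarity[match(m_ids, battery$measure_id)] ==
                    "higher_is_better", 1, -1)
  rows <- lapply(hemispheres, function(h) {
    offsets <- sweep(contacts[[h]], 2L, config$centroids[[h]], "-")
    signal <- planted_signal(offsets)
    delta_clin <- matrix(stats::rnorm(n * nm, 0, config$noise_sd), n, nm) +
      signal
    pre <- matrix(stats::rnorm(n * nm, rep(bmeans, each = n),
                               config$pre_sd), n, nm)
    post <- pre + sweep(delta_clin, 2L, signs, "*")
    tibble::tibble(subject_id = rep(ids, nm), hemisphere = h,
                   measure_id = rep(m_ids, each = n),
                   pre = c(pre), post = c(post))
  })
  scores <- dplyr::bind_rows(rows)
  as_cohort(subjects, scores,
            schema = cohort_schema(band = config$class_band),
            metadata = list(seed = config$seed,
                            config_hash = rlang::hash(config),
                            generator = "stnlda::simulate_cohort"))
}

#' Simulate per-lead VTA summary rows for a cohort
#'
#' Generates volume-of-tissue-activated *summaries* (total mm^3 and
#' fractional overlap with the motor, associative and limbic STN subregions
#' plus the remainder outside the nucleus) -- no field modelling is involved.
#' Totals are log-normal around `total_mean`; fractions are Dirichlet with
#' the given mean composition. An optional planted shift moves overlap mass
#' from the outside compartment into the motor compartment for subjects
#' carrying a history flag, for power/calibration studies of the VTA
#' comparisons.
#'
#' @param cohort An `"stnlda_cohort"`.
#' @param total_mean Mean total VTA (mm^3, default 60).
#' @param total_cv Coefficient of variation of totals (default 0.4).
#' @param frac_means Mean composition (motor, associative, limbic, outside);
#'   must sum to 1.
#' @param concentration Dirichlet concentration (larger = tighter).
#' @param shift_flag Optional flag name for a planted composition shift.
#' @param shift_amount Mean fraction moved outside -> motor for flagged
#'   subjects.
#' @param seed RNG seed.
#' @return The cohort with a populated `vta` table.
#' @export
simulate_vta_summaries <- function(cohort, total_mean = 60, total_cv = 0.4,
                                   frac_means = c(motor = 0.35,
                                                  associative = 0.15,
                                                  limbic = 0.05,
                                                  outside = 0.45),
                                   concentration = 40,
                                   shift_flag = NULL, shift_amount = 0.15,
                                   seed = 1L) {
  stopifnot(inherits(cohort, "stnlda_cohort"),
            abs(sum(frac_means) - 1) < 1e-9)
  set.seed(seed)
  subj <- cohort$subjects
  n <- nrow(subj)
  rows <- lapply(hemispheres, function(h) {
    sdlog <- sqrt(log(1 + total_cv^2))
    total <- stats::rlnorm(n, log(total_mean) - sdlog^2 / 2, sdlog)
    alpha <- frac_means * concentration
    g <- matrix(stats::rgamma(n * 4L, shape = rep(alpha, each = n)), n, 4L)
    fr <- g / rowSums(g)
    colnames(fr) <- names(frac_means)
    if (!is.null(shift_flag)) {
      flagged <- subj[[paste0("history_", shift_flag)]]
      moved <- pmin(shift_amount, fr[flagged, "outside"])
      fr[flagged, "motor"] <- fr[flagged, "motor"] + moved
      fr[flagged, "outside"] <- fr[flagged, "outside"] - moved
    }
    tibble::tibble(subject_id = subj$subject_id, hemisphere = h,
                   total_vta_mm3 = total, frac_motor = fr[, "motor"],
                   frac_associative = fr[, "associative"],
                   frac_limbic = fr[, "limbic"],
                   frac_outside = fr[, "outside"])
  })
  cohort$vta <- dplyr::bind_rows(rows)
  cohort
}
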