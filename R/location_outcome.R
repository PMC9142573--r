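#' Benjamini-Hochberg adjustment with rejection flags
#'
#' Step-up false-discovery-rate control: with m ordered p-values, the
#' adjusted value of the i-th smallest is `min over j >= i of m * p_(j) / j`
#' capped at 1, and a test is rejected at level `alpha` exactly when its
#' adjusted value is <= `alpha` (equivalent to the classical largest-k
#' step-up rule). Computation is delegated to [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed; passed
#'   through).
#' @param alpha False discovery rate (default 0.10).
#' @return List with `q` (adjusted values) and `rejected` (logical).
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.5, 0.9))  # rejects the first two
bh_adjust <- function(p, alpha = 0.10) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    abort("p-values must lie in [0, 1]", class = "stnlda_value_error")
  }
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, rejected = !is.na(q) & q <= alpha)
}

#' Subgroup selector for stratified analyses
#'
#' @param flag `"none"` (whole cohort) or one of `"depression"`,
#'   `"anxiety"`, `"vh"`, `"icb"`.
#' @param condition `"with"` or `"without"` the history flag.
#' @param min_n Minimum subjects for a family to be fitted (default 11;
#'   smaller discriminant fits were found too unstable to trust).
#' @return A `"subgroup_spec"` list.
#' @export
subgroup_spec <- function(flag = c("none", "depression", "anxiety", "vh",
                                   "icb"),
                          condition = c("with", "without"), min_n = 11L) {
  flag <- match.arg(flag)
  condition <- match.arg(condition)
  if (min_n < 4L) {
    abort("min_n must be at least 4", class = "stnlda_config_error")
  }
  structure(list(flag = flag, condition = condition,
                 min_n = as.integer(min_n)),
            class = "subgroup_spec")
}

#' Restrict a cohort to a psychiatric-history subgroup
#'
#' @param cohort An `"stnlda_cohort"`.
#' @param subgroup A [subgroup_spec()].
#' @return The filtered cohort.
#' @export
subset_cohort <- function(cohort, subgroup) {
  stopifnot(inherits(cohort, "stnlda_cohort"),
            inherits(subgroup, "subgroup_spec"))
  if (subgroup$flag == "none") return(cohort)
  col <- paste0("history_", subgroup$flag)
  keep <- cohort$subjects[[col]]
  if (subgroup$condition == "without") keep <- !keep
  cohort$subjects <- cohort$subjects[keep, ]
  cohort$scores <- cohort$scores[cohort$scores$subject_id %in%
                                   cohort$subjects$subject_id, ]
  if (!is.null(cohort$vta)) {
    cohort$vta <- cohort$vta[cohort$vta$subject_id %in%
                               cohort$subjects$subject_id, ]
  }
  cohort
}

# one full pass of the per-test pipeline, returning only r (NA if the fit
# is degenerate); used by the permutation calibration
pipeline_r <- function(coords, delta, band) {
  cl <- assign_class(delta, band)
  f <- tryCatch(suppressWarnings(fit_lda(coords, cl)),
                stnlda_single_class_error = function(e) NULL,
                stnlda_degenerate_error = function(e) NULL)
  if (is.null(f)) return(NA_real_)
  stats::cor(f$projections, delta)
}

skipped_row <- function(measure_id, hemisphere, n, status) {
  # plain data.frame: this sits on the Monte-Carlo hot path
  data.frame(measure_id = measure_id, hemisphere = hemisphere,
             n = n, r = NA_real_, p = NA_real_, q = NA_real_,
             significant = FALSE, pct_variance = NA_real_,
             p_x = NA_real_, p_y = NA_real_, p_z = NA_real_,
             status = status)
}

#' Location-outcome analysis for one measure and hemisphere
#'
#' The core per-test pipeline: take that hemisphere's effective contact
#' coordinates and the measure's change scores (pairwise deletion of
#' subjects missing either), discretize change into the tri-class outcome,
#' fit the Fisher discriminant axis ([fit_lda()]), project all usable
#' contacts onto the oriented LDA1, and correlate the normalized projections
#' with the change scores (Pearson, two-sided p from the t transform with
#' n - 2 degrees of freedom).
#'
#' @param cohort An `"stnlda_cohort"`.
#' @param measure_id Measure to analyze.
#' @param hemisphere `"left"` or `"right"`.
#' @param band Unchanged-band half-width (default: cohort schema, 5).
#' @param mode Delta mode, `"polarity_adjusted"` or `"strict"`.
#' @param min_points Minimum usable points to attempt a fit (default 4).
#' @param p_method `"parametric"` (default): two-sided p from the t
#'   transform of r with n - 2 degrees of freedom, as in the original
#'   procedure. `"permutation"`: the whole pipeline (class assignment, LDA
#'   fit, projection, correlation) is refitted under `n_perm` random
#'   permutations of the change scores against the contact locations, and
#'   p = (1 + #\{|r_perm| >= |r_obs|\}) / (1 + n_valid). The parametric p
#'   is anticonservative because the discriminant axis is selected using
#'   class labels derived from the very change scores it is then correlated
#'   with; the permutation p is calibrated for that selection by
#'   construction.
#' @param n_perm Number of permutations when `p_method = "permutation"`.
#' @return List with `status` (`"ok"`, `"single-class"`, or
#'   `"insufficient-n"`), `row` (one-row result tibble with n, r, p,
#'   variance explained and axis proportions), and `fit` (the
#'   `"stnlda_axis"`, `NULL` when skipped).
#' @export
run_measure <- function(cohort, measure_id, hemisphere,
                        band = cohort$schema$band,
                        mode = cohort$schema$delta_mode, min_points = 4L,
                        p_method = c("parametric", "permutation"),
                        n_perm = 999L) {
  p_method <- match.arg(p_method)
  delta <- measure_delta(cohort, measure_id, hemisphere, mode)
  mask <- is.finite(delta)
  n_use <- sum(mask)
  if (n_use < min_points) {
    return(list(status = "insufficient-n",
                row = skipped_row(measure_id, hemisphere, n_use,
                                  "insufficient-n"),
                fit = NULL))
  }
  coords <- contact_matrix(cohort, hemisphere)[mask, , drop = FALSE]
  delta <- delta[mask]
  classes <- assign_class(delta, band)
  fit <- tryCatch(
    suppressWarnings(fit_lda(coords, classes)),
    stnlda_single_class_error = function(e) NULL,
    stnlda_degenerate_error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(status = "single-class",
                row = skipped_row(measure_id, hemisphere, n_use,
                                  "single-class"),
                fit = NULL))
  }
  ct <- stats::cor.test(fit$projections, delta, method = "pearson")
  p_val <- ct$p.value
  if (p_method == "permutation") {
    r_obs <- unname(ct$estimate)
    r_perm <- vapply(seq_len(n_perm), function(b) {
      pipeline_r(coords, sample(delta), band)
    }, numeric(1))
    r_perm <- r_perm[!is.na(r_perm)]
    p_val <- (1 + sum(abs(r_perm) >= abs(r_obs))) / (1 + length(r_perm))
  }
  ap <- fit$axis_proportions
  row <- data.frame(measure_id = measure_id, hemisphere = hemisphere,
                    n = n_use, r = unname(ct$estimate),
                    p = p_val, q = NA_real_, significant = FALSE,
                    pct_variance = fit$pct_variance,
                    p_x = ap[["p_x"]], p_y = ap[["p_y"]],
                    p_z = ap[["p_z"]], status = "ok")
  list(status = "ok", row = row, fit = fit)
}

#' Run the full measure x hemisphere family with FDR control
#'
#' Runs [run_measure()] for every requested measure in each hemisphere
#' (hemispheres are never pooled) within one subgroup, then applies the
#' Benjamini-Hochberg procedure at `alpha` across the family's non-skipped
#' tests. By default the family is all measure x hemisphere tests of the run
#' (up to 36); `family = "per_hemisphere"` corrects the two hemispheres
#' separately. A subgroup smaller than `min_n` subjects skips the whole
#' family with status `"below-min-n"`. Row order is deterministic
#' (battery order, then hemisphere).
#'
#' @param cohort An `"stnlda_cohort"`.
#' @param subgroup A [subgroup_spec()]; default the whole cohort.
#' @param measures Measure ids (default: all measures present in the
#'   cohort's scores, in battery order).
#' @param band,mode Passed to [run_measure()].
#' @param alpha False discovery rate (default 0.10).
#' @param family `"all"` or `"per_hemisphere"` BH family definition.
#' @param keep_fits Attach the per-test `"stnlda_axis"` objects as the
#'   `"fits"` attribute (default `FALSE`).
#' @param p_method,n_perm Passed to [run_measure()]; `"permutation"` gives
#'   selection-calibrated p-values at considerable cost.
#' @param perm_seed Single seed set before the family loop so permutation
#'   p-values are reproducible; recorded in the result attributes.
#' @return Tibble with one row per attempted measure x hemisphere:
#'   `measure_id`, `hemisphere`, `n`, `r`, `p`, `q`, `significant`,
#'   `pct_variance`, `p_x`, `p_y`, `p_z`, `status`; attributes `alpha`,
#'   `subgroup`, `n_subjects`.
#' @export
run_family <- function(cohort, subgroup = subgroup_spec("none"),
                       measures = NULL, band = cohort$schema$band,
                       mode = cohort$schema$delta_mode, alpha = 0.10,
                       family = c("all", "per_hemisphere"),
                       keep_fits = FALSE,
                       p_method = c("parametric", "permutation"),
                       n_perm = 999L, perm_seed = NULL) {
  family <- match.arg(family)
  p_method <- match.arg(p_method)
  if (!is.null(perm_seed)) set.seed(perm_seed)
  if (is.null(measures)) {
    measures <- intersect(cohort$schema$battery$measure_id,
                          unique(cohort$scores$measure_id))
  }
  if (length(measures) == 0L) {
    abort("empty measure list", class = "stnlda_config_error")
  }
  sub <- subset_cohort(cohort, subgroup)
  n_sub <- nrow(sub$subjects)
  grid <- expand.grid(hemisphere = hemispheres, measure_id = measures,
                      stringsAsFactors = FALSE)[, c("measure_id",
                                                    "hemisphere")]
  grid <- grid[order(match(grid$measure_id, measures), grid$hemisphere), ]

  if (n_sub < subgroup$min_n) {
    rows <- dplyr::bind_rows(Map(skipped_row, grid$measure_id,
                                 grid$hemisphere, n_sub, "below-min-n"))
    message("subgroup '", subgroup$flag, ":", subgroup$condition,
            "' has ", n_sub, " subjects (< min_n = ", subgroup$min_n,
            "); family skipped")
  } else {
    out <- Map(function(m, h) run_measure(sub, m, h, band, mode,
                                          p_method = p_method,
                                          n_perm = n_perm),
               grid$measure_id, grid$hemisphere)
    rows <- dplyr::bind_rows(lapply(out, `[[`, "row"))
    groups <- if (family == "all") rep("all", nrow(rows)) else rows$hemisphere
    for (g in unique(groups)) {
      sel <- groups == g & rows$status == "ok"
      if (any(sel)) {
        adj <- bh_adjust(rows$p[sel], alpha)
        rows$q[sel] <- adj$q
        rows$significant[sel] <- adj$rejected
      }
    }
    if (keep_fits) {
      fits <- lapply(out, `[[`, "fit")
      names(fits) <- paste(grid$measure_id, grid$hemisphere, sep = ".")
      attr(rows, "fits") <- fits
    }
  }
  rows <- tibble::as_tibble(rows)
  attr(rows, "alpha") <- alpha
  attr(rows, "subgroup") <- subgroup
  attr(rows, "n_subjects") <- n_sub
  attr(rows, "p_method") <- p_method
  attr(rows, "perm_seed") <- perm_seed
  rows
}

#' Summary statistics of the significant associations
#'
#' Over the significant rows of a [run_family()] table: the count, mean and
#' SD of |r| (correlation magnitudes), of the variance explained by LDA1,
#' and of each MNI axis proportion of the LDA1 vector.
#'
#' @param results A [run_family()] result table.
#' @return One-row tibble of summaries; `n_significant = 0` with NA
#'   summaries when nothing is significant.
#' @export
summarize_significant <- function(results) {
  sig <- results[results$significant %in% TRUE, ]
  msd <- function(x) c(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0)
  if (nrow(sig) == 0L) {
    return(tibble::tibble(n_significant = 0L, mean_abs_r = NA_real_,
                          sd_abs_r = NA_real_, mean_pct_variance = NA_real_,
                          sd_pct_variance = NA_real_, mean_p_x = NA_real_,
                          sd_p_x = NA_real_, mean_p_y = NA_real_,
                          sd_p_y = NA_real_, mean_p_z = NA_real_,
                          sd_p_z = NA_real_))
  }
  r <- msd(abs(sig$r)); v <- msd(sig$pct_variance)
  px <- msd(sig$p_x); py <- msd(sig$p_y); pz <- msd(sig$p_z)
  tibble::tibble(n_significant = nrow(sig),
                 mean_abs_r = r[[1]], sd_abs_r = r[[2]],
                 mean_pct_variance = v[[1]], sd_pct_variance = v[[2]],
                 mean_p_x = px[[1]], sd_p_x = px[[2]],
                 mean_p_y = py[[1]], sd_p_y = py[[2]],
                 mean_p_z = pz[[1]], sd_p_z = pz[[2]])
}

#' Stratified analyses with and without a psychiatric-history flag
#'
#' Splits the cohort by one history flag, repeats the full [run_family()]
#' analysis in each stratum (each guarded by `min_n`), and reports the
#' overlap of significant measure x hemisphere associations between the two
#' strata and the full cohort.
#'
#' @param cohort An `"stnlda_cohort"`.
#' @param flag `"depression"`, `"anxiety"`, `"vh"`, or `"icb"`.
#' @param ... Passed to [run_family()] (measures, band, alpha, ...).
#' @param min_n Minimum stratum size (default 11).
#' @param full Optional precomputed full-cohort [run_family()] table to
#'   avoid refitting it per flag.
#' @return List with `with`, `without`, `full` result tables and `overlap`
#'   (per measure x hemisphere significance in each).
#' @export
compare_subgroups <- function(cohort, flag, ..., min_n = 11L, full = NULL) {
  if (!flag %in% c("depression", "anxiety", "vh", "icb")) {
    abort(paste0("unknown history flag: ", flag),
          class = "stnlda_config_error")
  }
  res_with <- run_family(cohort, subgroup_spec(flag, "with", min_n), ...)
  res_without <- run_family(cohort, subgroup_spec(flag, "without", min_n),
                            ...)
  if (is.null(full)) {
    full <- run_family(cohort, subgroup_spec("none", min_n = min_n), ...)
  }
  overlap <- tibble::tibble(
    measure_id = full$measure_id, hemisphere = full$hemisphere,
    sig_full = full$significant,
    sig_with = res_with$significant[match(
      paste(full$measure_id, full$hemisphere),
      paste(res_with$measure_id, res_with$hemisphere))],
    sig_without = res_without$significant[match(
      paste(full$measure_id, full$hemisphere),
      paste(res_without$measure_id, res_without$hemisphere))]
  )
  overlap$shared_with_full <- overlap$sig_full &
    (overlap$sig_with | overlap$sig_without)
  list(with = res_with, without = res_without, full = full,
       overlap = overlap)
}
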