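# Shapiro-Wilk normality gate at 0.05. Returns NA when the test is not
# applicable (n < 3, constant data); callers treat NA as "not normal" so the
# rank-based fallback is used.
shapiro_gate_p <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L || length(x) > 5000L || stats::sd(x) == 0) {
    return(NA_real_)
  }
  stats::shapiro.test(x)$p.value
}

# Two-group continuous comparison with the logged decision trail: Shapiro on
# both groups (0.05); if both pass, an F test on variances (0.05) chooses
# pooled vs Welch t; otherwise Wilcoxon rank sum.
two_group_test <- function(x, y, gate_alpha = 0.05) {
  sh_x <- shapiro_gate_p(x)
  sh_y <- shapiro_gate_p(y)
  normal <- isTRUE(sh_x >= gate_alpha) && isTRUE(sh_y >= gate_alpha)
  var_p <- NA_real_
  if (normal) {
    var_p <- stats::var.test(x, y)$p.value
    equal_var <- var_p >= gate_alpha
    ht <- stats::t.test(x, y, var.equal = equal_var)
    test_used <- if (equal_var) "two_sample_t" else "welch_t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    test_used <- "wilcoxon_rank_sum"
  }
  list(test_used = test_used, statistic = unname(ht$statistic),
       p = ht$p.value, shapiro_p_x = sh_x, shapiro_p_y = sh_y, var_p = var_p)
}

#' Pre/post change test for one measure
#'
#' Tests whether postoperative scores differ from preoperative scores across
#' subjects: a paired t-test on the differences when they pass the
#' Shapiro-Wilk normality gate (0.05), otherwise the Wilcoxon signed-rank
#' test. Zero-variance differences make the test statistic undefined: the
#' result is flagged `degenerate`, with p = 1 by convention when the shift is
#' exactly zero and p reported as 0 (below any machine-representable
#' threshold) for an exact nonzero constant shift.
#'
#' @param pre,post Numeric score vectors (pairwise complete cases used;
#'   at least 3 required).
#' @return One-row tibble: `n`, `mean_change`, `sd_change`, `test_used`,
#'   `statistic`, `p`, `shapiro_p`, `degenerate`.
#' @export
paired_change_test <- function(pre, post) {
  ok <- is.finite(pre) & is.finite(post)
  pre <- pre[ok]; post <- post[ok]
  if (length(pre) < 3L) {
    abort("need at least 3 complete pre/post pairs",
          class = "stnlda_value_error")
  }
  d <- post - pre
  if (stats::sd(d) == 0) {
    return(tibble::tibble(n = length(d), mean_change = mean(d),
                          sd_change = 0, test_used = "paired_t",
                          statistic = NA_real_,
                          p = if (mean(d) == 0) 1 else 0,
                          shapiro_p = NA_real_, degenerate = TRUE))
  }
  sh <- shapiro_gate_p(d)
  if (isTRUE(sh >= 0.05)) {
    ht <- stats::t.test(d)
    test_used <- "paired_t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(d, exact = FALSE))
    test_used <- "wilcoxon_signed_rank"
  }
  tibble::tibble(n = length(d), mean_change = mean(d), sd_change = sd(d),
                 test_used = test_used, statistic = unname(ht$statistic),
                 p = ht$p.value, shapiro_p = sh, degenerate = FALSE)
}

#' Per-measure pre/post change table for a cohort
#'
#' Applies [paired_change_test()] to every measure (one hemisphere's score
#' rows; in a real cohort both hemispheres carry the same subject-level
#' scores). Change is reported in polarity-adjusted units when the schema
#' says so. Both uncorrected and BH-adjusted p-values are reported.
#'
#' @param cohort An `"stnlda_cohort"`.
#' @param hemisphere Which hemisphere's score rows to use (default left).
#' @param subgroup Optional [subgroup_spec()] restriction.
#' @param alpha FDR level for the adjusted column (default 0.10).
#' @return Tibble with one row per measure.
#' @export
cohort_change_table <- function(cohort, hemisphere = "left",
                                subgroup = subgroup_spec("none"),
                                alpha = 0.10) {
  sub <- subset_cohort(cohort, subgroup)
  measures <- intersect(sub$schema$battery$measure_id,
                        unique(sub$scores$measure_id))
  rows <- lapply(measures, function(m) {
    sc <- sub$scores[sub$scores$measure_id == m &
                       sub$scores$hemisphere == hemisphere, ]
    info <- measure_info(m, sub$schema$battery)
    flip <- sub$schema$delta_mode == "polarity_adjusted" &&
      info$polarity == "lower_is_better"
    pre <- sc$pre
    post <- if (flip) pre - (sc$post - sc$pre) else sc$post
    cbind(tibble::tibble(measure_id = m,
                         pre_mean = mean(pre, na.rm = TRUE),
                         pre_sd = sd(pre, na.rm = TRUE),
                         post_mean = mean(sc$post, na.rm = TRUE),
                         post_sd = sd(sc$post, na.rm = TRUE)),
          paired_change_test(pre, post))
  })
  out <- tibble::as_tibble(dplyr::bind_rows(rows))
  out$q <- bh_adjust(out$p, alpha)$q
  out
}

#' Change score adjusted for baseline symptom severity
#'
#' Regresses the change score on the mean-centred baseline score,
#' `delta = b0 + b1 * (baseline - mean(baseline)) + e`; centering makes the
#' intercept `b0` the baseline-adjusted mean change, whose two-sided p-value
#' tests whether change differs from zero after controlling for baseline
#' severity. A constant baseline carries no information and the model
#' reduces to a one-sample t-test on delta (noted in the result).
#'
#' @param delta Change scores.
#' @param baseline Baseline covariate scores (same length).
#' @return One-row tibble: `n`, `adjusted_mean_change` (b0), `p_change`,
#'   `baseline_slope` (b1), `p_slope`, `note`.
#' @export
baseline_adjusted_change <- function(delta, baseline) {
  ok <- is.finite(delta) & is.finite(baseline)
  delta <- delta[ok]; baseline <- baseline[ok]
  if (length(delta) < 4L) {
    abort("need at least 4 complete pairs", class = "stnlda_value_error")
  }
  if (stats::sd(baseline) == 0) {
    ht <- stats::t.test(delta)
    return(tibble::tibble(n = length(delta),
                          adjusted_mean_change = mean(delta),
                          p_change = ht$p.value,
                          baseline_slope = NA_real_, p_slope = NA_real_,
                          note = "constant baseline; one-sample t-test"))
  }
  bc <- baseline - mean(baseline)
  fit <- stats::lm(delta ~ bc)
  cf <- summary(fit)$coefficients
  tibble::tibble(n = length(delta), adjusted_mean_change = cf[1, 1],
                 p_change = cf[1, 4], baseline_slope = cf[2, 1],
                 p_slope = cf[2, 4], note = NA_character_)
}

#' Compare VTA summaries between history strata
#'
#' For each hemisphere and VTA variable (total volume and each subregion
#' overlap fraction), compares subjects with and without the given history
#' flag using the gated test-selection rule (Shapiro-Wilk, then F test
#' choosing pooled vs Welch t, else Wilcoxon rank sum); the decision trail
#' is carried in the output.
#'
#' @param cohort An `"stnlda_cohort"` with a populated `vta` table.
#' @param flag History flag name.
#' @return Tibble with one row per hemisphere x variable, including group
#'   means/SDs, the test used, its p-value and the gate p-values; rows get
#'   status `"empty-stratum"` when a stratum has no leads.
#' @export
vta_group_compare <- function(cohort, flag) {
  stopifnot(inherits(cohort, "stnlda_cohort"))
  if (is.null(cohort$vta)) {
    abort("cohort has no VTA summary table", class = "stnlda_config_error")
  }
  col <- paste0("history_", flag)
  if (!col %in% names(cohort$subjects)) {
    abort(paste0("unknown history flag: ", flag),
          class = "stnlda_config_error")
  }
  flagged_ids <- cohort$subjects$subject_id[cohort$subjects[[col]]]
  vars <- c("total_vta_mm3", "frac_motor", "frac_associative", "frac_limbic",
            "frac_outside")
  rows <- list()
  for (h in hemispheres) {
    v <- cohort$vta[cohort$vta$hemisphere == h, ]
    with_grp <- v[v$subject_id %in% flagged_ids, ]
    without_grp <- v[!v$subject_id %in% flagged_ids, ]
    for (variable in vars) {
      x <- with_grp[[variable]]; y <- without_grp[[variable]]
      base <- tibble::tibble(hemisphere = h, variable = variable,
                             n_with = length(x), n_without = length(y),
                             mean_with = mean(x), sd_with = sd(x),
                             mean_without = mean(y), sd_without = sd(y))
      if (length(x) == 0L || length(y) == 0L) {
        rows[[length(rows) + 1L]] <-
          cbind(base, tibble::tibble(test_used = NA_character_,
                                     statistic = NA_real_, p = NA_real_,
                                     shapiro_p_with = NA_real_,
                                     shapiro_p_without = NA_real_,
                                     var_p = NA_real_,
                                     status = "empty-stratum"))
        next
      }
      tt <- two_group_test(x, y)
      rows[[length(rows) + 1L]] <-
        cbind(base, tibble::tibble(test_used = tt$test_used,
                                   statistic = tt$statistic, p = tt$p,
                                   shapiro_p_with = tt$shapiro_p_x,
                                   shapiro_p_without = tt$shapiro_p_y,
                                   var_p = tt$var_p, status = "ok"))
    }
  }
  tibble::as_tibble(dplyr::bind_rows(rows))
}

#' Correlate the motor:nonmotor stimulation ratio with outcome change
#'
#' Per measure and hemisphere, correlates each lead's ratio of motor to
#' nonmotor STN overlap, `frac_motor / (frac_associative + frac_limbic)`,
#' with the measure's change score. Pearson correlation is used when both
#' variables pass the Shapiro-Wilk gate (0.05), Spearman otherwise; BH
#' correction is applied across the family at `alpha`. Leads with zero
#' nonmotor overlap have an undefined ratio and are excluded (counted in
#' `n_excluded`).
#'
#' @param cohort An `"stnlda_cohort"` with a `vta` table.
#' @param measures Measure ids (default: all present).
#' @param alpha FDR level (default 0.10).
#' @param mode Delta mode, as in [run_measure()].
#' @return Tibble with one row per measure x hemisphere: `n`, `n_excluded`,
#'   `method`, `r`, `p`, `q`, `significant`, `status`.
#' @export
motor_ratio_correlation <- function(cohort, measures = NULL, alpha = 0.10,
                                    mode = cohort$schema$delta_mode) {
  stopifnot(inherits(cohort, "stnlda_cohort"))
  if (is.null(cohort$vta)) {
    abort("cohort has no VTA summary table", class = "stnlda_config_error")
  }
  if (is.null(measures)) {
    measures <- intersect(cohort$schema$battery$measure_id,
                          unique(cohort$scores$measure_id))
  }
  rows <- list()
  for (h in hemispheres) {
    v <- cohort$vta[cohort$vta$hemisphere == h, ]
    denom <- v$frac_associative + v$frac_limbic
    excluded <- denom <= 0
    if (any(excluded)) {
      message(sum(excluded), " lead(s) with zero nonmotor overlap excluded ",
              "from the ", h, " ratio analysis")
    }
    ratio <- stats::setNames(v$frac_motor[!excluded] / denom[!excluded],
                             v$subject_id[!excluded])
    for (m in measures) {
      delta <- measure_delta(cohort, m, h, mode)
      rr <- ratio[names(ratio) %in% names(delta)]
      dd <- delta[names(rr)]
      ok <- is.finite(dd) & is.finite(rr)
      n_use <- sum(ok)
      if (n_use < 4L) {
        rows[[length(rows) + 1L]] <-
          tibble::tibble(measure_id = m, hemisphere = h, n = n_use,
                         n_excluded = sum(excluded), method = NA_character_,
                         r = NA_real_, p = NA_real_, q = NA_real_,
                         significant = FALSE,
                         status = if (length(ratio) == 0L) "no-usable-ratio"
                                  else "insufficient-n")
        next
      }
      normal <- isTRUE(shapiro_gate_p(rr[ok]) >= 0.05) &&
        isTRUE(shapiro_gate_p(dd[ok]) >= 0.05)
      method <- if (normal) "pearson" else "spearman"
      ct <- suppressWarnings(stats::cor.test(rr[ok], dd[ok],
                                             method = method,
                                             exact = FALSE))
      rows[[length(rows) + 1L]] <-
        tibble::tibble(measure_id = m, hemisphere = h, n = n_use,
                       n_excluded = sum(excluded), method = method,
                       r = unname(ct$estimate), p = ct$p.value,
                       q = NA_real_, significant = FALSE, status = "ok")
    }
  }
  out <- tibble::as_tibble(dplyr::bind_rows(rows))
  sel <- out$status == "ok"
  if (any(sel)) {
    adj <- bh_adjust(out$p[sel], alpha)
    out$q[sel] <- adj$q
    out$significant[sel] <- adj$rejected
  }
  out
}
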