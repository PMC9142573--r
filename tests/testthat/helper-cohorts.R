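# Small in-code cohort fixtures for the IO and pipeline tests.

make_subjects_fixture <- function(n = 2L) {
  tibble::tibble(
    subject_id = sprintf("P%02d", seq_len(n)),
    history_depression = rep_len(c(TRUE, FALSE), n),
    history_anxiety = FALSE,
    history_vh = FALSE,
    history_icb = FALSE,
    left_x_mm = -12 + stats::rnorm(n, sd = 0.5),
    left_y_mm = -13 + stats::rnorm(n, sd = 0.5),
    left_z_mm = -6 + stats::rnorm(n, sd = 0.5),
    left_mode = "monopolar",
    right_x_mm = 12 + stats::rnorm(n, sd = 0.5),
    right_y_mm = -13 + stats::rnorm(n, sd = 0.5),
    right_z_mm = -6 + stats::rnorm(n, sd = 0.5),
    right_mode = "monopolar"
  )
}

make_scores_fixture <- function(subjects, measures = measure_battery()$measure_id) {
  grid <- expand.grid(subject_id = subjects$subject_id,
                      hemisphere = c("left", "right"),
                      measure_id = measures, stringsAsFactors = FALSE)
  grid$pre <- round(stats::rnorm(nrow(grid), 50, 8), 1)
  grid$post <- round(grid$pre + stats::rnorm(nrow(grid), 0, 6), 1)
  tibble::as_tibble(grid)
}

make_cohort_fixture <- function(n = 2L, measures = measure_battery()$measure_id,
                                seed = 1L) {
  set.seed(seed)
  subjects <- make_subjects_fixture(n)
  as_cohort(subjects, make_scores_fixture(subjects, measures))
}

# cohort whose flagged ("with") stratum carries its own planted direction
subgroup_effect_config <- function(flag = "depression", base_slope = 2,
                                   base_dir = c(0, 0, 1),
                                   extra_dir = c(0, 1, 0), extra_slope = 4,
                                   mode = "add", n = 42, seed = 1L,
                                   measures = c("list_recall",
                                                "semantic_fluency"),
                                   ...) {
  synthetic_config(
    n_subjects = n, planted_direction = base_dir, slope = base_slope,
    subgroup_effects = list(list(flag = flag, direction = extra_dir,
                                 slope = extra_slope, mode = mode)),
    measures = measures, seed = seed, ...)
}
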