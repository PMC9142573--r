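#' The neuropsychological test battery
#'
#' Returns the default 18-measure battery: 15 cognitive measures reported as
#' psychometric T scores (mean 50, SD 10, higher is better) plus three
#' self-report psychiatric scales -- CES-D (depression) and the Apathy
#' Evaluation Scale on their raw-score scales and the Zung Self-Rating Anxiety
#' Scale (SAS) as its anxiety index -- all scored so that lower is better.
#'
#' `polarity` records the clinical direction of each scale and is consumed by
#' [compute_delta()] when `mode = "polarity_adjusted"`.
#'
#' @return A tibble with columns `measure_id`, `scale`
#'   (`"T_score"`, `"raw"`, `"index"`), `polarity` (`"higher_is_better"`,
#'   `"lower_is_better"`), and `domain`.
#' @export
#' @examples
#' measure_battery()
measure_battery <- function() {
  cognitive <- tibble::tribble(
    ~measure_id,           ~domain,
    "trails_b",            "executive",
    "stroop",              "executive",
    "matrix_reasoning",    "executive",
    "similarities",        "executive",
    "semantic_fluency",    "language",
    "fas",                 "language",
    "boston_naming",       "language",
    "wtar",                "language",
    "list_learning",       "memory",
    "list_recall",         "memory",
    "figure_recall",       "memory",
    "figure_copy",         "visuospatial",
    "digit_span_forward",  "attention",
    "digit_span_backward", "attention",
    "picture_completion",  "attention"
  )
  cognitive$scale <- "T_score"
  cognitive$polarity <- "higher_is_better"
  psychiatric <- tibble::tibble(
    measure_id = c("cesd", "sas", "apathy"),
    domain = "psychiatric",
    scale = c("raw", "index", "raw"),
    polarity = "lower_is_better"
  )
  dplyr::bind_rows(cognitive, psychiatric)[, c("measure_id", "scale",
                                               "polarity", "domain")]
}

measure_ids <- function() measure_battery()$measure_id

#' Look up scale/polarity metadata for a measure
#'
#' @param measure_id Measure identifier as in [measure_battery()].
#' @param battery Battery table; defaults to [measure_battery()].
#' @return One-row tibble of battery metadata.
#' @export
measure_info <- function(measure_id, battery = measure_battery()) {
  row <- battery[battery$measure_id == measure_id, ]
  if (nrow(row) != 1L) {
    abort(paste0("unknown measure_id: ", measure_id),
          class = "stnlda_config_error")
  }
  row
}
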