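#' Pre/post change score
#'
#' Change is post minus pre on the measure's own scale. In `"strict"`
#' mode the raw difference is returned regardless of the clinical direction of
#' the scale. In the default `"polarity_adjusted"` mode the difference is
#' multiplied by -1 for lower-is-better scales (CES-D, SAS, Apathy), so a
#' positive delta always means clinical improvement and the improvement
#' outcome class keeps its clinical meaning on every scale.
#'
#' @param pre,post Numeric scores (same scale). Missing values propagate to
#'   `NA` rather than an error so pairwise deletion can happen downstream.
#' @param polarity `"higher_is_better"` or `"lower_is_better"`.
#' @param mode `"polarity_adjusted"` (default) or `"strict"`.
#' @return Numeric delta, `NA` if either score is missing.
#' @export
#' @examples
#' compute_delta(50, 45, "higher_is_better")            # -5
#' compute_delta(20, 10, "lower_is_better")             # +10: improvement
#' compute_delta(20, 10, "lower_is_better", "strict")  # -10
compute_delta <- function(pre, post,
                          polarity = c("higher_is_better", "lower_is_better"),
                          mode = c("polarity_adjusted", "strict")) {
  polarity <- match.arg(polarity)
  mode <- match.arg(mode)
  delta <- post - pre
  if (mode == "polarity_adjusted" && polarity == "lower_is_better") {
    delta <- -delta
  }
  delta
}

#' Tri-class outcome label for a change score
#'
#' Labels a delta as `"worsening"` (delta < -band), `"unchanged"`
#' (-band <= delta <= band, boundaries inclusive in the unchanged class) or
#' `"improvement"` (delta > band). The default band half-width of 5 makes the
#' unchanged class span 10 T-score points, i.e. one population SD on the
#' T-score scale, the conventional threshold for clinically meaningful change.
#'
#' @param delta Numeric vector of finite change scores.
#' @param band Positive half-width of the unchanged band (default 5).
#' @return Factor with levels `worsening`, `unchanged`, `improvement`.
#' @export
#' @examples
#' assign_class(c(-6, -5, 0, 5, 5.1))
assign_class <- function(delta, band = 5) {
  if (!is.numeric(band) || length(band) != 1L || !is.finite(band) || band <= 0) {
    abort("band must be a single positive number",
          class = "stnlda_config_error")
  }
  if (any(!is.finite(delta))) {
    abort("assign_class requires finite deltas; drop missing values first",
          class = "stnlda_value_error")
  }
  lab <- ifelse(delta < -band, "worsening",
                ifelse(delta > band, "improvement", "unchanged"))
  factor(lab, levels = c("worsening", "unchanged", "improvement"))
}
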