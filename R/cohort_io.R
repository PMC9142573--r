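#' Default cohort table schema
#'
#' Declares the file names and column names [read_cohort()] expects, the
#' measure battery (with per-measure scale and polarity, overridable), and
#' analysis defaults. Scores live in a long table keyed by
#' `(subject_id, hemisphere, measure_id)` -- pairwise missingness per measure
#' is natural in long format -- while per-subject history flags, active
#' contact coordinates and stimulation modes live in a wide subject table.
#' Coordinates are consumed as already-normalized MNI millimetres; no imaging
#' is ever read.
#'
#' @param ... Named overrides of any schema entry (e.g. a custom `battery`
#'   table to change measure polarities).
#' @return A schema list.
#' @export
cohort_schema <- function(...) {
  schema <- list(
    subjects_file = "subjects.csv",
    scores_file = "scores.csv",
    vta_file = "vta.csv",
    metadata_file = "metadata.json",
    subject_columns = c("subject_id",
                        "history_depression", "history_anxiety",
                        "history_vh", "history_icb",
                        "left_x_mm", "left_y_mm", "left_z_mm", "left_mode",
                        "right_x_mm", "right_y_mm", "right_z_mm", "right_mode"),
    score_columns = c("subject_id", "hemisphere", "measure_id", "pre", "post"),
    vta_columns = c("subject_id", "hemisphere", "total_vta_mm3", "frac_motor",
                    "frac_associative", "frac_limbic", "frac_outside"),
    battery = measure_battery(),
    band = 5,
    delta_mode = "polarity_adjusted"
  )
  utils::modifyList(schema, list(...))
}

hemispheres <- c("left", "right")

#' Active contact location
#'
#' @param hemisphere `"left"` or `"right"`.
#' @param x_mm,y_mm,z_mm Finite MNI coordinates in millimetres.
#' @return A `"contact_location"` list.
#' @export
contact_location <- function(hemisphere, x_mm, y_mm, z_mm) {
  hemisphere <- match.arg(hemisphere, hemispheres)
  coords <- c(x_mm = x_mm, y_mm = y_mm, z_mm = z_mm)
  if (!all(is.finite(coords))) {
    abort("contact coordinates must be finite", class = "stnlda_value_error")
  }
  structure(list(hemisphere = hemisphere, x_mm = x_mm, y_mm = y_mm,
                 z_mm = z_mm), class = "contact_location")
}

#' Effective stimulation location of a lead
#'
#' For monopolar stimulation the effective location is the cathode contact
#' itself; for bipolar stimulation it is the component-wise midpoint of the
#' cathode and anode contacts.
#'
#' @param cathode A [contact_location()].
#' @param anode A [contact_location()] (required for bipolar mode).
#' @param mode `"monopolar"` or `"bipolar"`.
#' @return A [contact_location()].
#' @export
#' @examples
#' a <- contact_location("left", -12, -13, -7)
#' b <- contact_location("left", -12, -13, -3)
#' effective_contact(a, b, "bipolar")  # (-12, -13, -5)
effective_contact <- function(cathode, anode = NULL,
                              mode = c("monopolar", "bipolar")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cathode, "contact_location"))
  if (mode == "monopolar") return(cathode)
  if (is.null(anode)) {
    abort("bipolar stimulation requires an anode contact",
          class = "stnlda_config_error")
  }
  stopifnot(inherits(anode, "contact_location"))
  if (cathode$hemisphere != anode$hemisphere) {
    abort("bipolar cathode and anode must be in the same hemisphere",
          class = "stnlda_config_error")
  }
  contact_location(cathode$hemisphere,
                   (cathode$x_mm + anode$x_mm) / 2,
                   (cathode$y_mm + anode$y_mm) / 2,
                   (cathode$z_mm + anode$z_mm) / 2)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(paste0(what, " table is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "stnlda_schema_error")
  }
  invisible(df)
}

check_numeric_column <- function(df, col, what) {
  v <- df[[col]]
  if (is.numeric(v)) return(invisible(df))
  parsed <- suppressWarnings(as.numeric(v))
  bad <- which(!is.na(v) & is.na(parsed))
  if (length(bad) > 0L) {
    abort(paste0("non-numeric value in ", what, " column ", col, " at row ",
                 bad[1L]),
          class = "stnlda_parse_error")
  }
  df[[col]] <- parsed
  invisible(df)
}

#' Assemble a validated cohort
#'
#' Builds the cohort container from in-memory tables, applying the same
#' validation as [read_cohort()]: required columns present, coordinates
#' numeric and finite, unique subject ids, known measure ids and hemispheres.
#' Rows with a missing pre or post score are retained with `delta = NA` so
#' that each measure x hemisphere analysis can use pairwise deletion. A
#' left-hemisphere contact with x > 0 (or right with x < 0) triggers a
#' warning, not an error: nonlinear warping into group space can displace
#' contacts across the midline.
#'
#' @param subjects Wide per-subject table (see [cohort_schema()]).
#' @param scores Long score table keyed by subject, hemisphere, measure.
#' @param vta Optional per-lead VTA summary table.
#' @param schema A [cohort_schema()].
#' @param metadata Optional named list stored alongside the cohort.
#' @return An object of class `"stnlda_cohort"`.
#' @export
as_cohort <- function(subjects, scores, vta = NULL, schema = cohort_schema(),
                      metadata = list()) {
  subjects <- tibble::as_tibble(subjects)
  scores <- tibble::as_tibble(scores)
  require_columns(subjects, schema$subject_columns, "subjects")
  require_columns(scores, schema$score_columns, "scores")
  for (col in grep("_(x|y|z)_mm$", schema$subject_columns, value = TRUE)) {
    subjects <- check_numeric_column(subjects, col, "subjects")
    if (any(!is.finite(subjects[[col]]))) {
      abort(paste0("non-finite coordinate in column ", col),
            class = "stnlda_parse_error")
    }
  }
  if (anyDuplicated(subjects$subject_id)) {
    abort("duplicate subject_id in subjects table",
          class = "stnlda_schema_error")
  }
  for (col in c("pre", "post")) {
    scores <- check_numeric_column(scores, col, "scores")
  }
  if (!all(scores$hemisphere %in% hemispheres)) {
    abort("scores hemisphere must be 'left' or 'right'",
          class = "stnlda_schema_error")
  }
  unknown <- setdiff(unique(scores$measure_id), schema$battery$measure_id)
  if (length(unknown) > 0L) {
    abort(paste0("unknown measure_id(s) in scores: ",
                 paste(unknown, collapse = ", ")),
          class = "stnlda_schema_error")
  }
  orphan <- setdiff(unique(scores$subject_id), subjects$subject_id)
  if (length(orphan) > 0L) {
    abort(paste0("scores reference unknown subject(s): ",
                 paste(orphan, collapse = ", ")),
          class = "stnlda_schema_error")
  }
  bad_left <- subjects$left_x_mm > 0
  bad_right <- subjects$right_x_mm < 0
  if (any(bad_left | bad_right)) {
    warn(paste0(sum(bad_left) + sum(bad_right), " contact(s) lie on the ",
                "unexpected side of the midline (group-space warping can ",
                "displace contacts); retained"))
  }
  scores$delta <- scores$post - scores$pre
  structure(list(subjects = subjects,
                 scores = scores,
                 vta = if (!is.null(vta)) tibble::as_tibble(vta),
                 schema = schema,
                 metadata = metadata),
            class = "stnlda_cohort")
}

#' Read a cohort from disk
#'
#' Reads the wide subject table, the long score table and (when present) the
#' VTA summary table from a directory, validating against the schema; see
#' [as_cohort()] for the validation rules.
#'
#' @param path Directory containing the cohort tables.
#' @param schema A [cohort_schema()].
#' @return An `"stnlda_cohort"`.
#' @export
read_cohort <- function(path, schema = cohort_schema()) {
  subj_path <- file.path(path, schema$subjects_file)
  score_path <- file.path(path, schema$scores_file)
  for (p in c(subj_path, score_path)) {
    if (!file.exists(p)) {
      abort(paste0("cohort file not found: ", p), class = "stnlda_io_error")
    }
  }
  subjects <- readr::read_csv(subj_path, show_col_types = FALSE,
                              progress = FALSE)
  scores <- readr::read_csv(score_path, show_col_types = FALSE,
                            progress = FALSE)
  vta_path <- file.path(path, schema$vta_file)
  vta <- if (file.exists(vta_path)) {
    v <- readr::read_csv(vta_path, show_col_types = FALSE, progress = FALSE)
    require_columns(v, schema$vta_columns, "vta")
    v
  }
  meta_path <- file.path(path, schema$metadata_file)
  metadata <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list()
  }
  as_cohort(subjects, scores, vta, schema, metadata)
}

#' Write a cohort to disk
#'
#' Writes the cohort tables as CSV plus a JSON metadata sidecar carrying the
#' generating seed (if any), a hash of the generating configuration, and the
#' package version, so an analysis directory is self-describing.
#'
#' @param cohort An `"stnlda_cohort"`.
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "stnlda_cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  schema <- cohort$schema
  scores_out <- cohort$scores[, schema$score_columns]
  readr::write_csv(cohort$subjects, file.path(path, schema$subjects_file))
  readr::write_csv(scores_out, file.path(path, schema$scores_file))
  if (!is.null(cohort$vta)) {
    readr::write_csv(cohort$vta, file.path(path, schema$vta_file))
  }
  metadata <- cohort$metadata
  metadata$package_version <- as.character(utils::packageVersion("stnlda"))
  jsonlite::write_json(metadata, file.path(path, schema$metadata_file),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @export
print.stnlda_cohort <- function(x, ...) {
  cat("STN-DBS cohort: ", nrow(x$subjects), " subjects, ",
      length(unique(x$scores$measure_id)), " measures, ",
      nrow(x$scores), " score rows",
      if (!is.null(x$vta)) ", with VTA summaries", "\n", sep = "")
  flags <- c(depression = sum(x$subjects$history_depression),
             anxiety = sum(x$subjects$history_anxiety),
             vh = sum(x$subjects$history_vh),
             icb = sum(x$subjects$history_icb))
  cat("  history flags: ",
      paste(names(flags), flags, sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Contact coordinate matrix for one hemisphere
#'
#' @param cohort An `"stnlda_cohort"`.
#' @param hemisphere `"left"` or `"right"`.
#' @return n x 3 matrix (columns `x_mm`, `y_mm`, `z_mm`, rownames
#'   subject ids) of effective active-contact MNI coordinates.
#' @export
contact_matrix <- function(cohort, hemisphere) {
  hemisphere <- match.arg(hemisphere, hemispheres)
  s <- cohort$subjects
  m <- as.matrix(s[, paste0(hemisphere, "_", c("x", "y", "z"), "_mm")])
  colnames(m) <- c("x_mm", "y_mm", "z_mm")
  rownames(m) <- s$subject_id
  m
}

#' Analysis-ready change scores for one measure and hemisphere
#'
#' Change scores in the cohort's configured delta mode (see
#' [compute_delta()]), aligned to the subject table order; `NA` where the
#' pre or post score is missing, so downstream analyses can pairwise-delete.
#'
#' @param cohort An `"stnlda_cohort"`.
#' @param measure_id Measure identifier.
#' @param hemisphere `"left"` or `"right"`.
#' @param mode Delta mode override.
#' @return Named numeric vector (names = subject ids).
#' @export
measure_delta <- function(cohort, measure_id, hemisphere,
                          mode = cohort$schema$delta_mode) {
  info <- measure_info(measure_id, cohort$schema$battery)
  sc <- cohort$scores
  sc <- sc[sc$measure_id == measure_id & sc$hemisphere == hemisphere, ]
  delta <- compute_delta(sc$pre, sc$post, info$polarity, mode)
  out <- stats::setNames(delta, sc$subject_id)[cohort$subjects$subject_id]
  stats::setNames(out, cohort$subjects$subject_id)
}
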