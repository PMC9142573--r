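#' Standardize a coordinate matrix
#'
#' Per-axis z-scoring (mean 0, SD 1) of an n x d coordinate matrix. The
#' discriminant axis is fitted in this standardized space so that millimetre
#' spread differences between the mediolateral, anterioposterior and
#' inferiosuperior axes do not bias the fit; the returned record inverts the
#' transform exactly and is what [to_native()] uses to express the axis back
#' in MNI millimetres.
#'
#' @param points Numeric matrix (n x d), n >= 2.
#' @return List with `points` (standardized matrix), `center` and `scale`
#'   (per-axis mean and SD).
#' @export
standardize <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || nrow(points) < 2L) {
    abort("standardize needs a numeric matrix with at least 2 rows",
          class = "stnlda_value_error")
  }
  center <- colMeans(points)
  scale <- apply(points, 2L, stats::sd)
  if (any(scale <= 0 | !is.finite(scale))) {
    bad <- which(scale <= 0 | !is.finite(scale))[1L]
    nm <- colnames(points)[bad]
    if (is.null(nm) || is.na(nm) || nm == "") nm <- c("x", "y", "z")[bad]
    abort(paste0("degenerate geometry: zero variance along axis ", nm),
          class = "stnlda_degenerate_error")
  }
  std <- sweep(sweep(points, 2L, center, "-"), 2L, scale, "/")
  list(points = std, center = center, scale = scale)
}

#' Invert a standardization
#'
#' @param points Standardized matrix.
#' @param record Record returned by [standardize()].
#' @return Matrix in the original coordinates.
#' @export
unstandardize <- function(points, record) {
  sweep(sweep(as.matrix(points), 2L, record$scale, "*"), 2L, record$center, "+")
}

#' Map a standardized-space direction back to native MNI space
#'
#' A direction in standardized space corresponds, under the inverse of the
#' per-axis z-scoring, to the native direction whose components are the
#' standardized components multiplied by the per-axis SDs; the result is
#' renormalized to unit length. Translation (the centering) does not affect a
#' direction.
#'
#' @param v_std Unit vector in standardized space.
#' @param record Record returned by [standardize()].
#' @return Unit vector in native space.
#' @export
to_native <- function(v_std, record) {
  v <- as.numeric(v_std) * record$scale
  v / sqrt(sum(v^2))
}

#' Per-axis proportions of a direction vector
#'
#' Decomposes a unit direction into fractional contributions along the
#' coordinate axes. The default `"abs"` method reports
#' `|v_i| / sum(|v|)`, so the three proportions sum to 1; the
#' `"squared"` alternative reports squared components (which for a unit
#' vector also sum to 1).
#'
#' @param v Unit 3-vector.
#' @param method `"abs"` (default) or `"squared"`.
#' @return Named numeric vector `c(p_x, p_y, p_z)` summing to 1.
#' @export
#' @examples
#' axis_proportions(c(1, 2, 2) / 3)  # 0.2 0.4 0.4
axis_proportions <- function(v, method = c("abs", "squared")) {
  method <- match.arg(method)
  v <- as.numeric(v)
  p <- switch(method,
              abs = abs(v) / sum(abs(v)),
              squared = v^2 / sum(v^2))
  stats::setNames(p, c("p_x", "p_y", "p_z")[seq_along(p)])
}

#' Project points onto a discriminant direction
#'
#' Computes the scalar projection `<x_i, v>` of each (standardized) point on
#' the unit direction and, by default, z-scores the projections. The
#' normalization is an affine map, so Pearson correlations of the projections
#' with any outcome are identical whether or not it is applied.
#'
#' @param points Standardized n x d matrix.
#' @param v_std Unit direction in the same space.
#' @param normalize Z-score the projections (default `TRUE`).
#' @return Numeric vector of n projections.
#' @export
project_points <- function(points, v_std, normalize = TRUE) {
  proj <- drop(as.matrix(points) %*% as.numeric(v_std))
  if (normalize) {
    s <- stats::sd(proj)
    if (!is.finite(s) || s <= 0) {
      abort("degenerate geometry: zero projection variance",
            class = "stnlda_degenerate_error")
    }
    proj <- (proj - mean(proj)) / s
  }
  proj
}

# Between-class scatter, class-size weighted: S_b = sum_c n_c (mu_c-mu)(mu_c-mu)'
# Within-class scatter:                       S_w = sum_c sum_{i in c} (x_i-mu_c)(x_i-mu_c)'
scatter_matrices <- function(points, labels) {
  mu <- colMeans(points)
  d <- ncol(points)
  s_b <- matrix(0, d, d)
  s_w <- matrix(0, d, d)
  for (cl in levels(droplevels(labels))) {
    xc <- points[labels == cl, , drop = FALSE]
    mu_c <- colMeans(xc)
    dmu <- mu_c - mu
    s_b <- s_b + nrow(xc) * tcrossprod(dmu)
    xc_c <- sweep(xc, 2L, mu_c, "-")
    s_w <- s_w + crossprod(xc_c)
  }
  list(s_b = s_b, s_w = s_w, grand_mean = mu)
}

# Generalized eigenproblem S_b v = lambda S_w v via whitening: with
# S_w = R'R (Cholesky), the symmetric problem R'^-1 S_b R^-1 u = lambda u has
# real nonnegative eigenvalues and v = R^-1 u. S_w is Tikhonov-regularized
# (eps = 1e-8 * trace/d) when ill-conditioned or non-PD; classes of size 2
# at cohort scale make this a live concern.
solve_discriminant <- function(s_b, s_w, cond_limit = 1e10) {
  d <- ncol(s_w)
  regularize <- function(m) m + diag(1e-8 * sum(diag(m)) / d, d)
  ev_w <- eigen(s_w, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_w) <= 0 || max(ev_w) / max(min(ev_w), .Machine$double.xmin) > cond_limit) {
    s_w <- regularize(s_w)
    ev_w <- eigen(s_w, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev_w) <= 0) {
      abort("within-class scatter singular even after regularization",
            class = "stnlda_degenerate_error")
    }
  }
  r <- chol(s_w)
  m <- backsolve(r, t(backsolve(r, t(s_b), transpose = TRUE)), transpose = TRUE)
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vectors <- backsolve(r, e$vectors)
  vectors <- sweep(vectors, 2L, sqrt(colSums(vectors^2)), "/")
  list(values = e$values, vectors = vectors)
}

#' Fit the Fisher discriminant axis to labelled contact coordinates
#'
#' Fits Fisher linear discriminant analysis to 3D (or 2D) coordinates
#' labelled by outcome class: class-size-weighted between-class scatter and
#' pooled within-class scatter are computed on standardized coordinates, the
#' generalized eigenproblem `S_b v = lambda S_w v` is solved, and the leading
#' eigenvector (LDA1) is retained. The axis is oriented toward the
#' improvement class, mapped back to native MNI space, decomposed into
#' per-axis proportions, and used to project all points.
#'
#' Classes with a single member are dropped from the scatter computation with
#' a warning (their points are still projected); the fit requires at least
#' two remaining classes with >= 2 members each. With C classes at most C-1
#' eigenvalues can exceed the rank tolerance, and the share of class-to-class
#' variability explained by LDA1 is computed over those supra-tolerance
#' eigenvalues.
#'
#' @param points n x 3 (or n x 2) matrix of native-space coordinates, n >= 4.
#' @param labels Outcome classes (factor as from [assign_class()], or any
#'   vector coercible to factor).
#' @param orient Orient LDA1 toward the improvement class (default `TRUE`).
#' @param proportion_method Passed to [axis_proportions()].
#' @return An object of class `"stnlda_axis"`: list with `eigenvalues`,
#'   `v_std`, `v_mni`, `pct_variance`, `class_means` (standardized space),
#'   `class_means_native`, `axis_proportions`, `projections` (normalized),
#'   `n`, `n_classes_used`, `dropped_classes`, `standardization`,
#'   `grand_mean`.
#' @export
fit_lda <- function(points, labels, orient = TRUE,
                    proportion_method = c("abs", "squared")) {
  proportion_method <- match.arg(proportion_method)
  points <- as.matrix(points)
  labels <- droplevels(as.factor(labels))
  if (nrow(points) != length(labels)) {
    abort("points and labels lengths differ", class = "stnlda_value_error")
  }
  if (nrow(points) < 4L) {
    abort("need at least 4 labelled points", class = "stnlda_value_error")
  }
  counts <- table(labels)
  singletons <- names(counts)[counts == 1L]
  usable <- names(counts)[counts >= 2L]
  if (length(usable) < 2L) {
    abort("fewer than 2 classes with >= 2 members; discriminant undefined",
          class = "stnlda_single_class_error")
  }
  if (length(singletons) > 0L) {
    warning("dropping singleton class(es) from the fit: ",
            paste(singletons, collapse = ", "), call. = FALSE)
  }
  fit_mask <- labels %in% usable
  std <- standardize(points)
  fit_pts <- std$points[fit_mask, , drop = FALSE]
  fit_lab <- droplevels(labels[fit_mask])

  sc <- scatter_matrices(fit_pts, fit_lab)
  eig <- solve_discriminant(sc$s_b, sc$s_w)
  values <- pmax(eig$values, 0)
  tol <- max(values) * 1e-7 + 1e-12
  keep <- values > tol
  n_keep <- sum(keep)
  if (n_keep == 0L) {
    abort("all discriminant eigenvalues below rank tolerance",
          class = "stnlda_degenerate_error")
  }
  idx <- 1L
  # near-tied leading eigenvalues: prefer the one better aligned with the
  # improvement class after orientation
  if (n_keep >= 2L && (values[1] - values[2]) <= 1e-9 * values[1]) {
    target <- improvement_direction(fit_pts, fit_lab, sc$grand_mean)
    a1 <- abs(sum(eig$vectors[, 1] * target))
    a2 <- abs(sum(eig$vectors[, 2] * target))
    if (a2 > a1) idx <- 2L
    message("leading discriminant eigenvalues tied within tolerance; ",
            "selecting by alignment with the improvement class")
  }
  v_std <- eig$vectors[, idx]

  class_means_std <- t(vapply(levels(fit_lab), function(cl) {
    colMeans(fit_pts[fit_lab == cl, , drop = FALSE])
  }, numeric(ncol(points))))
  res <- structure(list(
    eigenvalues = values,
    rank_tolerance = tol,
    v_std = v_std,
    v_mni = to_native(v_std, std),
    pct_variance = values[idx] / sum(values[keep]),
    class_means = class_means_std,
    class_means_native = unstandardize(class_means_std, std),
    grand_mean = sc$grand_mean,
    n = nrow(points),
    n_classes_used = length(usable),
    dropped_classes = singletons,
    standardization = std[c("center", "scale")],
    proportion_method = proportion_method
  ), class = "stnlda_axis")
  if (orient) res <- orient_vector(res)
  res$axis_proportions <- axis_proportions(res$v_mni, proportion_method)
  res$projections <- project_points(std$points, res$v_std)
  res
}

# unit vector (standardized space) from grand mean toward the orientation
# target class: improvement if present, else the present class with the best
# outcome ordering (improvement > unchanged > worsening)
improvement_direction <- function(points_std, labels, grand_mean) {
  lv <- levels(labels)
  target <- if ("improvement" %in% lv) {
    "improvement"
  } else {
    preferred <- intersect(c("improvement", "unchanged", "worsening"), lv)
    if (length(preferred) == 0L) preferred <- lv
    preferred[1L]
  }
  mu_t <- colMeans(points_std[labels == target, , drop = FALSE])
  d <- mu_t - grand_mean
  nrm <- sqrt(sum(d^2))
  if (nrm > 0) d / nrm else d
}

#' Orient a fitted discriminant toward the improvement class
#'
#' Flips the sign of LDA1 (both standardized and native representations,
#' plus any stored projections) so that it points from the grand mean toward
#' the improvement-class mean in standardized space; the positive end of the
#' axis then always corresponds to postoperative improvement. If the
#' improvement class is absent the best-outcome class present is used. An
#' axis exactly orthogonal to the target direction is returned unchanged, and
#' the operation is idempotent.
#'
#' @param result An `"stnlda_axis"` object from [fit_lda()].
#' @return The oriented object.
#' @export
orient_vector <- function(result) {
  stopifnot(inherits(result, "stnlda_axis"))
  cm <- result$class_means
  labs <- factor(rownames(cm), levels = rownames(cm))
  lab_long <- rep(labs, each = 1L)
  # class means serve as one-point-per-class stand-ins for the direction
  target <- improvement_direction(cm, lab_long, result$grand_mean)
  alignment <- sum(result$v_std * target)
  if (alignment < 0) {
    result$v_std <- -result$v_std
    result$v_mni <- -result$v_mni
    if (!is.null(result$projections)) {
      result$projections <- -result$projections
    }
  }
  result
}

#' @export
print.stnlda_axis <- function(x, ...) {
  cat("Fisher discriminant axis (n = ", x$n, ", classes used = ",
      x$n_classes_used, ")\n", sep = "")
  cat("  LDA1 (MNI space): [", paste(sprintf("%.3f", x$v_mni), collapse = ", "),
      "]\n", sep = "")
  cat(sprintf("  class-to-class variance explained: %.1f%%\n",
              100 * x$pct_variance))
  cat("  axis proportions (x, y, z): ",
      paste(sprintf("%.1f%%", 100 * x$axis_proportions), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
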