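test_that("standardization zeroes means, unit-scales SDs, and inverts", {
  set.seed(2)
  pts <- matrix(rnorm(60, sd = 4), 20, 3) + rep(c(5, -3, 0), each = 20)
  std <- standardize(pts)
  expect_equal(colMeans(std$points), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(std$points, 2, sd), rep(1, 3), tolerance = 1e-12)
  expect_equal(unstandardize(std$points, std), pts, tolerance = 1e-10,
               ignore_attr = TRUE)
  # idempotence: already standardized input is returned unchanged
  again <- standardize(std$points)
  expect_equal(again$points, std$points, tolerance = 1e-12)
  # degenerate geometry is refused and names the flat axis
  flat <- cbind(x = rnorm(5), y = rnorm(5), z = 2)
  expect_error(standardize(flat), "z", class = "stnlda_degenerate_error")
  expect_error(standardize(matrix(1, 2, 3)),
               class = "stnlda_degenerate_error")
})

test_that("perfect separation along one axis yields that axis with all the variance", {
  pts <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  fit <- fit_lda(pts, c("worsening", "worsening", "improvement",
                        "improvement"))
  expect_equal(abs(fit$v_std), c(1, 0), tolerance = 1e-9)
  expect_equal(fit$pct_variance, 1, tolerance = 1e-9)
  # oriented toward the improvement class, which sits at larger x
  expect_gt(fit$v_std[1], 0)
})

test_that("collinear class means recover the shared axis; second eigenvalue vanishes", {
  set.seed(3)
  means <- rbind(c(0, 0, -2), c(0, 0, 0), c(0, 0, 2))
  labels <- rep(c("worsening", "unchanged", "improvement"), each = 15)
  noise_levels <- c(1e-1, 1e-3)
  ratios <- vapply(noise_levels, function(ns) {
    pts <- means[rep(1:3, each = 15), ] + matrix(rnorm(135, sd = ns), 45, 3)
    fit <- fit_lda(pts, labels)
    expect_lt(angle_deg(fit$v_std, c(0, 0, 1)), 1)
    expect_gt(fit$v_mni[3], 0)  # oriented toward improvement (high z)
    fit$eigenvalues[2] / fit$eigenvalues[1]
  }, numeric(1))
  # shrinking the within-class noise drives the second eigenvalue to zero
  expect_lt(ratios[2], ratios[1] / 10)
  expect_lt(ratios[2], 1e-4)
})

test_that("fitted axis matches the brute-force Rayleigh maximizer (2D, 2 classes)", {
  set.seed(4)
  for (i in 1:10) {
    inst <- random_instance(30, 2, 2)
    fit <- fit_lda(inst$points, inst$labels)
    oracle <- brute_force_lda(inst$points, inst$labels)
    expect_lt(angle_deg(fit$v_std, oracle), 0.5)
  }
})

test_that("fitted axis matches the reference discriminant implementation (3D, 3 classes)", {
  set.seed(5)
  for (i in 1:10) {
    inst <- random_instance(40, 3, 3)
    fit <- fit_lda(inst$points, inst$labels)
    ref <- MASS::lda(scale(inst$points), grouping = inst$labels)
    expect_lt(angle_deg(fit$v_std, ref$scaling[, 1]), 0.5)
  }
})

test_that("singleton classes are dropped with a warning; sub-2-class fits are refused", {
  set.seed(6)
  pts <- rbind(matrix(rnorm(20), 10, 2) + 4, matrix(rnorm(20), 10, 2),
               c(50, 50))
  labels <- c(rep("improvement", 10), rep("unchanged", 10), "worsening")
  expect_warning(fit <- fit_lda(pts, labels), "singleton")
  expect_equal(fit$n_classes_used, 2L)
  expect_equal(fit$dropped_classes, "worsening")
  expect_length(fit$projections, 21L)  # dropped points are still projected
  expect_error(
    suppressWarnings(fit_lda(matrix(rnorm(10), 5, 2),
                             c("a", "a", "a", "a", "b"))),
    class = "stnlda_single_class_error")
})

test_that("orientation points toward improvement and is idempotent", {
  set.seed(7)
  inst <- random_instance(30, 3, 3)
  labels <- factor(c("worsening", "unchanged", "improvement")[
    as.integer(inst$labels)])
  fit <- fit_lda(inst$points, labels)
  mu_imp <- colMeans(standardize(inst$points)$points[labels == "improvement", ])
  expect_gte(sum(fit$v_std * (mu_imp - fit$grand_mean)), 0)
  # manually flip, reorient, recover
  flipped <- fit
  flipped$v_std <- -flipped$v_std
  flipped$v_mni <- -flipped$v_mni
  flipped$projections <- -flipped$projections
  back <- orient_vector(flipped)
  expect_equal(back$v_std, fit$v_std)
  expect_equal(back$projections, fit$projections)
  expect_equal(orient_vector(fit), fit)
})

test_that("native-space back-transform multiplies by axis SDs and renormalizes", {
  rec_iso <- list(center = c(0, 0, 0), scale = c(2, 2, 2))
  expect_equal(to_native(c(1, 2, 2) / 3, rec_iso), c(1, 2, 2) / 3)
  rec_axis <- list(center = c(1, 2, 3), scale = c(2, 2, 4))
  expect_equal(to_native(c(0, 0, 1), rec_axis), c(0, 0, 1))
  rec <- list(center = c(0, 0, 0), scale = c(3, 1, 1))
  expect_equal(to_native(c(1, 1, 0) / sqrt(2), rec), c(3, 1, 0) / sqrt(10))
  # finite-difference cross-check: map two standardized points through the
  # inverse transform and renormalize their difference
  set.seed(8)
  pts <- matrix(rnorm(30), 10, 3) * rep(c(3, 1, 1), each = 10)
  std <- standardize(pts)
  v <- c(1, 1, 0) / sqrt(2)
  p0 <- unstandardize(rbind(c(0, 0, 0), v), std)
  dvec <- p0[2, ] - p0[1, ]
  expect_equal(to_native(v, std), dvec / sqrt(sum(dvec^2)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("axis proportions decompose a unit vector as documented", {
  expect_equal(unname(axis_proportions(c(0, 0, 1))), c(0, 0, 1))
  expect_equal(unname(axis_proportions(c(1, 1, 0) / sqrt(2))),
               c(0.5, 0.5, 0))
  expect_equal(unname(axis_proportions(c(1, 2, 2) / 3)), c(0.2, 0.4, 0.4))
  expect_equal(unname(axis_proportions(c(-1, 2, -2) / 3)), c(0.2, 0.4, 0.4))
  expect_equal(sum(axis_proportions(c(0.3, -0.8, 0.52))), 1)
  expect_equal(unname(axis_proportions(c(1, 2, 2) / 3, "squared")),
               c(1, 4, 4) / 9)
})

test_that("projections are invariant to joint rigid rotation and to normalization choice", {
  set.seed(9)
  pts <- scale(matrix(rnorm(90), 30, 3))
  v <- c(1, 2, -2) / 3
  raw <- project_points(pts, v, normalize = FALSE)
  norm <- project_points(pts, v)
  rot <- random_rotation(3)
  rotated <- project_points(pts %*% t(rot), drop(rot %*% v),
                            normalize = FALSE)
  expect_equal(rotated, raw, tolerance = 1e-10)
  # normalization is affine, so correlations with any outcome are unchanged
  outcome <- rnorm(30)
  expect_equal(cor(raw, outcome), cor(norm, outcome), tolerance = 1e-12)
  expect_error(project_points(matrix(0, 5, 3), c(1, 0, 0)),
               class = "stnlda_degenerate_error")
})

test_that("discriminant eigenvalues are nonnegative with at most C-1 above tolerance", {
  set.seed(10)
  for (i in 1:25) {
    n_cl <- sample(2:3, 1)
    inst <- random_instance(sample(10:40, 1), 3, n_cl)
    fit <- suppressWarnings(fit_lda(inst$points, inst$labels))
    expect_true(all(fit$eigenvalues >= -1e-10))
    expect_lte(sum(fit$eigenvalues > fit$rank_tolerance), n_cl - 1L)
    expect_true(fit$pct_variance >= 0 && fit$pct_variance <= 1)
    expect_equal(sum(fit$axis_proportions), 1, tolerance = 1e-9)
    expect_equal(sqrt(sum(fit$v_std^2)), 1, tolerance = 1e-9)
    expect_equal(sqrt(sum(fit$v_mni^2)), 1, tolerance = 1e-9)
  }
})
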