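# Independent oracles for the discriminant fit. Everything here recomputes
# scatter matrices and the Rayleigh quotient from the definitions with plain
# loops -- deliberately sharing no code with the package internals.

oracle_scatter <- function(points, labels) {
  mu <- colMeans(points)
  d <- ncol(points)
  s_b <- matrix(0, d, d)
  s_w <- matrix(0, d, d)
  for (cl in unique(labels)) {
    xc <- points[labels == cl, , drop = FALSE]
    mc <- colMeans(xc)
    s_b <- s_b + nrow(xc) * outer(mc - mu, mc - mu)
    for (i in seq_len(nrow(xc))) {
      s_w <- s_w + outer(xc[i, ] - mc, xc[i, ] - mc)
    }
  }
  list(s_b = s_b, s_w = s_w)
}

rayleigh_quotient <- function(v, sc) {
  drop(v %*% sc$s_b %*% v) / drop(v %*% sc$s_w %*% v)
}

# Brute-force maximizer of the Rayleigh quotient over directions:
# dense grid (vectorized evaluation) plus local refinement.
brute_force_lda <- function(points, labels) {
  pts <- scale(points)
  sc <- oracle_scatter(pts, labels)
  d <- ncol(pts)
  ray_cols <- function(dirs) {
    colSums((sc$s_b %*% dirs) * dirs) / colSums((sc$s_w %*% dirs) * dirs)
  }
  if (d == 2L) {
    theta <- seq(0, pi, length.out = 3601L)[-3601L]
    dirs <- rbind(cos(theta), sin(theta))
    best <- which.max(ray_cols(dirs))
    f <- function(th) rayleigh_quotient(c(cos(th), sin(th)), sc)
    opt <- stats::optimize(f, theta[best] + c(-2, 2) * pi / 3600,
                           maximum = TRUE, tol = 1e-12)
    v <- c(cos(opt$maximum), sin(opt$maximum))
  } else {
    theta <- seq(0, pi, length.out = 61L)
    phi <- seq(0, 2 * pi, length.out = 121L)[-121L]
    g <- expand.grid(theta = theta, phi = phi)
    dirs <- rbind(sin(g$theta) * cos(g$phi), sin(g$theta) * sin(g$phi),
                  cos(g$theta))
    best <- which.max(ray_cols(dirs))
    f <- function(ang) {
      v <- c(sin(ang[1]) * cos(ang[2]), sin(ang[1]) * sin(ang[2]),
             cos(ang[1]))
      -rayleigh_quotient(v, sc)
    }
    opt <- stats::optim(c(g$theta[best], g$phi[best]), f,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 2000))
    v <- c(sin(opt$par[1]) * cos(opt$par[2]),
           sin(opt$par[1]) * sin(opt$par[2]), cos(opt$par[1]))
  }
  v / sqrt(sum(v^2))
}

# angle between two directions, sign-agnostic, in degrees
angle_deg <- function(u, v) {
  cosang <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, cosang)) * 180 / pi
}

# random labelled instance with guaranteed class sizes >= 2
random_instance <- function(n, d, n_classes) {
  centers <- matrix(stats::rnorm(n_classes * d, sd = 2), n_classes, d)
  base <- rep(seq_len(n_classes), each = 2L)
  labels <- c(base, sample(seq_len(n_classes), n - length(base),
                           replace = TRUE))
  points <- centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * d), n, d)
  # spread the axes so standardization is non-trivial
  points <- sweep(points, 2L, stats::runif(d, 0.5, 3), "*")
  list(points = points, labels = factor(paste0("c", labels)))
}

random_rotation <- function(d) {
  qrd <- qr(matrix(stats::rnorm(d * d), d, d))
  q <- qr.Q(qrd)
  q * sign(diag(qr.R(qrd)))[col(q)]
}
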