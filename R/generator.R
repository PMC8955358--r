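#' Parametric description of one synthetic cell population
#'
#' A cluster is either multivariate normal (`shape_alpha = 0`) or multivariate
#' skew-normal with shape parameter \eqn{\alpha} applied along the x axis.
#' Left skew is realised by mirroring a positive-\eqn{\alpha} sample, never by
#' a negative shape parameter, so the two directions are exactly
#' distribution-symmetric.
#'
#' @param mean mean vector (channel intensity units, arbitrary scale).
#' @param covariance symmetric positive-definite covariance matrix.
#' @param shape_alpha nonnegative skew-normal shape parameter \eqn{\alpha};
#'   0 gives a normal cluster.
#' @param skew_side `"right"` or `"left"`.
#' @param size number of events to draw.
#' @return object of class `cluster_model`.
#' @export
cluster_model <- function(mean, covariance, shape_alpha = 0,
                          skew_side = c("right", "left"), size = 1000L) {
  skew_side <- match.arg(skew_side)
  mean <- as.numeric(mean)
  covariance <- as.matrix(covariance)
  check_spd(covariance)
  if (length(mean) != nrow(covariance))
    cb_stop("invalid_model", "mean length must match covariance dimension")
  if (shape_alpha < 0)
    cb_stop("invalid_model", "shape_alpha must be >= 0 (use skew_side for left skew)")
  size <- as.integer(size)
  if (size < 1L) cb_stop("invalid_model", "size must be >= 1")
  structure(list(mean = mean, covariance = covariance,
                 shape_alpha = shape_alpha, skew_side = skew_side,
                 size = size),
            class = "cluster_model")
}

#' Random covariance matrix with a controlled eigenvalue range
#'
#' Draws eigenvalues uniformly in `[eig_low, eig_high]` and a uniformly random
#' rotation (QR orthonormalisation of a Gaussian matrix with the sign of the
#' R diagonal fixed), returning \eqn{Q \Lambda Q^\top}.  The eigenvalue range
#' controls the spread of cluster diameters and shapes in generated datasets.
#'
#' @param dim dimension (number of channels).
#' @param eig_low,eig_high eigenvalue bounds, `0 < eig_low <= eig_high`.
#' @param rng_seed optional integer seed; `NULL` uses the current RNG stream.
#' @return `dim` x `dim` SPD matrix.
#' @export
random_covariance <- function(dim, eig_low = 1, eig_high = 5, rng_seed = NULL) {
  if (!(dim >= 1) || !(eig_low > 0) || eig_low > eig_high)
    cb_stop("invalid_argument", "need dim >= 1 and 0 < eig_low <= eig_high")
  with_seed(rng_seed, {
    lam <- stats::runif(dim, eig_low, eig_high)
    qr_ <- qr(matrix(stats::rnorm(dim * dim), dim, dim))
    Q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))), dim)
    S <- Q %*% diag(lam, dim) %*% t(Q)
    (S + t(S)) / 2
  })
}

#' Sample a multivariate normal cluster
#'
#' @param model a [cluster_model()] with `shape_alpha = 0`.
#' @inheritParams random_covariance
#' @return `model$size` x dim numeric event matrix.
#' @export
sample_normal_cluster <- function(model, rng_seed = NULL) {
  stopifnot(inherits(model, "cluster_model"))
  if (model$shape_alpha != 0)
    cb_stop("invalid_argument",
            "model has shape_alpha > 0; use sample_skew_normal_cluster")
  d <- length(model$mean)
  with_seed(rng_seed, {
    Z <- matrix(stats::rnorm(model$size * d), model$size, d)
    sweep(Z %*% chol(model$covariance), 2L, model$mean, "+")
  })
}

# delta parameter induced by an x-axis shape vector (alpha, 0, ..., 0)
sn_delta <- function(alpha) alpha / sqrt(1 + alpha^2)

#' Sample a multivariate skew-normal cluster
#'
#' Uses the conditioning stochastic representation of the skew-normal: with
#' correlation-scale matrix \eqn{\bar\Omega} from `model$covariance` and shape
#' vector \eqn{(\alpha, 0, \ldots, 0)}, draw \eqn{(X_0, X)} jointly Gaussian
#' with \eqn{\mathrm{cor}(X_0, X_j) = \delta_j},
#' \eqn{\delta = \bar\Omega\alpha / \sqrt{1 + \alpha^\top\bar\Omega\alpha}},
#' and set \eqn{Z = X} if \eqn{X_0 > 0}, else \eqn{-X}.  Events are scaled by
#' \eqn{\omega = \sqrt{\mathrm{diag}(\Sigma)}} and location-shifted so the
#' theoretical mean equals `model$mean` (the skew-normal mean offset
#' \eqn{\omega\delta\sqrt{2/\pi}} is subtracted).  `skew_side = "left"`
#' mirrors the x coordinate about the theoretical mean.
#'
#' @param model a [cluster_model()] with `shape_alpha > 0`.
#' @inheritParams random_covariance
#' @return `model$size` x dim numeric event matrix.
#' @export
sample_skew_normal_cluster <- function(model, rng_seed = NULL) {
  stopifnot(inherits(model, "cluster_model"))
  if (model$shape_alpha <= 0)
    cb_stop("invalid_argument",
            "model has shape_alpha = 0; use sample_normal_cluster")
  d <- length(model$mean)
  omega <- sqrt(diag(model$covariance))
  Obar <- model$covariance / tcrossprod(omega)
  av <- c(model$shape_alpha, rep(0, d - 1L))
  delta <- as.numeric(Obar %*% av) / sqrt(1 + drop(av %*% Obar %*% av))
  C <- rbind(c(1, delta), cbind(delta, Obar))
  with_seed(rng_seed, {
    W <- matrix(stats::rnorm(model$size * (d + 1L)), model$size, d + 1L) %*%
      chol(C)
    Z <- W[, -1L, drop = FALSE] * sign(W[, 1L])
    xi <- model$mean - omega * delta * sqrt(2 / pi)
    Y <- sweep(sweep(Z, 2L, omega, "*"), 2L, xi, "+")
    if (model$skew_side == "left") Y[, 1L] <- 2 * model$mean[1L] - Y[, 1L]
    Y
  })
}

#' Restore the pre-skew width of a skewed cluster
#'
#' Skewing contracts the x marginal: its variance falls by the factor
#' \eqn{1 - 2\delta^2/\pi}, \eqn{\delta = \alpha/\sqrt{1+\alpha^2}}.  This
#' multiplies the mean-centered x coordinates by the inverse square root of
#' that factor, restoring the x variance the cluster would have had unskewed.
#' Skewness is invariant under positive affine maps, so the shape of the
#' asymmetry is untouched.
#'
#' @param points event matrix.
#' @param shape_alpha the positive shape parameter the cluster was drawn with.
#' @return rescaled event matrix.
#' @export
rescale_to_preskew_width <- function(points, shape_alpha) {
  stopifnot(shape_alpha > 0)
  points <- as.matrix(points)
  s <- 1 / sqrt(1 - 2 * sn_delta(shape_alpha)^2 / pi)
  cx <- mean(points[, 1L])
  points[, 1L] <- cx + (points[, 1L] - cx) * s
  points
}

# closed-form skewness of the skew-normal x marginal
sn_skewness <- function(alpha) {
  d <- sn_delta(alpha)
  (4 - pi) / 2 * (d * sqrt(2 / pi))^3 / (1 - 2 * d^2 / pi)^1.5
}

#' Moment-ratio sample skewness
#'
#' \eqn{g_1 = m_3 / m_2^{3/2}} with central sample moments.  Invariant under
#' positive affine transformations, negated by mirroring.
#'
#' @param values numeric vector, at least 3 values with nonzero variance.
#' @return scalar skewness.
#' @export
sample_skewness <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L)
    cb_stop("degenerate_input", "need at least 3 values")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) cb_stop("degenerate_input", "constant input has no skewness")
  mean((values - m)^3) / m2^1.5
}
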