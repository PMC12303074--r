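#' Ornstein-Uhlenbeck Gaussian prior
#'
#' Gaussian prior with exponential covariance
#' `Gamma = sigma^2 * Xi`, `Xi_ij = exp(-||r_i - r_j|| / tau)`, which
#' promotes local spatial correlation while still admitting sharp contrast.
#' Because `Xi` is shared by every field defined on the same pixel set, the
#' Cholesky factor `R = chol(Xi)` (upper triangular, `Xi = R'R`) is stored
#' once; the whitening operator is `L = R^{-T} / sigma`, so that
#' `L'L = Gamma^{-1}` as required by the penalised least-squares objective.
#'
#' @param pixel_coords N x 2 matrix of pixel-centre coordinates (metres), or
#'   a `pat_grid` (target-domain pixels are used).
#' @param sigma marginal standard deviation (parameter units).
#' @param tau characteristic length scale, metres.
#' @param mean prior mean: a scalar (broadcast) or a field of length N.
#' @return object of class `pat_ou_prior` with elements `mean`, `sigma`,
#'   `tau`, `coords`, `chol_xi`.
#' @export
build_ou_prior <- function(pixel_coords, sigma, tau, mean = 0) {
  if (inherits(pixel_coords, "pat_grid")) {
    cc <- grid_coords(pixel_coords, "target")
    pixel_coords <- as.matrix(expand.grid(x = cc$x, y = cc$y))
  }
  if (sigma <= 0 || tau <= 0) stop("sigma and tau must be positive")
  n <- nrow(pixel_coords)
  xi <- exp(-as.matrix(stats::dist(pixel_coords)) / tau)
  ch <- tryCatch(chol(xi), error = function(e) {
    stop(sprintf(
      "unit covariance factorisation failed for N = %d, tau = %.3g m: %s",
      n, tau, conditionMessage(e)))
  })
  structure(list(mean = rep_len(as.vector(mean), n), sigma = sigma, tau = tau,
                 n = n, coords = pixel_coords, chol_xi = ch),
            class = "pat_ou_prior")
}

#' @export
print.pat_ou_prior <- function(x, ...) {
  cat(sprintf("<pat_ou_prior> N = %d, sigma = %.4g, tau = %.4g mm\n",
              x$n, x$sigma, x$tau * 1e3))
  invisible(x)
}

# Whitening: L z = R^{-T} z / sigma, with Xi = R'R
ou_whiten <- function(prior, z) {
  backsolve(prior$chol_xi, z, transpose = TRUE) / prior$sigma
}

# Gamma^{-1} z = R^{-1} R^{-T} z / sigma^2
ou_precision_apply <- function(prior, z) {
  backsolve(prior$chol_xi,
            backsolve(prior$chol_xi, z, transpose = TRUE)) / prior$sigma^2
}

#' Prior standard deviation from the true parameter range
#'
#' Rule used throughout the study design: a quarter of the true value range,
#' so that roughly 95% of prior mass lies within the range.
#'
#' @param z_true_min,z_true_max extreme true parameter values.
#' @return standard deviation `(max - min) / 4`.
#' @export
choose_sigma <- function(z_true_min, z_true_max) {
  if (z_true_max <= z_true_min) stop("max must exceed min")
  (z_true_max - z_true_min) / 4
}

#' Prior energy of a field
#'
#' `0.5 * || L (z - mean) ||^2`, one of the regularising terms of the
#' reconstruction objective.
#'
#' @param z field (vector or matrix with N elements).
#' @param prior a `pat_ou_prior`.
#' @return scalar energy.
#' @export
prior_energy <- function(z, prior) {
  z <- as.vector(z)
  if (length(z) != prior$n) stop("field dimension does not match prior")
  0.5 * sum(ou_whiten(prior, z - prior$mean)^2)
}

#' Gradient of the prior energy
#'
#' `Gamma^{-1} (z - mean)`.
#'
#' @inheritParams prior_energy
#' @return vector of length N.
#' @export
prior_gradient <- function(z, prior) {
  z <- as.vector(z)
  if (length(z) != prior$n) stop("field dimension does not match prior")
  as.vector(ou_precision_apply(prior, z - prior$mean))
}

#' Draw samples from an OU prior
#'
#' @param prior a `pat_ou_prior`.
#' @param n_samples number of fields to draw.
#' @return N x n_samples matrix.
#' @export
sample_ou_prior <- function(prior, n_samples = 1L) {
  w <- matrix(stats::rnorm(prior$n * n_samples), prior$n)
  prior$mean + prior$sigma * crossprod(prior$chol_xi, w)
}

#' Additive Gaussian noise model
#'
#' Zero-mean white noise with scalar standard deviation per dataset; the
#' data-weighting operator is `L_e = I / sigma_e`.
#'
#' @param sigma_e noise standard deviation, Pa.
#' @return object of class `pat_noise_model`.
#' @export
make_noise_model <- function(sigma_e) {
  if (sigma_e <= 0) stop("sigma_e must be positive")
  structure(list(mean = 0, sigma_e = sigma_e), class = "pat_noise_model")
}

#' Estimate the noise standard deviation from recorded data
#'
#' A stated fraction of the peak-to-peak amplitude of the (noisy) dataset,
#' as a single scalar per dataset.
#'
#' @param y_noisy a `pat_sensor_data` or numeric matrix.
#' @param level fraction of peak-to-peak amplitude (e.g. 0.01 for 1%).
#' @return standard deviation (Pa).
#' @export
estimate_noise_std <- function(y_noisy, level = 0.01) {
  if (level <= 0) stop("level must be positive")
  y <- if (inherits(y_noisy, "pat_sensor_data")) y_noisy$y else y_noisy
  ptp <- max(y) - min(y)
  if (ptp == 0) stop("constant data: peak-to-peak amplitude is zero")
  level * ptp
}
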