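#' Acoustic medium
#'
#' @param c speed-of-sound field over the full grid (m/s), a matrix of size
#'   `n_total` x `n_total`, or a scalar for a homogeneous medium.
#' @param grid a `pat_grid`.
#' @param c_ref scalar reference speed for the k-space correction; defaults
#'   to `max(c)`, which keeps the corrected scheme stable.
#' @return object of class `pat_medium`.
#' @export
make_medium <- function(c, grid, c_ref = NULL) {
  if (length(c) == 1L) c <- matrix(c, grid$n_total, grid$n_total)
  stopifnot(nrow(c) == grid$n_total, ncol(c) == grid$n_total)
  if (any(c <= 0)) stop("speed of sound must be positive everywhere")
  if (is.null(c_ref)) c_ref <- max(c)
  if (c_ref < max(c)) {
    warning("c_ref below max(c): the k-space corrected scheme may be unstable")
  }
  structure(list(c = c, c_ref = c_ref), class = "pat_medium")
}

# Precompute spectral multipliers and PML factors for the stepper.
ks_prepare <- function(medium, grid, pml = NULL) {
  n <- grid$n_total
  if (is.null(pml)) pml <- make_pml(grid)
  wn <- make_wavenumbers(grid)
  kappa <- k_sinc(medium$c_ref * wn$k * grid$dt / 2)
  kx <- wn$kx
  ky <- wn$ky
  if (n %% 2 == 0) {
    nyq <- n %/% 2 + 1L
    kx[nyq, ] <- 0   # zero odd-symmetry-breaking Nyquist components
    ky[, nyq] <- 0
  }
  ikx <- 1i * kx * kappa
  iky <- 1i * ky * kappa
  # absorption rate alpha * c_ref / dx (Np/s), applied as exp(-a dt/2) twice
  sxv <- exp(-pml$alpha * medium$c_ref / grid$dx * grid$dt / 2)
  list(ikx = ikx, iky = iky,
       sx = matrix(sxv, n, n),
       sy = matrix(sxv, n, n, byrow = TRUE),
       c2 = medium$c^2)
}

k_sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)

check_stability <- function(medium, grid) {
  cfl <- max(medium$c) * grid$dt / grid$dx
  if (cfl > 1) {
    stop(sprintf(
      "stability bound violated: c_max * dt / dx = %.3f exceeds 1", cfl))
  }
  invisible(cfl)
}

#' Simulate photoacoustic wave propagation
#'
#' Solves the initial value problem for the 2D wave equation in a
#' heterogeneous non-absorbing medium with the k-space pseudo-spectral
#' scheme: initial pressure `p0`, zero initial pressure rate, sensor traces
#' recorded at every time step (including `t = 0`).
#'
#' @param medium a `pat_medium`.
#' @param p0 initial pressure on the target domain (`n_interior` square
#'   matrix; zero-padded into the margins) or on the full grid.
#' @param grid a `pat_grid`.
#' @param sensors a `pat_sensors` object, or `NULL` to record no traces.
#' @param record_full if `TRUE`, also store the full spatio-temporal
#'   pressure field and the density history needed for speed-of-sound
#'   gradients.
#' @param pml optional `pat_pml` (defaults to `make_pml(grid)`).
#' @return object of class `pat_sensor_data` when `record_full = FALSE`;
#'   otherwise a list with elements `data` (the sensor data) and `field`
#'   (a `pat_pressure_field` carrying the stored histories).
#' @export
simulate_forward <- function(medium, p0, grid, sensors, record_full = FALSE,
                             pml = NULL) {
  check_stability(medium, grid)
  if (nrow(p0) == grid$n_interior) p0 <- embed_field(p0, grid)
  stopifnot(nrow(p0) == grid$n_total, ncol(p0) == grid$n_total)
  op <- ks_prepare(medium, grid, pml)
  sidx <- if (is.null(sensors)) integer(0) else sensor_linear_index(sensors, grid)
  res <- ks_forward_cpp(p0, op$c2, op$ikx, op$iky, op$sx, op$sy,
                        sidx, grid$nt, grid$dt,
                        record_rho = record_full, record_p = record_full,
                        u0x = matrix(0, 1, 1), u0y = matrix(0, 1, 1),
                        use_u0 = FALSE)
  data <- new_sensor_data(res$y, grid)
  if (!record_full) return(data)
  field <- structure(list(p_hist = res$p_hist, rho_hist = res$rho_hist,
                          grid = grid),
                     class = "pat_pressure_field")
  list(data = data, field = field)
}

new_sensor_data <- function(y, grid, dataset = 1L) {
  structure(list(y = y, dx = grid$dx, dt = grid$dt, nt = ncol(y),
                 dataset = as.integer(dataset)),
            class = "pat_sensor_data")
}

#' @export
print.pat_sensor_data <- function(x, ...) {
  cat(sprintf("<pat_sensor_data> %d sensors x %d samples (dt = %.4g ns)\n",
              nrow(x$y), x$nt, x$dt * 1e9))
  invisible(x)
}

# Low-level stepper access with an explicit initial state; used by the
# time-reversal diagnostics.  u0x/u0y are the staggered velocities half a
# step before t = 0.
ks_step_state <- function(medium, grid, p_init, u0x, u0y, sensors = NULL,
                          pml = NULL, record_p = FALSE) {
  op <- ks_prepare(medium, grid, pml)
  sidx <- if (is.null(sensors)) integer(0) else sensor_linear_index(sensors, grid)
  ks_forward_cpp(p_init, op$c2, op$ikx, op$iky, op$sx, op$sy, sidx,
                 grid$nt, grid$dt, record_rho = FALSE, record_p = record_p,
                 u0x = u0x, u0y = u0y, use_u0 = TRUE)
}

#' Second time derivative of a recorded pressure field
#'
#' Centred second differences at interior samples, second-order one-sided
#' stencils at the first and last samples.  Exact for fields quadratic in
#' time.
#'
#' @param p_hist matrix with one column per time sample (pixels x nt), or a
#'   `pat_pressure_field`.
#' @param dt time step (taken from the field if omitted).
#' @return matrix of the same shape containing the second time derivative.
#' @export
second_time_derivative <- function(p_hist, dt = NULL) {
  if (inherits(p_hist, "pat_pressure_field")) {
    if (is.null(dt)) dt <- p_hist$grid$dt
    p_hist <- p_hist$p_hist
  }
  nt <- ncol(p_hist)
  if (nt < 3) stop("at least 3 time samples are required")
  if (is.null(dt)) stop("dt must be supplied")
  d2 <- p_hist
  d2[, 2:(nt - 1)] <- p_hist[, 1:(nt - 2)] - 2 * p_hist[, 2:(nt - 1)] +
    p_hist[, 3:nt]
  # one-sided second-order stencils: f0'' ~ 2f0 - 5f1 + 4f2 - f3
  d2[, 1] <- 2 * p_hist[, 1] - 5 * p_hist[, 2] + 4 * p_hist[, 3] - p_hist[, 4]
  d2[, nt] <- 2 * p_hist[, nt] - 5 * p_hist[, nt - 1] + 4 * p_hist[, nt - 2] -
    p_hist[, nt - 3]
  d2 / dt^2
}

#' Extract sensor traces from a stored pressure field
#'
#' Pure bookkeeping: rows of the recorded field at the sensor nodes, no
#' interpolation.
#'
#' @param field a `pat_pressure_field` (with `p_hist`).
#' @param sensors a `pat_sensors` object whose nodes lie on the field's grid.
#' @return a `pat_sensor_data`.
#' @export
sample_sensors <- function(field, sensors) {
  grid <- field$grid
  if (any(sensors$ix < 1 | sensors$ix > grid$n_total |
          sensors$iy < 1 | sensors$iy > grid$n_total)) {
    stop("sensor off grid")
  }
  idx <- sensor_linear_index(sensors, grid) + 1L
  new_sensor_data(field$p_hist[idx, , drop = FALSE], grid)
}

#' Export sensor data to CSV
#'
#' Long-format export (`sensor`, `time_s`, `pressure`) for small cases.
#'
#' @param data a `pat_sensor_data`.
#' @param path output file path.
#' @export
write_sensor_csv <- function(data, path) {
  nt <- ncol(data$y)
  df <- data.frame(
    sensor = rep(seq_len(nrow(data$y)), times = nt),
    time_s = rep((seq_len(nt) - 1) * data$dt, each = nrow(data$y)),
    pressure = as.vector(data$y))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
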