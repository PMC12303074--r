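#' Computational grid for the acoustic problem
#'
#' Defines the spatial and temporal discretisation used by the wave solver.
#' The full computational domain is a square of
#' `n_interior + 2 * n_sensor_margin + 2 * n_pml` pixels per side: the target
#' domain of `n_interior` pixels is surrounded first by a sensor band (where
#' the point-like detectors live) and then by a perfectly matched layer that
#' absorbs outgoing waves.  Physical coordinates place pixel centres at
#' `(i - 1/2) * dx` with the origin at the corner of the target domain, so
#' margin pixels have negative coordinates.  All lengths are metres, times
#' seconds.
#'
#' @param n_interior pixels per side of the target domain.
#' @param dx pixel size in metres.
#' @param n_sensor_margin pixels added outside the target on each side for
#'   the sensor band.
#' @param n_pml pixels of perfectly matched layer on each side, outside the
#'   sensor band.
#' @param dt time step in seconds.
#' @param nt number of time samples (the horizon is `T = (nt - 1) * dt`).
#' @return An object of class `pat_grid`.
#' @export
make_grid <- function(n_interior, dx, n_sensor_margin = 0L, n_pml = 0L,
                      dt = 1, nt = 2L) {
  if (n_interior < 1 || dx <= 0 || n_sensor_margin < 0 || n_pml < 0 ||
      dt <= 0 || nt < 2) {
    stop("invalid grid configuration: counts must be positive, dx/dt > 0, nt >= 2")
  }
  g <- list(
    n_interior = as.integer(n_interior),
    dx = dx,
    n_sensor_margin = as.integer(n_sensor_margin),
    n_pml = as.integer(n_pml),
    dt = dt,
    nt = as.integer(nt),
    n_total = as.integer(n_interior + 2L * (n_sensor_margin + n_pml)),
    offset = as.integer(n_sensor_margin + n_pml)
  )
  g$extent <- g$n_interior * dx           # target-domain side length
  g$t_end <- (g$nt - 1L) * dt
  class(g) <- "pat_grid"
  g
}

#' @export
print.pat_grid <- function(x, ...) {
  cat(sprintf(
    "<pat_grid> %d px target (+%d sensor, +%d PML per side), dx = %.4g um, dt = %.4g ns, nt = %d (T = %.3g us)\n",
    x$n_interior, x$n_sensor_margin, x$n_pml, x$dx * 1e6, x$dt * 1e9, x$nt,
    x$t_end * 1e6))
  invisible(x)
}

#' Physical coordinates of pixel centres
#'
#' @param grid a `pat_grid`.
#' @param region `"full"` for the whole computational grid, `"target"` for
#'   the interior target domain only.
#' @return list with vectors `x`, `y` of pixel-centre coordinates (metres).
#' @export
grid_coords <- function(grid, region = c("full", "target")) {
  region <- match.arg(region)
  n <- if (region == "full") grid$n_total else grid$n_interior
  off <- if (region == "full") grid$offset else 0L
  v <- ((seq_len(n) - off) - 0.5) * grid$dx
  list(x = v, y = v)
}

#' Index range of the target domain within the full grid
#' @param grid a `pat_grid`.
#' @return integer vector of indices (applies to both axes).
#' @export
target_indices <- function(grid) {
  grid$offset + seq_len(grid$n_interior)
}

#' Embed a target-domain field into the full computational grid
#'
#' @param field `n_interior` x `n_interior` matrix.
#' @param grid a `pat_grid`.
#' @param fill value for margin and PML pixels.
#' @return `n_total` x `n_total` matrix.
#' @export
embed_field <- function(field, grid, fill = 0) {
  stopifnot(nrow(field) == grid$n_interior, ncol(field) == grid$n_interior)
  full <- matrix(fill, grid$n_total, grid$n_total)
  idx <- target_indices(grid)
  full[idx, idx] <- field
  full
}

#' Restrict a full-grid field to the target domain
#' @param field full-grid matrix.
#' @param grid a `pat_grid`.
#' @return `n_interior` x `n_interior` matrix.
#' @export
extract_target <- function(field, grid) {
  idx <- target_indices(grid)
  field[idx, idx]
}

#' Maximum frequency supported by a grid
#'
#' The shortest resolvable wavelength on a grid of spacing `dx` is `2 dx`,
#' so the highest temporal frequency a wave travelling at `c_min` can carry
#' is `c_min / (2 dx)`.
#'
#' @param grid a `pat_grid` (or anything with a `dx` field).
#' @param c_min slowest speed of sound in the medium, m/s.
#' @return frequency in Hz.
#' @export
max_supported_frequency <- function(grid, c_min) {
  if (c_min <= 0) stop("c_min must be positive")
  c_min / (2 * grid$dx)
}

#' FFT-ordered angular wavenumber fields
#'
#' @param grid a `pat_grid`.
#' @return list with matrices `kx`, `ky` (rad/m, varying along rows and
#'   columns respectively) and the magnitude `k`.
#' @export
make_wavenumbers <- function(grid) {
  n <- grid$n_total
  kvec <- 2 * pi * fft_freq(n, grid$dx)
  kx <- matrix(kvec, n, n)
  ky <- matrix(kvec, n, n, byrow = TRUE)
  list(kx = kx, ky = ky, k = sqrt(kx^2 + ky^2))
}

# DFT sample frequencies (cycles per metre), FFT ordering.
fft_freq <- function(n, dx) {
  i <- seq_len(n) - 1L
  f <- ifelse(i <= n %/% 2, i, i - n)
  if (n %% 2 == 0) f[n %/% 2 + 1L] <- -(n %/% 2)  # Nyquist as negative freq
  f / (n * dx)
}

#' Place point sensors on a square contour around the target
#'
#' Sensors are distributed as evenly as possible along the four sides of a
#' square contour at distance `inset` outside the target boundary, then
#' snapped to the nearest grid nodes inside the sensor band.  With a count
#' divisible by four each side receives `count / 4` sensors; corners are not
#' duplicated.
#'
#' @param grid a `pat_grid` with a sensor margin.
#' @param count number of sensors (>= 4).
#' @param inset distance of the contour outside the target boundary, metres.
#' @return object of class `pat_sensors` with fields `ix`, `iy` (1-based full
#'   grid indices), `x`, `y` (snapped physical coordinates) and `count`.
#' @export
place_sensors <- function(grid, count, inset) {
  if (count < 4) stop("at least 4 sensors are required")
  band <- grid$n_sensor_margin * grid$dx
  if (inset < 0 || inset > band) {
    stop(sprintf("sensor inset %.3g m outside the sensor band [0, %.3g m]",
                 inset, band))
  }
  L <- grid$extent
  lo <- -inset
  hi <- L + inset

  per_side <- rep(count %/% 4L, 4L)
  extra <- count %% 4L
  if (extra > 0) per_side[seq_len(extra)] <- per_side[seq_len(extra)] + 1L

  side_pts <- function(m, fixed, axis) {
    # m points strictly inside (lo, hi) so that corners are never duplicated
    s <- lo + (seq_len(m) - 0.5) * (hi - lo) / m
    if (axis == "x") cbind(x = s, y = rep(fixed, m))
    else cbind(x = rep(fixed, m), y = s)
  }
  pts <- rbind(
    side_pts(per_side[1L], lo, "x"),   # bottom
    side_pts(per_side[2L], hi, "x"),   # top
    side_pts(per_side[3L], lo, "y"),   # left
    side_pts(per_side[4L], hi, "y")    # right
  )

  cc <- grid_coords(grid, "full")
  snap <- function(v) vapply(v, function(p) which.min(abs(cc$x - p)), integer(1))
  ix <- snap(pts[, "x"])
  iy <- snap(pts[, "y"])
  key <- paste(ix, iy)
  if (anyDuplicated(key)) {
    stop("sensor snapping produced duplicate nodes; reduce count or refine the grid")
  }
  structure(list(ix = ix, iy = iy, x = cc$x[ix], y = cc$y[iy],
                 count = as.integer(count)),
            class = "pat_sensors")
}

#' @export
print.pat_sensors <- function(x, ...) {
  cat(sprintf("<pat_sensors> %d point sensors\n", x$count))
  invisible(x)
}

# 0-based linear (column-major) indices of sensor nodes on the full grid
sensor_linear_index <- function(sensors, grid) {
  as.integer((sensors$ix - 1L) + (sensors$iy - 1L) * grid$n_total)
}

#' Polynomial PML absorption profile
#'
#' Dimensionless per-axis absorption coefficient ramps, zero over the target
#' and sensor regions and rising polynomially to `peak` at the outer
#' boundary.  The wave solver scales the profile by `c_ref / dx` to obtain an
#' absorption rate in nepers per second.
#'
#' @param grid a `pat_grid`.
#' @param order polynomial order of the ramp (>= 1).
#' @param peak peak dimensionless absorption coefficient (>= 0).
#' @return object of class `pat_pml` with the per-axis profile vector
#'   `alpha` (length `n_total`; both axes share it by symmetry).
#' @export
make_pml <- function(grid, order = 4L, peak = 2) {
  if (order < 1 || peak < 0) stop("PML order must be >= 1 and peak >= 0")
  n <- grid$n_total
  alpha <- numeric(n)
  np <- grid$n_pml
  if (np > 0) {
    depth <- seq_len(np) / np                 # innermost -> outermost
    ramp <- peak * depth^order
    alpha[np:1] <- ramp                        # left/bottom edge
    alpha[(n - np + 1L):n] <- ramp             # right/top edge
  }
  structure(list(alpha = alpha, order = as.integer(order), peak = peak),
            class = "pat_pml")
}
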