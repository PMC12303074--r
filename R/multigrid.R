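#' Bilinear prolongation of a target-domain field between grids
#'
#' Interpolates on physical pixel-centre coordinates; both grids must cover
#' the same physical target extent.  Bilinear interpolation is exact for
#' fields linear in the coordinates and preserves values at coincident
#' pixel centres; fine-grid centres outside the coarse centre lattice are
#' clamped to the nearest coarse row/column (constant extrapolation).
#'
#' @param field matrix on the source grid's target domain.
#' @param from,to `pat_grid` objects sharing the physical target extent.
#' @return matrix on the destination grid's target domain.
#' @export
prolong_field <- function(field, from, to) {
  if (abs(from$extent - to$extent) > 0.05 * from$extent) {
    stop("grids differ in physical extent")
  }
  stopifnot(nrow(field) == from$n_interior, ncol(field) == from$n_interior)
  src <- grid_coords(from, "target")$x
  dst <- grid_coords(to, "target")$x
  interp_axis <- function(coord) {
    j <- findInterval(coord, src, all.inside = TRUE)
    w <- (coord - src[j]) / (src[j + 1] - src[j])
    w <- pmin(pmax(w, 0), 1)   # clamp beyond outermost centres
    list(j = j, w = w)
  }
  ax <- interp_axis(dst)
  # rows then columns (separable bilinear)
  tmp <- (1 - ax$w) * field[ax$j, , drop = FALSE] +
    ax$w * field[ax$j + 1, , drop = FALSE]
  out <- tmp[, ax$j, drop = FALSE] %*% diag(1 - ax$w, length(dst)) +
    tmp[, ax$j + 1, drop = FALSE] %*% diag(ax$w, length(dst))
  out
}

#' Resample sensor data onto a new time axis
#'
#' Per-sensor linear interpolation in time onto `nt_new` samples of spacing
#' `dt_new`.  By default the traces are first low-pass filtered at a stated
#' cutoff (forward-backward Butterworth) so that frequencies unsupported by
#' a coarse reconstruction grid do not alias.
#'
#' @param data a `pat_sensor_data`.
#' @param dt_new new time step, seconds.
#' @param nt_new number of new samples; the new horizon must fit inside the
#'   recorded one.
#' @param lowpass_hz cutoff frequency in Hz, or `NULL` to skip filtering.
#' @return a `pat_sensor_data` on the new axis.
#' @export
resample_data_time <- function(data, dt_new, nt_new, lowpass_hz = NULL) {
  t_old <- (seq_len(data$nt) - 1) * data$dt
  t_new <- (seq_len(nt_new) - 1) * dt_new
  if (max(t_new) > max(t_old) + 1e-12 * data$dt) {
    stop("new time axis exceeds the recorded horizon")
  }
  y <- data$y
  if (!is.null(lowpass_hz)) {
    fnyq <- 1 / (2 * data$dt)
    wc <- lowpass_hz / fnyq
    if (wc < 1) {
      bf <- signal::butter(4, wc, type = "low")
      y <- t(apply(y, 1, function(tr) signal::filtfilt(bf, tr)))
    }
  }
  if (identical(t_old, t_new)) {
    out <- y
  } else {
    out <- t(apply(y, 1, function(tr) {
      stats::approx(t_old, tr, xout = t_new)$y
    }))
  }
  structure(list(y = out, dx = data$dx, dt = dt_new, nt = as.integer(nt_new),
                 dataset = data$dataset),
            class = "pat_sensor_data")
}

#' Level schedule for multigrid continuation
#'
#' @param grids list of `pat_grid` objects ordered coarse to fine (strictly
#'   decreasing `dx`); each level may carry its own optimizer settings.
#' @param optimizer list (or list of per-level lists) of arguments passed to
#'   [minimize()] (`max_iter`, `tol`, `memory`, ...).
#' @return object of class `pat_schedule`.
#' @export
make_schedule <- function(grids, optimizer = list()) {
  dxs <- vapply(grids, function(g) g$dx, numeric(1))
  if (any(diff(dxs) >= 0)) stop("level dx must be strictly decreasing (coarse to fine)")
  per_level <- if (length(optimizer) && is.list(optimizer[[1]])) optimizer
  else rep(list(optimizer), length(grids))
  if (length(per_level) != length(grids)) stop("one optimizer setting per level required")
  structure(list(grids = grids, optimizer = per_level), class = "pat_schedule")
}

#' Initial guess for the joint reconstruction
#'
#' Zero initial pressures and the prior-mean speed of sound.
#'
#' @param prior_c the speed-of-sound `pat_ou_prior` on the level's pixels.
#' @param I number of datasets.
#' @return packed unknown vector.
#' @export
initial_guess <- function(prior_c, I) {
  N <- prior_c$n
  c(rep(0, I * N), rep_len(prior_c$mean, N))
}

#' Coarse-to-fine multigrid reconstruction
#'
#' For each level: rebuild the OU priors on that level's pixel set (same
#' sigma and physical tau), resample the data onto the level's time axis
#' (low-passed at the level's maximum supported frequency by default),
#' minimise the objective with projected L-BFGS, then bilinearly prolong
#' the estimates to the next level as its initial guess.  The L-BFGS
#' history is grid-specific and resets at each level.  Schedules whose
#' level `dx` coincides with the data-simulation `dx` are refused (inverse
#' crime) unless `allow_inverse_crime = TRUE`.
#'
#' @param schedule a `pat_schedule`.
#' @param data list of I `pat_sensor_data` recorded on the simulation grid.
#' @param sensor_spec list with `count` and `inset` used to place sensors on
#'   every level grid.
#' @param prior_spec list with `sigma_p0`, `mean_p0`, `sigma_c`, `mean_c`,
#'   `tau` (SI units).
#' @param noise list of I `pat_noise_model` (or length 1, recycled).
#' @param bounds_spec list with `c_lower`, `c_upper` (p0 is bounded below by
#'   zero).
#' @param x_init optional packed start vector on the coarsest level
#'   (defaults to [initial_guess()]).
#' @param data_dx pixel size of the data-simulation grid (for the
#'   inverse-crime check); taken from `data[[1]]$dx` when `NULL`.
#' @param lowpass low-pass data before temporal resampling (default TRUE).
#' @param allow_inverse_crime override the distinct-discretisation check.
#' @param c_ref_speed reference speed for the k-space correction and for
#'   the per-level frequency cutoff (defaults to `bounds_spec$c_lower`).
#' @param verbose print per-level progress.
#' @return object of class `pat_result`: final `p0` (list) and `c` on the
#'   finest target grid, `levels` (per-level estimates and traces), and the
#'   finest `grid`.
#' @export
run_multigrid <- function(schedule, data, sensor_spec, prior_spec, noise,
                          bounds_spec = list(c_lower = 1300, c_upper = 1800),
                          x_init = NULL, data_dx = NULL, lowpass = TRUE,
                          allow_inverse_crime = FALSE, c_ref_speed = NULL,
                          verbose = FALSE) {
  I <- length(data)
  if (length(noise) == 1L) noise <- rep(noise, I)
  if (is.null(data_dx)) data_dx <- data[[1]]$dx
  if (is.null(c_ref_speed)) c_ref_speed <- bounds_spec$c_lower
  for (g in schedule$grids) {
    if (!allow_inverse_crime && abs(g$dx - data_dx) < 1e-12) {
      stop("inverse crime: reconstruction level dx equals the data-simulation dx (set allow_inverse_crime = TRUE to override)")
    }
  }

  levels <- list()
  x <- NULL
  prev_grid <- NULL
  for (li in seq_along(schedule$grids)) {
    grid <- schedule$grids[[li]]
    sensors <- place_sensors(grid, sensor_spec$count, sensor_spec$inset)
    prior_p0 <- build_ou_prior(grid, prior_spec$sigma_p0, prior_spec$tau,
                               mean = prior_spec$mean_p0)
    prior_c <- build_ou_prior(grid, prior_spec$sigma_c, prior_spec$tau,
                              mean = prior_spec$mean_c)
    cutoff <- if (lowpass) max_supported_frequency(grid, c_ref_speed) else NULL
    dlev <- lapply(data, function(d) {
      resample_data_time(d, grid$dt, grid$nt, lowpass_hz = cutoff)
    })
    problem <- make_problem(grid, sensors, dlev, noise, prior_p0, prior_c,
                            margin_c = prior_spec$mean_c,
                            c_upper = bounds_spec$c_upper)
    bounds <- default_bounds(problem, bounds_spec$c_lower, bounds_spec$c_upper)

    if (is.null(x)) {
      x <- if (!is.null(x_init) && li == 1L) x_init else initial_guess(prior_c, I)
    }
    if (li > 1L) {
      # prolong previous level estimates
      prev_problem <- list(I = I, N = prev_grid$n_interior^2, grid = prev_grid)
      u <- unpack_unknowns(x, prev_problem)
      p0f <- lapply(u$p0, prolong_field, from = prev_grid, to = grid)
      cf <- prolong_field(u$c, from = prev_grid, to = grid)
      x <- pack_unknowns(p0f, cf)
    }
    x <- project_bounds(x, bounds)

    opts <- schedule$optimizer[[li]]
    if (verbose) message(sprintf("level %d/%d: %d px, nt = %d",
                                 li, length(schedule$grids),
                                 grid$n_interior, grid$nt))
    fit <- do.call(minimize, c(list(
      fn = function(z) evaluate_objective(z, problem)$total,
      gr = function(z) objective_with_gradient(z, problem),
      x0 = x, bounds = bounds, verbose = verbose), opts))
    x <- fit$x
    levels[[li]] <- list(grid = grid, estimate = unpack_unknowns(x, problem),
                         trace = fit$trace, status = fit$status,
                         value = fit$value)
    if (fit$status == "line_search_failure" && verbose) {
      message(sprintf("  level %d stopped on line-search failure", li))
    }
    prev_grid <- grid
  }
  final <- levels[[length(levels)]]$estimate
  structure(list(p0 = final$p0, c = final$c,
                 grid = schedule$grids[[length(schedule$grids)]],
                 levels = levels),
            class = "pat_result")
}

#' @export
print.pat_result <- function(x, ...) {
  cat(sprintf("<pat_result> %d initial pressure fields + c on %d x %d target grid (%d levels)\n",
              length(x$p0), x$grid$n_interior, x$grid$n_interior,
              length(x$levels)))
  invisible(x)
}
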