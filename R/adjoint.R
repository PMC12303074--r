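#' Assemble the weighted-residual adjoint source
#'
#' The adjoint wave problem is driven by the data residual weighted by the
#' noise precision, `S = L_e' L_e (y - f(x))`, supported on the sensor nodes.
#' Time reversal of the source is handled inside [simulate_adjoint()]; the
#' source is stored in data (forward) time order.
#'
#' @param residual a `pat_sensor_data` (or matrix) holding `y - f(x)`,
#'   sensors x time.
#' @param noise_weight a `pat_noise_model`.
#' @param sensors the `pat_sensors` the residual rows correspond to.
#' @param grid the `pat_grid` of the adjoint run.
#' @return object of class `pat_adjoint_source` with the weighted residual
#'   `v` (sensors x nt) and the sensor geometry.
#' @export
assemble_adjoint_source <- function(residual, noise_weight, sensors, grid) {
  r <- if (inherits(residual, "pat_sensor_data")) residual$y else residual
  if (nrow(r) != sensors$count || ncol(r) != grid$nt) {
    stop(sprintf("residual is %d x %d, expected %d sensors x %d samples",
                 nrow(r), ncol(r), sensors$count, grid$nt))
  }
  structure(list(v = r / noise_weight$sigma_e^2, sensors = sensors),
            class = "pat_adjoint_source")
}

#' Solve the adjoint wave problem
#'
#' Computes the action of the transpose of the forward map on the source:
#' the time-reversed weighted residual is injected at the sensor nodes and
#' propagated through the (exactly transposed) k-space recursion.  The
#' terminal snapshot equals `F' v`, the sensitivity of `<v, f(p0, c)>` with
#' respect to the initial pressure; it is the data-misfit part of the
#' initial-pressure gradient (up to sign, fixed in [gradient_p0()]) and,
#' for unweighted data, a time-reversal image of the source.
#'
#' When a forward `pat_pressure_field` recorded with `record_full = TRUE`
#' is supplied, the sweep also accumulates `dc`, the exact sensitivity of
#' `<v, f(p0, c)>` with respect to the speed of sound, pairing the stored
#' forward history with the adjoint recursion step by step (the discrete
#' counterpart of the continuous time integral of `(-2/c^3) d2p/dt2 * q`).
#'
#' @param medium a `pat_medium` (must match the forward run).
#' @param source a `pat_adjoint_source`.
#' @param grid a `pat_grid`.
#' @param record_full store the per-step adjoint pressure increments.
#' @param forward optional forward `pat_pressure_field` enabling the
#'   speed-of-sound sensitivity.
#' @param pml optional `pat_pml`.
#' @return object of class `pat_adjoint_field` with `terminal` (full-grid
#'   matrix `F' v`), optionally `dc` and `q_hist`.
#' @export
simulate_adjoint <- function(medium, source, grid, record_full = FALSE,
                             forward = NULL, pml = NULL) {
  check_stability(medium, grid)
  op <- ks_prepare(medium, grid, pml)
  sidx <- sensor_linear_index(source$sensors, grid)
  want_gc <- !is.null(forward)
  rho_hist <- if (want_gc) forward$rho_hist else matrix(0, 0, 0)
  res <- ks_backward_cpp(source$v, medium$c, op$c2, op$ikx, op$iky,
                         op$sx, op$sy, sidx, grid$dt, rho_hist,
                         want_gc = want_gc, record_q = record_full)
  structure(list(terminal = res$gp0,
                 dc = if (want_gc) res$gc else NULL,
                 q_hist = if (record_full) res$q_hist else NULL,
                 grid = grid),
            class = "pat_adjoint_field")
}
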