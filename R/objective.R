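#' Bundle a joint reconstruction problem
#'
#' Collects everything the objective and its gradients need: the grid,
#' sensors, the I observed datasets (already resampled to this grid's time
#' axis), per-dataset noise models, the OU priors for the initial pressures
#' and the speed of sound, and fixed solver settings.  The unknown vector
#' `x = (p0^1, ..., p0^I, c)` covers target-domain pixels only; margin and
#' PML pixels hold the speed of sound fixed at `margin_c` and the initial
#' pressures at zero.  The k-space reference speed `c_ref` is kept constant
#' across the optimisation so the discrete forward map does not change
#' between iterates.
#'
#' @param grid a `pat_grid` (reconstruction grid).
#' @param sensors a `pat_sensors` on that grid.
#' @param data list of I `pat_sensor_data` objects with `nt` matching `grid`.
#' @param noise list of I `pat_noise_model` objects (recycled if length 1).
#' @param prior_p0,prior_c `pat_ou_prior` objects on the target pixel set.
#' @param margin_c speed of sound held fixed outside the target domain
#'   (defaults to the c prior mean).
#' @param c_ref k-space reference speed (defaults to the upper c bound if
#'   given, else 1.3 x the prior mean).
#' @param c_upper optional upper bound used for the default `c_ref`.
#' @param pml optional `pat_pml`.
#' @return object of class `pat_problem`.
#' @export
make_problem <- function(grid, sensors, data, noise, prior_p0, prior_c,
                         margin_c = NULL, c_ref = NULL, c_upper = NULL,
                         pml = NULL) {
  I <- length(data)
  if (I < 1) stop("at least one dataset is required")
  for (d in data) {
    if (ncol(d$y) != grid$nt)
      stop("dataset time axis does not match the reconstruction grid; resample first")
    if (nrow(d$y) != sensors$count) stop("dataset sensor count mismatch")
  }
  if (length(noise) == 1L) noise <- rep(noise, I)
  N <- grid$n_interior^2
  if (prior_p0$n != N || prior_c$n != N)
    stop("priors must be built on this grid's target pixel set")
  if (is.null(margin_c)) margin_c <- stats::median(prior_c$mean)
  if (is.null(c_ref)) c_ref <- if (!is.null(c_upper)) c_upper else 1.3 * margin_c
  structure(list(grid = grid, sensors = sensors, data = data, noise = noise,
                 prior_p0 = prior_p0, prior_c = prior_c, I = I, N = N,
                 margin_c = margin_c, c_ref = c_ref,
                 pml = if (is.null(pml)) make_pml(grid) else pml),
            class = "pat_problem")
}

#' Pack unknown fields into the optimisation vector
#'
#' @param p0_list list of I target-domain initial-pressure fields.
#' @param c_field target-domain speed-of-sound field.
#' @return numeric vector of length `(I + 1) * N` in the order
#'   `(p0^1, ..., p0^I, c)`.
#' @export
pack_unknowns <- function(p0_list, c_field) {
  c(unlist(lapply(p0_list, as.vector), use.names = FALSE), as.vector(c_field))
}

#' Unpack the optimisation vector
#'
#' @param x packed vector.
#' @param problem a `pat_problem` (or a list with `I`, `N`, `grid`).
#' @return list with `p0` (list of I matrices) and `c` (matrix), on the
#'   target domain.
#' @export
unpack_unknowns <- function(x, problem) {
  I <- problem$I; N <- problem$N
  if (length(x) != (I + 1) * N) stop("unknown vector has wrong length")
  n <- problem$grid$n_interior
  p0 <- lapply(seq_len(I), function(i) {
    matrix(x[((i - 1) * N + 1):(i * N)], n, n)
  })
  list(p0 = p0, c = matrix(x[(I * N + 1):((I + 1) * N)], n, n))
}

# Run the I forward solves for an iterate; returns simulated data (and
# fields when record_full).
problem_forward <- function(x, problem, record_full = FALSE) {
  u <- unpack_unknowns(x, problem)
  grid <- problem$grid
  c_full <- embed_field(u$c, grid, fill = problem$margin_c)
  medium <- make_medium(c_full, grid, c_ref = max(problem$c_ref, max(c_full)))
  lapply(seq_len(problem$I), function(i) {
    simulate_forward(medium, u$p0[[i]], grid, problem$sensors,
                     record_full = record_full, pml = problem$pml)
  })
}

#' Evaluate the penalised least-squares objective
#'
#' Runs the I forward solves sharing the current speed of sound and returns
#' the total objective together with its parts: per-dataset data misfits
#' `0.5 ||L_e (y^i - f_i)||^2`, per-dataset initial-pressure prior energies
#' and the speed-of-sound prior energy.
#'
#' @param x packed unknown vector.
#' @param problem a `pat_problem`.
#' @return list with `total`, `data_terms`, `prior_p0_terms`, `prior_c_term`.
#' @export
evaluate_objective <- function(x, problem) {
  u <- unpack_unknowns(x, problem)
  sims <- problem_forward(x, problem, record_full = FALSE)
  data_terms <- vapply(seq_len(problem$I), function(i) {
    r <- problem$data[[i]]$y - sims[[i]]$y
    0.5 * sum(r^2) / problem$noise[[i]]$sigma_e^2
  }, numeric(1))
  p0_terms <- vapply(seq_len(problem$I), function(i) {
    prior_energy(u$p0[[i]], problem$prior_p0)
  }, numeric(1))
  c_term <- prior_energy(u$c, problem$prior_c)
  list(total = sum(data_terms) + sum(p0_terms) + c_term,
       data_terms = data_terms, prior_p0_terms = p0_terms,
       prior_c_term = c_term)
}

#' Initial-pressure gradient block
#'
#' Combines the adjoint terminal snapshot with the prior gradient.  The
#' adjoint run returns the sensitivity of `<v, f>` with `v` the weighted
#' residual `L_e'L_e (y - f)`; the misfit `0.5||L_e(y - f)||^2` decreases
#' along `+F'v`, so the descent-consistent gradient negates the snapshot.
#'
#' @param adjoint a `pat_adjoint_field` (or a full-grid terminal matrix).
#' @param p0 current target-domain initial pressure field.
#' @param prior the p0 `pat_ou_prior`.
#' @param grid the `pat_grid` (needed when a bare matrix is passed).
#' @return target-domain gradient matrix.
#' @export
gradient_p0 <- function(adjoint, p0, prior, grid = NULL) {
  if (inherits(adjoint, "pat_adjoint_field")) {
    grid <- adjoint$grid
    term <- adjoint$terminal
  } else term <- adjoint
  gt <- extract_target(term, grid)
  if (length(gt) != prior$n) stop("dimension mismatch between adjoint and prior")
  n <- grid$n_interior
  -gt + matrix(prior_gradient(p0, prior), n, n)
}

#' Speed-of-sound gradient block
#'
#' Sums the per-dataset adjoint speed-of-sound sensitivities (accumulated
#' during the adjoint sweeps against the stored forward histories) and adds
#' the prior gradient.
#'
#' @param forward_fields list of forward `pat_pressure_field` objects (one
#'   per dataset; used for validation that histories were recorded).
#' @param adjoint_fields list of `pat_adjoint_field` objects carrying `dc`.
#' @param c current target-domain speed-of-sound field.
#' @param prior the c `pat_ou_prior`.
#' @return target-domain gradient matrix.
#' @export
gradient_c <- function(forward_fields, adjoint_fields, c, prior) {
  if (length(forward_fields) != length(adjoint_fields))
    stop("one adjoint field per forward field is required")
  grid <- adjoint_fields[[1]]$grid
  acc <- 0
  for (i in seq_along(adjoint_fields)) {
    if (is.null(adjoint_fields[[i]]$dc))
      stop("adjoint field lacks speed-of-sound sensitivity; rerun simulate_adjoint with forward = <field recorded with record_full = TRUE>")
    acc <- acc - extract_target(adjoint_fields[[i]]$dc, grid)
  }
  n <- grid$n_interior
  acc + matrix(prior_gradient(c, prior), n, n)
}

#' Stack per-field gradient blocks into the optimisation vector
#'
#' @param grad_p0_blocks list of I target-domain gradient matrices.
#' @param grad_c target-domain speed-of-sound gradient matrix.
#' @return packed gradient vector matching [pack_unknowns()] ordering.
#' @export
stack_gradient <- function(grad_p0_blocks, grad_c) {
  pack_unknowns(grad_p0_blocks, grad_c)
}

#' Objective value and full gradient in one pass
#'
#' One forward solve (with stored history) and one adjoint sweep per
#' dataset.
#'
#' @param x packed unknown vector.
#' @param problem a `pat_problem`.
#' @return list with `value`, `gradient` (packed vector) and the objective
#'   `parts`.
#' @export
objective_with_gradient <- function(x, problem) {
  u <- unpack_unknowns(x, problem)
  grid <- problem$grid
  c_full <- embed_field(u$c, grid, fill = problem$margin_c)
  medium <- make_medium(c_full, grid, c_ref = max(problem$c_ref, max(c_full)))

  grad_p0 <- vector("list", problem$I)
  fwd_fields <- vector("list", problem$I)
  adj_fields <- vector("list", problem$I)
  data_terms <- numeric(problem$I)
  for (i in seq_len(problem$I)) {
    sim <- simulate_forward(medium, u$p0[[i]], grid, problem$sensors,
                            record_full = TRUE, pml = problem$pml)
    r <- problem$data[[i]]$y - sim$data$y
    data_terms[i] <- 0.5 * sum(r^2) / problem$noise[[i]]$sigma_e^2
    src <- assemble_adjoint_source(r, problem$noise[[i]], problem$sensors, grid)
    adj <- simulate_adjoint(medium, src, grid, forward = sim$field,
                            pml = problem$pml)
    grad_p0[[i]] <- gradient_p0(adj, u$p0[[i]], problem$prior_p0)
    fwd_fields[[i]] <- sim$field
    adj_fields[[i]] <- adj
  }
  gc_blk <- gradient_c(fwd_fields, adj_fields, u$c, problem$prior_c)
  p0_terms <- vapply(seq_len(problem$I), function(i) {
    prior_energy(u$p0[[i]], problem$prior_p0)
  }, numeric(1))
  c_term <- prior_energy(u$c, problem$prior_c)
  list(value = sum(data_terms) + sum(p0_terms) + c_term,
       gradient = stack_gradient(grad_p0, gc_blk),
       parts = list(data_terms = data_terms, prior_p0_terms = p0_terms,
                    prior_c_term = c_term))
}
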