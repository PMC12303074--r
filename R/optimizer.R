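#' Box bounds for the packed unknown vector
#'
#' @param lower,upper numeric vectors (or scalars, broadcast) of elementwise
#'   bounds; use `-Inf` / `Inf` for unbounded components.
#' @return object of class `pat_bounds`.
#' @export
make_bounds <- function(lower, upper) {
  if (any(lower > upper)) stop("lower bound exceeds upper bound")
  structure(list(lower = lower, upper = upper), class = "pat_bounds")
}

#' Bounds for the joint reconstruction vector
#'
#' Initial pressures are non-negative with no upper bound; the speed of
#' sound is boxed to a physically plausible interval.
#'
#' @param problem a `pat_problem` (for I and N).
#' @param c_lower,c_upper speed-of-sound bounds, m/s.
#' @return a `pat_bounds` over the packed vector.
#' @export
default_bounds <- function(problem, c_lower = 1300, c_upper = 1800) {
  N <- problem$N; I <- problem$I
  make_bounds(c(rep(0, I * N), rep(c_lower, N)),
              c(rep(Inf, I * N), rep(c_upper, N)))
}

#' Project onto box bounds
#'
#' Elementwise clamp `P(z) = min(max(z, L), U)`.
#'
#' @param z numeric vector.
#' @param bounds a `pat_bounds` (or `NULL` for no constraints).
#' @return projected vector.
#' @export
project_bounds <- function(z, bounds) {
  if (is.null(bounds)) return(z)
  pmin(pmax(z, bounds$lower), bounds$upper)
}

# L-BFGS curvature-pair history.  Pairs with non-positive curvature
# (phi' kappa <= 0 up to a relative threshold) are rejected.
new_lbfgs_history <- function(memory = 20L) {
  structure(list(kappa = list(), phi = list(), rho = numeric(0),
                 memory = as.integer(memory)),
            class = "pat_lbfgs_history")
}

update_lbfgs_history <- function(history, kappa, phi,
                                 curvature_tol = 1e-10) {
  ip <- sum(phi * kappa)
  if (!is.finite(ip) ||
      ip <= curvature_tol * sqrt(sum(phi^2)) * sqrt(sum(kappa^2))) {
    return(history)  # curvature condition failed: skip the pair
  }
  history$kappa <- c(history$kappa, list(kappa))
  history$phi <- c(history$phi, list(phi))
  history$rho <- c(history$rho, 1 / ip)
  if (length(history$rho) > history$memory) {
    history$kappa <- history$kappa[-1]
    history$phi <- history$phi[-1]
    history$rho <- history$rho[-1]
  }
  history
}

#' L-BFGS search direction by two-loop recursion
#'
#' Applies the limited-memory inverse-Hessian approximation to the gradient
#' without forming matrices.  The initial approximation is the scaled
#' identity `H0 = (kappa'phi) / (phi'phi) * I` built from the most recent
#' pair; with an empty history the direction is steepest descent.
#'
#' @param grad gradient vector.
#' @param history a `pat_lbfgs_history`.
#' @return the direction `-H grad`.
#' @export
two_loop_direction <- function(grad, history) {
  if (length(grad) == 0) stop("empty gradient")
  m <- length(history$rho)
  q <- grad
  if (m == 0) return(-q)
  alpha <- numeric(m)
  for (j in m:1) {
    alpha[j] <- history$rho[j] * sum(history$kappa[[j]] * q)
    q <- q - alpha[j] * history$phi[[j]]
  }
  gamma <- sum(history$kappa[[m]] * history$phi[[m]]) /
    sum(history$phi[[m]]^2)
  z <- gamma * q
  for (j in 1:m) {
    beta <- history$rho[j] * sum(history$phi[[j]] * z)
    z <- z + (alpha[j] - beta) * history$kappa[[j]]
  }
  -z
}

#' Projected backtracking line search
#'
#' Armijo sufficient decrease evaluated at the projected trial point
#' `x(alpha) = P(x + alpha * direction)`: accepts the largest
#' `alpha = alpha0 * beta^m` with
#' `f(x(alpha)) <= f(x) + c1 * grad' (x(alpha) - x)`.
#'
#' @param x current iterate (within bounds).
#' @param direction search direction.
#' @param fn objective function of one vector argument.
#' @param fx objective value at `x`.
#' @param grad gradient at `x`.
#' @param bounds a `pat_bounds` or `NULL`.
#' @param alpha0 initial step.
#' @param c1 Armijo constant.
#' @param beta backtracking factor in (0, 1).
#' @param max_halvings number of reductions before giving up.
#' @return list with `alpha`, `x_new`, `f_new`, `n_eval` and `failed`.
#' @export
backtracking_search <- function(x, direction, fn, fx, grad, bounds = NULL,
                                alpha0 = 1, c1 = 1e-4, beta = 0.5,
                                max_halvings = 30L) {
  alpha <- alpha0
  n_eval <- 0L
  for (m in seq_len(max_halvings + 1L)) {
    x_new <- project_bounds(x + alpha * direction, bounds)
    step <- x_new - x
    if (sum(step^2) > 0) {
      f_new <- fn(x_new)
      n_eval <- n_eval + 1L
      if (is.finite(f_new) && f_new <= fx + c1 * sum(grad * step)) {
        return(list(alpha = alpha, x_new = x_new, f_new = f_new,
                    n_eval = n_eval, failed = FALSE))
      }
    }
    alpha <- alpha * beta
  }
  list(alpha = 0, x_new = x, f_new = fx, n_eval = n_eval, failed = TRUE)
}

#' Bound-constrained limited-memory BFGS
#'
#' Iterates `x <- P(x + alpha * d)` with `d = -H grad` from the two-loop
#' recursion, projected Armijo backtracking, curvature-guarded history
#' updates, and a stopping rule on relative objective decrease.
#'
#' @param fn objective function `x -> value`.
#' @param gr gradient oracle `x -> list(value, gradient)`; when `NULL`, a
#'   list-returning `fn` is expected to supply both.
#' @param x0 starting point (projected onto the bounds if outside).
#' @param bounds a `pat_bounds` or `NULL`.
#' @param memory number of stored curvature pairs.
#' @param max_iter iteration cap.
#' @param tol relative objective decrease threshold.
#' @param patience number of consecutive low-progress iterations that
#'   triggers convergence.
#' @param grad_tol stop when the projected gradient norm falls below this.
#' @param verbose print per-iteration progress.
#' @return list with `x`, `value`, `trace` (data.frame with `iter`, `value`,
#'   `grad_norm`, `alpha`, `n_active`), `status` and `iterations`.
#' @export
minimize <- function(fn, gr, x0, bounds = NULL, memory = 20L,
                     max_iter = 200L, tol = 1e-4, patience = 5L,
                     grad_tol = 0, verbose = FALSE) {
  x <- project_bounds(x0, bounds)
  ev <- gr(x)
  f <- ev$value
  g <- ev$gradient
  history <- new_lbfgs_history(memory)
  trace <- list()
  low_progress <- 0L
  status <- "max_iter"
  iter <- 0L

  proj_grad_norm <- function(x, g) {
    # norm of the projected steepest-descent step (first-order optimality)
    sqrt(sum((x - project_bounds(x - g, bounds))^2))
  }

  for (iter in seq_len(max_iter)) {
    pg <- proj_grad_norm(x, g)
    if (pg <= grad_tol) { status <- "converged_gradient"; iter <- iter - 1L; break }

    d <- two_loop_direction(g, history)
    alpha0 <- if (length(history$rho) == 0) {
      m <- max(abs(g))
      if (m > 0) 1 / m else 1
    } else 1
    ls <- backtracking_search(x, d, fn, f, g, bounds, alpha0 = alpha0)
    if (ls$failed) {
      if (length(history$rho) > 0) {   # restart from steepest descent once
        history <- new_lbfgs_history(memory)
        d <- -g
        m <- max(abs(g))
        ls <- backtracking_search(x, d, fn, f, g, bounds,
                                  alpha0 = if (m > 0) 1 / m else 1)
      }
      if (ls$failed) { status <- "line_search_failure"; break }
    }

    ev <- gr(ls$x_new)
    history <- update_lbfgs_history(history, ls$x_new - x, ev$gradient - g)
    rel_dec <- (f - ls$f_new) / max(abs(f), .Machine$double.eps)
    x <- ls$x_new
    f <- ev$value
    g <- ev$gradient
    n_active <- if (is.null(bounds)) 0L else
      sum(x <= bounds$lower | x >= bounds$upper)
    trace[[iter]] <- data.frame(iter = iter, value = f,
                                grad_norm = sqrt(sum(g^2)),
                                alpha = ls$alpha, n_active = n_active)
    if (verbose) {
      message(sprintf("  it %3d  f = %.6e  |g| = %.3e  alpha = %.2e",
                      iter, f, sqrt(sum(g^2)), ls$alpha))
    }
    low_progress <- if (rel_dec < tol) low_progress + 1L else 0L
    if (low_progress >= patience) { status <- "converged"; break }
  }

  list(x = x, value = f,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(iter = integer(), value = numeric(),
                    grad_norm = numeric(), alpha = numeric(),
                    n_active = integer()),
       status = status, iterations = iter)
}
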