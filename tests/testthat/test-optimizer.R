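# dense one-pair inverse-Hessian: H = (I - rho k f') H0 (I - rho f k') + rho k k'
dense_one_pair_H <- function(kappa, phi) {
  n <- length(kappa)
  rho <- 1 / sum(phi * kappa)
  H0 <- diag(sum(kappa * phi) / sum(phi * phi), n)
  V <- diag(n) - rho * outer(phi, kappa)
  t(V) %*% H0 %*% V + rho * outer(kappa, kappa)
}

test_that("two-loop recursion reproduces dense L-BFGS formulas", {
  set.seed(31)
  g <- stats::rnorm(6)
  h0 <- patjrec:::new_lbfgs_history(5L)
  expect_equal(two_loop_direction(g, h0), -g)
  expect_error(two_loop_direction(numeric(0), h0), "empty")

  kappa <- stats::rnorm(6); phi <- kappa + 0.3 * stats::rnorm(6)
  if (sum(kappa * phi) < 0) phi <- -phi
  h1 <- patjrec:::update_lbfgs_history(h0, kappa, phi)
  expect_equal(two_loop_direction(g, h1),
               as.vector(-dense_one_pair_H(kappa, phi) %*% g),
               tolerance = 1e-10)
})

test_that("the two-loop result equals the dense recursive inverse-Hessian update", {
  set.seed(32)
  n <- 5
  h <- patjrec:::new_lbfgs_history(20L)
  pairs <- list()
  for (k in 1:4) {
    kappa <- stats::rnorm(n)
    phi <- kappa + 0.4 * stats::rnorm(n)
    if (sum(kappa * phi) < 0) phi <- -phi
    h <- patjrec:::update_lbfgs_history(h, kappa, phi)
    pairs[[k]] <- list(kappa = kappa, phi = phi)
  }
  m <- length(pairs)
  gamma <- sum(pairs[[m]]$kappa * pairs[[m]]$phi) / sum(pairs[[m]]$phi^2)
  H <- diag(gamma, n)
  for (p in pairs) {
    rho <- 1 / sum(p$phi * p$kappa)
    V <- diag(n) - rho * outer(p$phi, p$kappa)
    H <- t(V) %*% H %*% V + rho * outer(p$kappa, p$kappa)
  }
  g <- stats::rnorm(n)
  expect_equal(two_loop_direction(g, h), as.vector(-H %*% g),
               tolerance = 1e-10)
})

test_that("history eviction and curvature guarding work", {
  h <- patjrec:::new_lbfgs_history(3L)
  set.seed(33)
  for (k in 1:7) {
    kappa <- stats::rnorm(4)
    h <- patjrec:::update_lbfgs_history(h, kappa, kappa + 0.1 * stats::rnorm(4))
  }
  expect_equal(length(h$rho), 3L)

  before <- length(h$rho)
  kappa <- stats::rnorm(4)
  h2 <- patjrec:::update_lbfgs_history(h, kappa, -kappa)  # negative curvature
  expect_equal(length(h2$rho), before)
  expect_identical(h2$kappa, h$kappa)
})

test_that("bound projection clamps, preserves interior points and is idempotent", {
  b <- make_bounds(c(0, 0, -Inf), c(1, Inf, 2))
  expect_equal(project_bounds(c(0.5, 3, -7), b), c(0.5, 3, -7))
  expect_equal(project_bounds(c(-1, -2, 5), b), c(0, 0, 2))
  z <- c(-3, 10, 0.3)
  expect_equal(project_bounds(project_bounds(z, b), b), project_bounds(z, b))
  expect_error(make_bounds(c(1, 0), c(0, 1)), "exceeds")
})

test_that("backtracking accepts exact steps, respects bounds and signals failure", {
  fn <- function(x) (x - 3)^2
  gr <- -6  # gradient at x = 0
  ls <- backtracking_search(0, 3, fn, fn(0), gr, NULL, alpha0 = 1)
  expect_false(ls$failed)
  expect_equal(ls$alpha, 1)
  expect_equal(ls$x_new, 3)

  b <- make_bounds(-Inf, 2)
  ls2 <- backtracking_search(0, 3, fn, fn(0), gr, b, alpha0 = 1)
  expect_false(ls2$failed)
  expect_equal(ls2$x_new, 2)

  ls3 <- backtracking_search(0, -3, fn, fn(0), gr, NULL, alpha0 = 1,
                             max_halvings = 10L)
  expect_true(ls3$failed)
})

test_that("projected L-BFGS solves box-bounded quadratics to the KKT solution", {
  set.seed(34)
  n <- 4
  A <- crossprod(matrix(stats::rnorm(n * n), n)) + 0.5 * diag(n)
  b <- stats::rnorm(n, sd = 3)
  lo <- rep(0, n); up <- rep(1, n)
  fn <- function(x) as.numeric(0.5 * t(x) %*% A %*% x - sum(b * x))
  gr <- function(x) list(value = fn(x), gradient = as.vector(A %*% x - b))

  # oracle: enumerate active sets and check KKT conditions
  best <- NULL
  for (code in 0:(3^n - 1)) {
    state <- (code %/% 3^(0:(n - 1))) %% 3   # 0 free, 1 at lower, 2 at upper
    x <- numeric(n)
    x[state == 1] <- lo[state == 1]
    x[state == 2] <- up[state == 2]
    free <- which(state == 0)
    if (length(free)) {
      rhs <- b[free] - A[free, -free, drop = FALSE] %*% x[-free]
      x[free] <- solve(A[free, free, drop = FALSE], rhs)
    }
    if (any(x < lo - 1e-9) || any(x > up + 1e-9)) next
    g <- as.vector(A %*% x - b)
    ok <- all(abs(g[state == 0]) < 1e-8) && all(g[state == 1] > -1e-8) &&
      all(g[state == 2] < 1e-8)
    if (ok) best <- x
  }
  expect_false(is.null(best))

  fit <- minimize(fn, gr, x0 = rep(0.5, n), bounds = make_bounds(lo, up),
                  memory = 20L, max_iter = 200L, tol = 1e-14,
                  patience = 10L, grad_tol = 0)
  expect_lt(sqrt(sum((fit$x - best)^2)), 1e-6)
  # all iterates feasible and monotone decreasing
  expect_true(all(fit$x >= lo & fit$x <= up))
  expect_true(all(diff(fit$trace$value) <= 1e-12))
})

test_that("unconstrained quadratics reach the minimiser and a start at the optimum stops immediately", {
  set.seed(35)
  n <- 8
  A <- crossprod(matrix(stats::rnorm(n * n), n)) + diag(n)
  b <- stats::rnorm(n)
  xstar <- solve(A, b)
  fn <- function(x) as.numeric(0.5 * t(x) %*% A %*% x - sum(b * x))
  gr <- function(x) list(value = fn(x), gradient = as.vector(A %*% x - b))
  fit <- minimize(fn, gr, x0 = rep(0, n), memory = 20L, max_iter = 50L,
                  tol = 1e-15, patience = 10L)
  expect_lt(sqrt(sum((fit$x - xstar)^2)), 1e-6)

  fit0 <- minimize(fn, gr, x0 = xstar, memory = 20L, max_iter = 50L,
                   grad_tol = 1e-9)
  expect_lte(fit0$iterations, 1L)
  expect_equal(fit0$status, "converged_gradient")
})

test_that("bounded Rosenbrock converges to the known minimiser", {
  fn <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  gr <- function(x) list(value = fn(x), gradient = c(
    -2 * (1 - x[1]) - 400 * x[1] * (x[2] - x[1]^2),
    200 * (x[2] - x[1]^2)))
  fit <- minimize(fn, gr, x0 = c(-1.2, 1), bounds = make_bounds(-1.5, 1.5),
                  memory = 20L, max_iter = 500L, tol = 1e-15,
                  patience = 20L, grad_tol = 1e-10)
  expect_lt(max(abs(fit$x - c(1, 1))), 1e-3)
})
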