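test_that("bilinear prolongation preserves constants, linears and matches a 1D oracle", {
  g_co <- make_grid(8, 1e-3)
  g_fi <- make_grid(16, 0.5e-3)

  expect_true(all(prolong_field(matrix(7, 8, 8), g_co, g_fi) == 7))

  xc <- grid_coords(g_co, "target")$x
  xf <- grid_coords(g_fi, "target")$x
  ramp <- outer(xc, xc, function(a, b) 2 + 3 * a - b)
  up <- prolong_field(ramp, g_co, g_fi)
  ref <- outer(xf, xf, function(a, b) 2 + 3 * a - b)
  interior <- xf >= min(xc) & xf <= max(xc)   # exact away from extrapolation
  expect_equal(up[interior, interior], ref[interior, interior],
               tolerance = 1e-12)

  set.seed(41)
  f <- matrix(stats::rnorm(64), 8)
  up2 <- prolong_field(f, g_co, g_fi)
  # separable two-pass 1D linear interpolation oracle (clamped at the ends)
  int1 <- function(vals) stats::approx(xc, vals, xout = xf, rule = 2)$y
  tmp <- apply(f, 2, int1)
  ref2 <- t(apply(tmp, 1, int1))
  expect_equal(up2, ref2, tolerance = 1e-12)

  gx <- make_grid(8, 2e-3)   # different physical extent
  expect_error(prolong_field(f, g_co, gx), "extent")
})

test_that("prolongation of a bounded field stays within the bounds", {
  g_co <- make_grid(8, 1e-3)
  g_fi <- make_grid(20, 0.4e-3)
  set.seed(42)
  f <- pmin(pmax(matrix(stats::rnorm(64, 1500, 100), 8), 1300), 1800)
  up <- prolong_field(f, g_co, g_fi)
  expect_true(all(up >= 1300 & up <= 1800))
})

test_that("temporal resampling is exact on identical axes and accurate for sines", {
  y <- matrix(stats::rnorm(3 * 50), 3)
  d <- patjrec:::new_sensor_data(y, make_grid(4, 1e-3, dt = 1e-8, nt = 50))
  same <- resample_data_time(d, 1e-8, 50, lowpass_hz = NULL)
  expect_identical(same$y, y)

  dc <- d; dc$y <- matrix(4.2, 3, 50)
  down <- resample_data_time(dc, 2e-8, 25, lowpass_hz = NULL)
  expect_true(all(abs(down$y - 4.2) < 1e-12))

  # sine at a quarter of the coarse Nyquist, downsampled 2x
  dt <- 1e-8; nt <- 200
  f0 <- 1 / (2 * 2 * dt) / 4
  tv <- (seq_len(nt) - 1) * dt
  ds <- patjrec:::new_sensor_data(matrix(sin(2 * pi * f0 * tv), 1),
                                  make_grid(4, 1e-3, dt = dt, nt = nt))
  out <- resample_data_time(ds, 2 * dt, 100, lowpass_hz = NULL)
  ref <- sin(2 * pi * f0 * (seq_len(100) - 1) * 2 * dt)
  expect_lt(sqrt(sum((out$y[1, ] - ref)^2) / sum(ref^2)), 1e-2)

  expect_error(resample_data_time(d, 1e-8, 51), "horizon")
})

test_that("the initial guess is zero pressure and the prior-mean sound speed", {
  pr <- build_ou_prior(make_grid(6, 1e-3), sigma = 37.5, tau = 1.5e-3,
                       mean = 1505)
  x <- initial_guess(pr, 4L)
  expect_equal(length(x), 5 * 36)
  expect_true(all(x[1:(4 * 36)] == 0))
  expect_true(all(x[(4 * 36 + 1):(5 * 36)] == 1505))
  b <- make_bounds(c(rep(0, 4 * 36), rep(1300, 36)),
                   c(rep(Inf, 4 * 36), rep(1800, 36)))
  expect_equal(project_bounds(x, b), x)
})

test_that("schedules enforce coarse-to-fine ordering and the inverse-crime guard", {
  g1 <- make_grid(8, 2e-3, 2, 4, dt = 4e-7, nt = 20)
  g2 <- make_grid(16, 1e-3, 2, 4, dt = 2e-7, nt = 40)
  expect_error(make_schedule(list(g2, g1)), "decreasing")
  sch <- make_schedule(list(g1, g2))

  d <- patjrec:::new_sensor_data(matrix(0, 8, 80),
                                 make_grid(16, 1e-3, dt = 1e-7, nt = 80))
  expect_error(
    run_multigrid(sch, list(d), sensor_spec = list(count = 8, inset = 1e-3),
                  prior_spec = list(sigma_p0 = 2.5, mean_p0 = 5,
                                    sigma_c = 37.5, mean_c = 1500,
                                    tau = 1.5e-3),
                  noise = list(make_noise_model(1))),
    "inverse crime")
})

test_that("a single-level schedule reduces to plain minimisation", {
  tp <- make_test_problem(n_interior = 12L, nt = 30L, I = 1L, seed = 7)
  grid <- tp$grid
  # data simulated on a slightly different grid to avoid the inverse crime
  data_grid <- make_grid(18L, 10e-3 / 18, 2L, 4L,
                         dt = 0.3 * (10e-3 / 18) / 1600, nt = 60L)
  ph_med <- make_medium(embed_field(
    prolong_field(tp$c_true, grid, data_grid), data_grid, fill = 1500),
    data_grid, c_ref = 1600)
  sens_d <- place_sensors(data_grid, 24L, 0.3e-3)
  obs <- simulate_forward(ph_med, prolong_field(tp$p0_true[[1]], grid,
                                                data_grid),
                          data_grid, sens_d)

  prior_spec <- list(sigma_p0 = 2.5, mean_p0 = 5, sigma_c = 37.5,
                     mean_c = 1500, tau = 1.5e-3)
  opts <- list(max_iter = 8L, tol = 1e-9, memory = 10L)
  sch <- make_schedule(list(grid), list(opts))
  res <- run_multigrid(sch, list(obs),
                       sensor_spec = list(count = 24, inset = 0.3e-3),
                       prior_spec = prior_spec,
                       noise = list(make_noise_model(0.05)),
                       bounds_spec = list(c_lower = 1300, c_upper = 1800),
                       data_dx = data_grid$dx, lowpass = FALSE)

  # replicate by hand: same problem, same start, same optimizer settings
  sensors <- place_sensors(grid, 24L, 0.3e-3)
  dres <- resample_data_time(obs, grid$dt, grid$nt, lowpass_hz = NULL)
  prior_p0 <- build_ou_prior(grid, 2.5, 1.5e-3, mean = 5)
  prior_c <- build_ou_prior(grid, 37.5, 1.5e-3, mean = 1500)
  prob <- make_problem(grid, sensors, list(dres), list(make_noise_model(0.05)),
                       prior_p0, prior_c, margin_c = 1500, c_upper = 1800)
  bnds <- default_bounds(prob)
  fit <- minimize(function(z) evaluate_objective(z, prob)$total,
                  function(z) objective_with_gradient(z, prob),
                  x0 = initial_guess(prior_c, 1L), bounds = bnds,
                  max_iter = 8L, tol = 1e-9, memory = 10L)
  expect_equal(pack_unknowns(res$p0, res$c), fit$x, tolerance = 1e-10)
  # objective decreases monotonically along accepted steps
  expect_true(all(diff(res$levels[[1]]$trace$value) <= 1e-9))
})
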