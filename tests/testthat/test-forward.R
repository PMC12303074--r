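test_that("zero initial pressure gives zero traces and linearity holds", {
  sc <- make_test_scene(nt = 48L)
  z <- simulate_forward(sc$medium, matrix(0, 32, 32), sc$grid, sc$sensors)
  expect_true(all(z$y == 0))

  set.seed(2)
  p0 <- matrix(stats::rnorm(32^2), 32)
  y1 <- simulate_forward(sc$medium, p0, sc$grid, sc$sensors)$y
  y2 <- simulate_forward(sc$medium, 2 * p0, sc$grid, sc$sensors)$y
  expect_equal(y2, 2 * y1, tolerance = 1e-12)
})

test_that("stability violations are reported with the offending CFL number", {
  g <- make_grid(16, 1e-4, 2, 4, dt = 1e-7, nt = 8)   # CFL = 1.5 at 1500 m/s
  med <- make_medium(1500, g)
  expect_error(simulate_forward(med, matrix(0, 16, 16), g, NULL),
               "c_max \\* dt / dx")
})

test_that("homogeneous-medium traces match the free-space solution and converge under refinement", {
  run_case <- function(n, dtf) {
    # blob at centre, sensor at a radius on-node for every refinement
    dx <- 8e-3 / n
    grid <- make_grid(n, dx, round(0.075 * n), round(0.25 * n),
                      dt = dtf * dx / 1500, nt = round(n * 0.55 / dtf))
    c0 <- 1500
    med <- make_medium(c0, grid, c_ref = c0)
    s <- 1.6e-4   # Gaussian width: well resolved on both grids
    cc <- grid_coords(grid, "full")
    ctr <- grid$extent / 2
    X <- matrix(cc$x, grid$n_total, grid$n_total)
    Y <- matrix(cc$y, grid$n_total, grid$n_total, byrow = TRUE)
    p0 <- exp(-((X - ctr)^2 + (Y - ctr)^2) / (2 * s^2))
    # sensor on the x-axis at r = 2.4 mm from the blob centre
    r <- 2.4e-3
    ix <- which.min(abs(cc$x - (ctr + r)))
    iy <- which.min(abs(cc$x - ctr))
    sens <- structure(list(ix = ix, iy = iy, x = cc$x[ix], y = cc$x[iy],
                           count = 1L), class = "pat_sensors")
    sim <- simulate_forward(med, p0, grid, sens)
    tvec <- (seq_len(grid$nt) - 1) * grid$dt
    ref <- gaussian_freespace_pressure(abs(cc$x[ix] - ctr), tvec, c0, s)
    sqrt(sum((sim$y[1, ] - ref)^2) / sum(ref^2))
  }
  err_coarse <- run_case(64, 0.30)
  expect_lt(err_coarse, 0.01)
  err_fine <- run_case(128, 0.30)
  expect_lt(err_fine, err_coarse / 2)
})

test_that("energy is conserved on a periodic homogeneous domain", {
  n <- 48
  g1 <- make_grid(n, 1e-4, 0, 0, dt = 0.1 * 1e-4 / 1500, nt = 101)
  med <- make_medium(1500, g1)
  x <- grid_coords(g1, "full")$x
  ctr <- g1$extent / 2
  X <- matrix(x, n, n); Y <- matrix(x, n, n, byrow = TRUE)
  p0 <- exp(-((X - ctr)^2 + (Y - ctr)^2) / (2 * (4e-4)^2))
  pml0 <- make_pml(g1, peak = 0)
  energy_at <- function(nt) {
    g <- make_grid(n, 1e-4, 0, 0, dt = g1$dt, nt = nt)
    st <- patjrec:::ks_step_state(med, g, p0,
                                  u0x = matrix(0, n, n), u0y = matrix(0, n, n),
                                  pml = pml0)
    # u given at -dt/2 relative to run start equal to zero mimics the
    # standard init only at nt = 1; for the drift check both snapshots are
    # computed the same way, so the common staggering bias cancels.
    p <- med$c^2 * (st$rx + st$ry)
    0.5 * sum(st$ux^2 + st$uy^2 + p^2 / med$c^2)
  }
  e1 <- energy_at(101)
  e2 <- energy_at(601)
  expect_lt(abs(e2 - e1) / e1, 1e-3)
})

test_that("the PML suppresses re-entrant reflections below 1% of the source peak", {
  n <- 64
  grid <- make_grid(n, 1e-4, 2, 20, dt = 2.2e-8, nt = 520)
  med <- make_medium(1500, grid)
  x <- grid_coords(grid, "target")$x
  ctr <- grid$extent / 2
  X <- matrix(x, n, n); Y <- matrix(x, n, n, byrow = TRUE)
  p0 <- 10 * exp(-((X - ctr)^2 + (Y - ctr)^2) / (2 * (3e-4)^2))
  sim <- simulate_forward(med, p0, grid, NULL, record_full = TRUE)
  ti <- target_indices(grid)
  # outgoing wave clears the 3.2 mm half-domain by ~3 us; watch what returns
  t_clear <- ceiling(2.2 * (grid$extent / 2) / 1500 / grid$dt)
  late <- sim$field$p_hist[, t_clear:grid$nt]
  full_idx <- matrix(seq_len(grid$n_total^2), grid$n_total)
  expect_lt(max(abs(late[as.vector(full_idx[ti, ti]), ])), 0.01 * max(p0))
})

test_that("time reversal on a homogeneous medium reproduces the initial pressure", {
  n <- 48
  g <- make_grid(n, 1e-4, 0, 0, dt = 2e-8, nt = 90)
  med <- make_medium(1500, g)
  x <- grid_coords(g, "full")$x
  ctr <- g$extent / 2
  X <- matrix(x, n, n); Y <- matrix(x, n, n, byrow = TRUE)
  p0 <- exp(-((X - ctr)^2 + (Y - ctr)^2) / (2 * (4e-4)^2))
  pml0 <- make_pml(g, peak = 0)
  fwd <- patjrec:::ks_step_state(med, g, p0, matrix(0, n, n), matrix(0, n, n),
                                 pml = pml0)
  p_end <- med$c^2 * (fwd$rx + fwd$ry)
  # advance the staggered velocities half a leapfrog cycle so that negating
  # them reverses the trajectory exactly
  wn <- make_wavenumbers(g)
  kap <- patjrec:::k_sinc(med$c_ref * wn$k * g$dt / 2)
  dspec <- function(f, ik) Re(fft(ik * kap * fft(f), inverse = TRUE)) / n^2
  ux2 <- fwd$ux - g$dt * dspec(p_end, 1i * wn$kx)
  uy2 <- fwd$uy - g$dt * dspec(p_end, 1i * wn$ky)
  back <- patjrec:::ks_step_state(med, g, p_end, -ux2, -uy2, pml = pml0)
  p_back <- med$c^2 * (back$rx + back$ry)
  expect_lt(norm(p_back - p0, "F") / norm(p0, "F"), 0.02)
})

test_that("second time derivative is exact for quadratics and accurate for sinusoids", {
  nt <- 50; dt <- 0.1
  tv <- (seq_len(nt) - 1) * dt
  const <- matrix(3, 4, nt)
  expect_true(all(second_time_derivative(const, dt) == 0))

  quad <- matrix(rep(tv^2, each = 2), 2, byrow = FALSE)
  d2 <- second_time_derivative(quad, dt)
  expect_equal(d2[1, ], rep(2, nt), tolerance = 1e-10)

  omega <- 1; dts <- 0.1 / omega
  tv2 <- (seq_len(200) - 1) * dts
  f <- matrix(sin(omega * tv2), 1)
  d2s <- second_time_derivative(f, dts)
  interior <- 2:199
  err <- max(abs(d2s[1, interior] + omega^2 * sin(omega * tv2[interior])))
  expect_lt(err, (omega * dts)^2 / 12 * omega^2 * 1.01)

  expect_error(second_time_derivative(matrix(0, 2, 2), 0.1), "3 time samples")
})

test_that("sensor sampling extracts rows without interpolation", {
  sc <- make_test_scene(n_interior = 16L, nt = 12L)
  set.seed(3)
  p0 <- matrix(stats::rnorm(16^2), 16)
  sim <- simulate_forward(sc$medium, p0, sc$grid, sc$sensors,
                          record_full = TRUE)
  resampled <- sample_sensors(sim$field, sc$sensors)
  expect_equal(resampled$y, sim$data$y)

  ones <- structure(list(p_hist = matrix(1, sc$grid$n_total^2, 3),
                         grid = sc$grid), class = "pat_pressure_field")
  expect_true(all(sample_sensors(ones, sc$sensors)$y == 1))

  perm <- sample(sc$sensors$count)
  sp <- sc$sensors
  sp$ix <- sp$ix[perm]; sp$iy <- sp$iy[perm]
  expect_equal(sample_sensors(sim$field, sp)$y, sim$data$y[perm, ])

  bad <- sc$sensors; bad$ix[1] <- sc$grid$n_total + 5L
  expect_error(sample_sensors(sim$field, bad), "off grid")
})
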