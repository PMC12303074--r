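# Shared fixtures.  The twin-study run is expensive, so it is computed once
# per test session and reused by every test that needs it.

.fixture_env <- new.env(parent = emptyenv())

get_twin_results <- function() {
  if (is.null(.fixture_env$twin)) {
    .fixture_env$twin <- twin_study(seeds = 1:10)
  }
  .fixture_env$twin
}

# Small heterogeneous test scene shared by forward/adjoint tests
make_test_scene <- function(n_interior = 32L, nt = 64L, seed = 1,
                            contrast = 80) {
  grid <- make_grid(n_interior, 1e-4, 4L, 8L, dt = 1.8e-8, nt = nt)
  set.seed(seed)
  cfull <- matrix(1500, grid$n_total, grid$n_total)
  ti <- target_indices(grid)
  bump <- matrix(stats::rnorm(n_interior^2), n_interior)
  # smooth the heterogeneity a little so it is resolvable
  bump <- (bump + bump[c(1, seq_len(n_interior - 1)), ] +
             bump[, c(1, seq_len(n_interior - 1))]) / 3
  cfull[ti, ti] <- 1500 + contrast * bump / max(abs(bump))
  medium <- make_medium(cfull, grid)
  sensors <- place_sensors(grid, 40L, 2e-4)
  list(grid = grid, medium = medium, sensors = sensors)
}

# Free-space 2D wave solution for a Gaussian initial pressure, evaluated by
# radial Fourier-Bessel quadrature: p(r, t) = s^2 Int k exp(-s^2 k^2 / 2)
# cos(c k t) J0(k r) dk.  Independent of the FFT machinery.
gaussian_freespace_pressure <- function(r, t, c0, s) {
  kmax <- 8 / s
  k <- seq(0, kmax, length.out = 4096)
  dk <- k[2] - k[1]
  vapply(seq_along(t), function(j) {
    integrand <- k * exp(-s^2 * k^2 / 2) * cos(c0 * k * t[j]) *
      besselJ(k * r, 0)
    s^2 * (sum(integrand) - integrand[1] / 2 -
             integrand[length(k)] / 2) * dk
  }, numeric(1))
}

# Small joint-reconstruction problem with data generated by the problem's
# own forward map at a known truth (for objective/gradient verification).
make_test_problem <- function(n_interior = 16L, nt = 40L, I = 2L, seed = 5,
                              sigma_e = 1, priors_at_truth = FALSE,
                              n_margin = 2L, n_pml = 4L) {
  dx <- 10e-3 / n_interior
  grid <- make_grid(n_interior, dx, n_margin, n_pml,
                    dt = 0.35 * dx / 1600, nt = nt)
  sensors <- place_sensors(grid, 24L, min(0.3e-3, (n_margin - 0.5) * dx))
  set.seed(seed)
  cc <- grid_coords(grid, "target")$x
  X <- matrix(cc, n_interior, n_interior)
  Y <- matrix(cc, n_interior, n_interior, byrow = TRUE)
  ctr <- grid$extent / 2
  c_true <- 1500 + 60 * exp(-((X - 0.6 * ctr)^2 + (Y - ctr)^2) /
                              (2 * (0.15 * grid$extent)^2))
  p0_true <- lapply(seq_len(I), function(i) {
    x0 <- ctr * (0.6 + 0.4 * (i %% 2))
    y0 <- ctr * (1.3 - 0.5 * (i %% 3) / 2)
    10 * exp(-((X - x0)^2 + (Y - y0)^2) / (2 * (0.12 * grid$extent)^2))
  })
  x_true <- pack_unknowns(p0_true, c_true)

  prior_p0 <- build_ou_prior(grid, sigma = 2.5, tau = 1.5e-3,
                             mean = if (priors_at_truth)
                               as.vector(p0_true[[1]]) else 5)
  prior_c <- build_ou_prior(grid, sigma = 37.5, tau = 1.5e-3,
                            mean = if (priors_at_truth)
                              as.vector(c_true) else 1500)

  placeholder <- lapply(seq_len(I), function(i) {
    patjrec:::new_sensor_data(matrix(0, sensors$count, nt), grid, i)
  })
  problem <- make_problem(grid, sensors, placeholder,
                          list(make_noise_model(sigma_e)),
                          prior_p0, prior_c, margin_c = 1500, c_ref = 1600)
  sims <- patjrec:::problem_forward(x_true, problem)
  problem$data <- lapply(sims, function(s) s)
  list(problem = problem, x_true = x_true, p0_true = p0_true,
       c_true = c_true, grid = grid, sensors = sensors)
}
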