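#' Relative error between true and reconstructed fields
#'
#' `100 * ||true - rec|| / ||true||` with Euclidean norms over all pixels.
#'
#' @param true_field,rec_field fields of identical dimensions.
#' @return relative error in percent.
#' @export
relative_error <- function(true_field, rec_field) {
  if (length(true_field) != length(rec_field)) stop("field dimensions differ")
  nrm <- sqrt(sum(true_field^2))
  if (nrm == 0) stop("true field has zero norm")
  100 * sqrt(sum((true_field - rec_field)^2)) / nrm
}

#' Resample a true field onto a reconstruction grid
#'
#' Bilinear resampling on physical pixel-centre coordinates, used to
#' compare reconstructions with the truth when simulation and
#' reconstruction discretisations differ.
#'
#' @param true_field target-domain field on `from`.
#' @param from,to `pat_grid` objects with (approximately) matching target
#'   extent.
#' @return field on `to`'s target domain.
#' @export
truth_on_grid <- function(true_field, from, to) {
  prolong_field(true_field, from, to)
}

#' Grid schedules matching the study's discretisation table
#'
#' The data-simulation grid and the five reconstruction (multigrid) levels:
#' pixel sizes 526.3/370.4/227.3/156.3/101.0 um, target sizes
#' 39/55/89/129/199 px, with their sensor margins, PML widths and time axes.
#' Levels 1-4 are used for the simple-phantom studies and 2-5 for the
#' tissue-mimicking studies.
#'
#' @param which `"data"` for the simulation grid, or an integer vector of
#'   level numbers (1-5).
#' @return a `pat_grid` (for `"data"`) or list of `pat_grid`s.
#' @export
study_grids <- function(which = 1:4) {
  rows <- list(
    data = list(n = 335L, dx = 63.7e-6, ms = 10L, pml = 20L,
                dt = 12.1e-9, nt = 1747L),
    l1 = list(n = 39L, dx = 526.3e-6, ms = 2L, pml = 19L,
              dt = 99.9e-9, nt = 212L),
    l2 = list(n = 55L, dx = 370.4e-6, ms = 4L, pml = 31L,
              dt = 70.4e-9, nt = 301L),
    l3 = list(n = 89L, dx = 227.3e-6, ms = 4L, pml = 14L,
              dt = 43.2e-9, nt = 490L),
    l4 = list(n = 129L, dx = 156.3e-6, ms = 6L, pml = 17L,
              dt = 29.7e-9, nt = 712L),
    l5 = list(n = 199L, dx = 101.0e-6, ms = 8L, pml = 14L,
              dt = 19.2e-9, nt = 1101L))
  mk <- function(r) make_grid(r$n, r$dx, r$ms, r$pml, r$dt, r$nt)
  if (identical(which, "data")) return(mk(rows$data))
  lapply(which, function(k) mk(rows[[paste0("l", k)]]))
}

#' Experiment configuration
#'
#' Aggregates everything [run_experiment()] needs.  Defaults give the
#' reduced-scale twin study: a 20 mm domain, a 64 px data-simulation grid,
#' a two-level (32/48 px) reconstruction schedule, a three-inclusion
#' sound-speed phantom with four initial-pressure datasets at 10 Pa, 100
#' boundary sensors, 1% additive noise, OU priors with the range/4 standard
#' deviation rule and the median-of-range means, and soft-tissue
#' sound-speed bounds.
#'
#' @param phantom a `pat_phantom_spec` (defaults to the three-inclusion
#'   variant).
#' @param data_grid `pat_grid` for data simulation.
#' @param level_grids list of `pat_grid`s, coarse to fine.
#' @param optimizer per-level (or shared) [minimize()] settings.
#' @param sensor_count,sensor_inset sensor geometry.
#' @param noise_level fraction of peak-to-peak amplitude.
#' @param prior list with `sigma_p0`, `mean_p0`, `sigma_c`, `mean_c`, `tau`;
#'   missing entries are filled with the range-based defaults for the
#'   phantom.
#' @param bounds list with `c_lower`, `c_upper`.
#' @param seed base RNG seed for the noise realisations.
#' @return object of class `pat_experiment_config`.
#' @export
experiment_config <- function(phantom = simple_phantom_spec("three_inclusion"),
                              data_grid = NULL, level_grids = NULL,
                              optimizer = NULL,
                              sensor_count = 100L, sensor_inset = 0.2e-3,
                              noise_level = 0.01,
                              prior = list(), bounds = NULL, seed = 1L) {
  if (is.null(data_grid)) {
    data_grid <- make_grid(64L, 312.5e-6, 4L, 8L, dt = 80e-9, nt = 250L)
  }
  if (is.null(level_grids)) {
    level_grids <- list(
      make_grid(32L, 625e-6, 2L, 6L, dt = 170e-9, nt = 118L),
      make_grid(48L, 416.6667e-6, 3L, 7L, dt = 115e-9, nt = 174L))
  }
  if (is.null(optimizer)) {
    optimizer <- list(list(max_iter = 30L, tol = 1e-4, memory = 20L),
                      list(max_iter = 25L, tol = 1e-4, memory = 20L))
  }
  c_true_range <- c(min(phantom$background_c, phantom$inclusions$c),
                    max(phantom$background_c, phantom$inclusions$c))
  p0_amp <- max(vapply(phantom$p0_sets, function(s) max(s$amplitude),
                       numeric(1)))
  defaults <- list(
    sigma_p0 = choose_sigma(0, p0_amp), mean_p0 = p0_amp / 2,
    sigma_c = choose_sigma(c_true_range[1], c_true_range[2]),
    mean_c = mean(c_true_range), tau = 1.5e-3)
  prior <- utils::modifyList(defaults, prior)
  if (is.null(bounds)) {
    bounds <- list(c_lower = 1300,
                   c_upper = if (is.null(phantom$bone)) 1800 else 3000)
  }
  structure(list(phantom = phantom, data_grid = data_grid,
                 schedule = make_schedule(level_grids, optimizer),
                 sensor = list(count = as.integer(sensor_count),
                               inset = sensor_inset),
                 noise_level = noise_level, prior = prior, bounds = bounds,
                 seed = as.integer(seed)),
            class = "pat_experiment_config")
}

#' Simulate the study datasets for a configuration
#'
#' Rasterises the phantom on the data-simulation grid, runs one forward
#' solve per initial-pressure distribution and adds the configured noise
#' (seeded per dataset from the config seed).
#'
#' @param config a `pat_experiment_config`.
#' @return list with `data` (noisy `pat_sensor_data` list), `clean` (noise-
#'   free), `truth` (list `p0`, `c_target`), and the `data_grid`.
#' @export
simulate_study_data <- function(config) {
  grid <- config$data_grid
  ph <- build_simple_phantom(config$phantom, grid)
  sensors <- place_sensors(grid, config$sensor$count, config$sensor$inset)
  clean <- lapply(seq_along(ph$p0), function(i) {
    d <- simulate_forward(ph$medium, ph$p0[[i]], grid, sensors)
    d$dataset <- i
    d
  })
  noisy <- lapply(seq_along(clean), function(i) {
    add_noise(clean[[i]], config$noise_level,
              seed = config$seed * 1000L + i)
  })
  list(data = noisy, clean = clean,
       truth = list(p0 = ph$p0, c_target = ph$c_target),
       data_grid = grid, sensors = sensors)
}

#' Run a reconstruction experiment
#'
#' Simulates the datasets on the data grid, runs the multigrid joint
#' reconstruction (all I datasets in `"proposed"` mode, only the first in
#' `"reference"` mode) and reports relative errors against the truth
#' resampled onto the finest reconstruction grid.
#'
#' @param config a `pat_experiment_config`.
#' @param mode `"proposed"` or `"reference"`.
#' @param study optional precomputed output of [simulate_study_data()]
#'   (reused across modes to share the identical noise realisation).
#' @param verbose print progress.
#' @return list with `result` (a `pat_result`), `errors` (list `E_p0`
#'   vector, `E_c` scalar), `truth_on_finest`, and `config`.
#' @export
run_experiment <- function(config, mode = c("proposed", "reference"),
                           study = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  if (is.null(study)) study <- simulate_study_data(config)
  data <- if (mode == "proposed") study$data else study$data[1]

  sigma <- vapply(data, estimate_noise_std, numeric(1),
                  level = config$noise_level)
  noise <- lapply(sigma, make_noise_model)

  result <- run_multigrid(
    config$schedule, data,
    sensor_spec = config$sensor,
    prior_spec = config$prior,
    noise = noise,
    bounds_spec = config$bounds,
    data_dx = study$data_grid$dx,
    verbose = verbose)

  fine <- result$grid
  truth_p0 <- lapply(study$truth$p0[seq_along(data)], truth_on_grid,
                     from = study$data_grid, to = fine)
  truth_c <- truth_on_grid(study$truth$c_target, study$data_grid, fine)
  E_p0 <- vapply(seq_along(data), function(i) {
    relative_error(truth_p0[[i]], result$p0[[i]])
  }, numeric(1))
  E_c <- relative_error(truth_c, result$c)
  list(result = result,
       errors = list(E_p0 = E_p0, E_c = E_c),
       truth_on_finest = list(p0 = truth_p0, c = truth_c),
       config = config, mode = mode)
}

#' Paired proposed-versus-reference twin study
#'
#' Runs the reduced-scale twin experiment across several noise seeds and
#' collects the relative errors of both reconstruction modes on identical
#' noisy data.
#'
#' @param seeds integer vector of noise seeds.
#' @param config base configuration (the per-seed runs replace its seed).
#' @param verbose print per-seed progress.
#' @return data.frame with one row per seed: `seed`, `E_c_proposed`,
#'   `E_c_reference`, `E_p01_proposed`, `E_p01_reference`.
#' @export
twin_study <- function(seeds = 1:10, config = experiment_config(),
                       verbose = FALSE) {
  rows <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    study <- simulate_study_data(cfg)
    prop <- run_experiment(cfg, "proposed", study = study)
    ref <- run_experiment(cfg, "reference", study = study)
    if (verbose) {
      message(sprintf("seed %d: E_c %.2f%% (proposed) vs %.2f%% (reference)",
                      s, prop$errors$E_c, ref$errors$E_c))
    }
    data.frame(seed = s,
               E_c_proposed = prop$errors$E_c,
               E_c_reference = ref$errors$E_c,
               E_p01_proposed = prop$errors$E_p0[1],
               E_p01_reference = ref$errors$E_p0[1])
  })
  do.call(rbind, rows)
}

#' Read an experiment configuration from a YAML file
#'
#' Grid blocks use the config units `dx_um`, `dt_ns`, `inset_mm`, `tau_mm`;
#' omitted sections fall back to the reduced-scale defaults of
#' [experiment_config()].
#'
#' @param path YAML file; see
#'   `system.file("extdata", "twin_experiment.yaml", package = "patjrec")`
#'   for the schema.
#' @return a `pat_experiment_config`.
#' @export
read_experiment_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read config files")
  }
  cf <- yaml::read_yaml(path)
  grid_from <- function(b) {
    make_grid(b$n_interior, b$dx_um * 1e-6, b$n_sensor_margin, b$n_pml,
              dt = b$dt_ns * 1e-9, nt = b$nt)
  }
  args <- list()
  if (!is.null(cf$phantom)) {
    args$phantom <- do.call(simple_phantom_spec, cf$phantom)
  }
  if (!is.null(cf$data_grid)) args$data_grid <- grid_from(cf$data_grid)
  if (!is.null(cf$levels)) args$level_grids <- lapply(cf$levels, grid_from)
  if (!is.null(cf$optimizer)) args$optimizer <- cf$optimizer
  if (!is.null(cf$sensor)) {
    args$sensor_count <- cf$sensor$count
    args$sensor_inset <- cf$sensor$inset_mm * 1e-3
  }
  if (!is.null(cf$noise_level)) args$noise_level <- cf$noise_level
  if (!is.null(cf$prior)) {
    pr <- cf$prior
    if (!is.null(pr$tau_mm)) { pr$tau <- pr$tau_mm * 1e-3; pr$tau_mm <- NULL }
    args$prior <- pr
  }
  if (!is.null(cf$bounds)) args$bounds <- cf$bounds
  if (!is.null(cf$seed)) args$seed <- cf$seed
  do.call(experiment_config, args)
}
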