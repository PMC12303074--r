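#!/usr/bin/env Rscript
# Full-scale simple-phantom study: data simulated on the 335 px / 63.7 um
# grid (1747 time steps) and reconstructed through multigrid levels 1-4,
# with the proposed multi-dataset mode and the single-dataset reference.
#
# NOT desk scale: a single variant takes several hours on one CPU and a few
# GiB of memory.  Run e.g.
#   Rscript scripts/reproduce_full_table.R --variant low_contrast --seed 1
#
# Relative errors comparable to the package's reported tables depend on the
# inclusion geometry, which is approximate (the reference figures are not
# tabulated), so errors are expected to agree in ordering and rough
# magnitude rather than digit for digit.

suppressMessages({
  library(optparse)
  library(patjrec)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--variant", type = "character", default = "low_contrast",
              help = "low_contrast | water_bath | high_contrast"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "results/full_scale")
)))

dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)

data_grid <- study_grids("data")
levels <- study_grids(1:4)
phantom <- simple_phantom_spec(opts$variant)

cfg <- experiment_config(
  phantom = phantom,
  data_grid = data_grid,
  level_grids = levels,
  optimizer = rep(list(list(max_iter = 200L, tol = 1e-4, memory = 20L)), 4),
  sensor_count = 236L,
  sensor_inset = 0.2e-3,
  noise_level = 0.01,
  prior = list(tau = 1.5e-3,
               mean_c = if (opts$variant == "high_contrast") 1482 else 1505,
               sigma_c = choose_sigma(1430, 1580)),
  bounds = list(c_lower = 1300,
                c_upper = if (opts$variant == "high_contrast") 3000 else 1800),
  seed = opts$seed)

message("simulating data on the ", data_grid$n_interior, " px grid ...")
study <- simulate_study_data(cfg)

for (mode in c("proposed", "reference")) {
  message("reconstructing (", mode, ") ...")
  out <- run_experiment(cfg, mode, study = study, verbose = TRUE)
  err <- data.frame(field = c(paste0("E_p0_", seq_along(out$errors$E_p0)),
                              "E_c"),
                    percent = c(out$errors$E_p0, out$errors$E_c))
  print(err)
  write.csv(err, file.path(opts$out, sprintf("errors_%s_%s_seed%d.csv",
                                             opts$variant, mode, opts$seed)),
            row.names = FALSE)
  saveRDS(out$result, file.path(opts$out, sprintf("result_%s_%s_seed%d.rds",
                                                  opts$variant, mode,
                                                  opts$seed)))
}
message("done; outputs in ", opts$out)
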