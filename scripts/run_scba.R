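#!/usr/bin/env Rscript
# Command-line wrapper around the package pipeline.
#
#   Rscript scripts/run_scba.R --scenario meat15 --seed 1 --n-iter 100 \
#       --out out_dir [--config cfg.yaml] [--sensitivity]
#
# Writes trajectory.csv, impact.csv, health_delta.csv, cashflows.csv,
# ledger.csv, ledger_by_stakeholder.csv and manifest.json into --out;
# with --sensitivity additionally sensitivity.csv (one-way variants).

suppressPackageStartupMessages({
  library(optparse)
  library(foodscba)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--scenario", type = "character", default = "meat15",
              help = "reference, meat15, meat30 or fv10"),
  make_option("--config", type = "character", default = NULL,
              help = "optional YAML configuration"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--n-iter", type = "integer", default = 100L, dest = "n_iter"),
  make_option("--out", type = "character", default = "scba_out"),
  make_option("--sensitivity", action = "store_true", default = FALSE)
)))

config <- if (is.null(opts$config)) {
  scba_config()
} else {
  read_scba_config(opts$config)
}

fit <- scba(opts$scenario, config, seed = opts$seed, n_iter = opts$n_iter)
write_scba_outputs(fit, opts$out)
print(fit)

if (opts$sensitivity) {
  sens <- run_sensitivity(opts$scenario, config, seed = opts$seed,
                          n_iter = opts$n_iter)
  utils::write.csv(sens$summary, file.path(opts$out, "sensitivity.csv"),
                   row.names = FALSE)
  print(sens)
}
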