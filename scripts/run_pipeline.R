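#!/usr/bin/env Rscript
# Thin shell entry point over comorbidikit::run_pipeline().
#   Rscript scripts/run_pipeline.R --scenario ami --n 5000 --reps 200 \
#       --seed 42 --out results/run
suppressPackageStartupMessages({
  library(optparse)
  library(comorbidikit)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--scenario", default = "ami",
              help = "bundled scenario name or YAML path [default %default]"),
  make_option("--config", default = NULL,
              help = "full run-config YAML (overrides --scenario)"),
  make_option("--n", type = "integer", default = 5000L,
              help = "number of simulated patients [default %default]"),
  make_option("--reps", type = "integer", default = 200L,
              help = "bootstrap replications [default %default]"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", default = "results/run")
)))

cfg <- if (!is.null(opts$config)) opts$config else
  run_config(scenario = opts$scenario, n_patients = opts$n,
             n_bootstrap = opts$reps, seed = opts$seed)
tryCatch({
  run_pipeline(cfg, opts$out)
  render_tables(opts$out)
  cat("report written to", file.path(opts$out, "report.md"), "\n")
}, error = function(e) {
  message("pipeline failed: ", conditionMessage(e))
  quit(status = 2)
})
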