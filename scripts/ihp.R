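#!/usr/bin/env Rscript

# Thin shell front end over holophos::run_pipeline().
#
# Usage:
#   Rscript scripts/ihp.R run --config config.yaml
#   Rscript scripts/ihp.R run --seed 7 --outdir out/          # all defaults
#
# The YAML config schema is documented in ?holophos::run_config.

suppressMessages({
  library(optparse)
  library(holophos)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L || args[1] != "run") {
  cat("usage: Rscript scripts/ihp.R run [--config FILE | --seed N --outdir DIR]\n")
  quit(status = 2)
}

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--outdir", type = "character", default = "ihp_run")
)), args = args[-1])

config <- if (!is.null(opts$config)) {
  read_run_config(opts$config)
} else {
  run_config(seed = opts$seed, outdir = opts$outdir)
}

report <- run_pipeline(config)
message(sprintf("pipeline complete; report at %s",
                file.path(config$outdir, "report.json")))
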