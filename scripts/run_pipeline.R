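#!/usr/bin/env Rscript
# Thin shell entry point over vilipower::run_pipeline(). Usage:
#   Rscript scripts/run_pipeline.R [--config cfg.yaml] [--scenario name]
#                                  [--seed int] [--out dir]
# CLI flags take precedence over values in the YAML config.

suppressPackageStartupMessages({
  library(optparse)
  library(vilipower)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML configuration file"),
  make_option("--scenario", type = "character", default = NULL,
              help = "cohort8 | table1_like | patlak_demo"),
  make_option("--seed", type = "integer", default = NULL),
  make_option("--out", type = "character", default = NULL,
              help = "output directory")
)))

cfg <- if (is.null(opts$config)) run_config() else read_run_config(opts$config)
if (!is.null(opts$scenario)) cfg$scenario <- opts$scenario
if (!is.null(opts$seed)) cfg$seed <- opts$seed
if (!is.null(opts$out)) cfg$output_dir <- opts$out

res <- run_pipeline(cfg)
message("wrote ", length(Filter(is.data.frame, res)), " tables to ",
        cfg$output_dir)
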