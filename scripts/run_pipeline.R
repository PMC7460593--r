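#!/usr/bin/env Rscript

# Thin command-line wrapper over protonrbe::run_pipeline().
#
#   Rscript scripts/run_pipeline.R [--config cfg.json] [--seed 1] [--outdir out]
#
# Without --config, the packaged default configuration (the full
# PBS-vs-DS study layout) is used.

suppressPackageStartupMessages({
  library(optparse)
  library(protonrbe)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--outdir", type = "character", default = "pipeline_out")
)))

cfg <- if (is.null(opts$config)) {
  default_pipeline_config(seed = opts$seed, output_dir = opts$outdir)
} else {
  read_pipeline_config(opts$config)
}
cfg$seed <- opts$seed
cfg$output_dir <- opts$outdir

res <- run_pipeline(cfg)
cat("report bundle written to", res$output_dir, "\n")
print(res$rbe)
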