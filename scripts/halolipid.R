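#!/usr/bin/env Rscript
# Thin command-line wrapper over halolipid::run_stage().
#
# Usage: Rscript scripts/halolipid.R <stage> [--config <yaml>]
#          [--seed <int>] [--out-dir <dir>] [--log-level <level>]
# Stages: build-library simulate annotate cores network chemotax report all

suppressPackageStartupMessages({
  library(optparse)
  library(halolipid)
})

parser <- OptionParser(
  usage = "%prog <stage> [options]",
  option_list = list(
    make_option("--config", type = "character", default = NULL),
    make_option("--seed", type = "integer", default = NULL),
    make_option("--out-dir", type = "character", default = "halolipid_out",
                dest = "out_dir"),
    make_option("--log-level", type = "character", default = "info",
                dest = "log_level")
  ))
args <- parse_args(parser, positional_arguments = 1)
stage <- args$args

config <- run_config(args$options$config)
if (!is.null(args$options$seed)) config$seed <- args$options$seed

runner <- function() {
  if (stage == "all") run_pipeline(config, args$options$out_dir)
  else run_stage(stage, config, args$options$out_dir)
}
if (args$options$log_level == "quiet") {
  suppressMessages(runner())
} else {
  runner()
}
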