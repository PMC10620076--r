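#!/usr/bin/env Rscript
# Thin command-line wrapper over tistim::run_pipeline().
# Usage: Rscript scripts/run_pipeline.R [--config cfg.yaml] --out dir/

suppressPackageStartupMessages(library(tistim))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(config = NULL, out = NULL)
i <- 1
while (i <= length(args)) {
  if (args[i] == "--config") { opt$config <- args[i + 1]; i <- i + 2 }
  else if (args[i] == "--out") { opt$out <- args[i + 1]; i <- i + 2 }
  else stop("unknown argument: ", args[i])
}
if (is.null(opt$out)) stop("--out is required")

cfg <- if (is.null(opt$config)) run_config() else read_run_config(opt$config)
manifest <- run_pipeline(cfg, opt$out)
cat(sprintf("wrote %d artifacts to %s\n", nrow(manifest$files), opt$out))
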