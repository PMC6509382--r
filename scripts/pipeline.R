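#!/usr/bin/env Rscript
# Thin command-line wrapper over pbsn::run_pipeline(): run the complete
# sociospatial analysis either on a telemetry CSV or on a simulated study.
#
# Usage:
#   Rscript scripts/pipeline.R --telemetry fixes.csv --out results/
#   Rscript scripts/pipeline.R --simulate --seed 7 --n-iter 500 --out results/

suppressMessages({
  library(optparse)
  library(pbsn)
})

parser <- OptionParser(option_list = list(
  make_option("--telemetry", type = "character", default = NULL,
              help = "telemetry CSV (animal_id, herd, timestamp, x, y)"),
  make_option("--simulate", action = "store_true", default = FALSE,
              help = "simulate the default two-season study instead"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--n-iter", type = "integer", default = 1000L, dest = "n_iter",
              help = "permutation iterations [default %default]"),
  make_option("--assoc-dist", type = "double", default = 50, dest = "assoc_dist"),
  make_option("--out", type = "character", default = "pbsn-results")
))
opt <- parse_args(parser)

input <- if (!is.null(opt$telemetry)) {
  list(mode = "telemetry", path = opt$telemetry)
} else if (opt$simulate) {
  list(mode = "simulate")
} else {
  stop("supply --telemetry <csv> or --simulate")
}

cfg <- pipeline_config(
  input = input, seed = opt$seed, n_iter = opt$n_iter,
  assoc_dist = opt$assoc_dist, out_dir = opt$out
)
res <- run_pipeline(cfg)
print(tidy(res$models))
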