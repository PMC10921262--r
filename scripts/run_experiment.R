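#!/usr/bin/env Rscript
# Command-line entry point for the batch experiments: a thin wrapper over
# prebotc::run_experiment(). Results (CSV tables, a JSON summary and a
# config echo) are written to --outdir.
#
# Examples (from the repository root, with the package installed):
#   Rscript scripts/run_experiment.R ramp_batch --n-networks 10 --outdir out/
#   Rscript scripts/run_experiment.R mor_policy --n-networks 6 --outdir out/
#   Rscript scripts/run_experiment.R gnap_rescue --factor 1.3 --outdir out/
#   Rscript scripts/run_experiment.R density_sweep --density 1,4 --outdir out/

suppressPackageStartupMessages({
  library(optparse)
  library(prebotc)
})

parser <- OptionParser(
  usage = paste("%prog <experiment> [options] — experiment is one of:",
                "ramp_batch, sensitivity_split, density_sweep,",
                "topology_correlation, mor_policy, gnap_rescue,",
                "gleak_rescue, phase_diagram"),
  option_list = list(
    make_option("--n-networks", type = "integer", default = 40,
                dest = "n_networks", help = "batch size [default %default]"),
    make_option("--seed", type = "integer", default = 1,
                help = "base seed; network i uses seed + i - 1"),
    make_option("--density", type = "character", default = "1,2,4,8,16",
                help = "comma-separated density factors [default %default]"),
    make_option("--mor-policy", type = "character", default = "random",
                dest = "mor_policy",
                help = "random, low or high (g_leak targeting)"),
    make_option("--factor", type = "character", default = NULL,
                help = "comma-separated drug factors for the rescue runs"),
    make_option("--dt", type = "double", default = 0.05,
                help = "integration step in ms [default %default]"),
    make_option("--outdir", type = "character", default = "prebotc_out",
                help = "output directory [default %default]")
  ))
opt <- parse_args(parser, positional_arguments = 1)

policy <- c(random = "random", low = "low_gleak", high = "high_gleak",
            low_gleak = "low_gleak", high_gleak = "high_gleak")
cfg <- experiment_config(
  experiment = opt$args,
  n_networks = opt$options$n_networks,
  base_seed = opt$options$seed,
  dt = opt$options$dt,
  mor_policy = unname(policy[opt$options$mor_policy]),
  density_factors = as.numeric(strsplit(opt$options$density, ",")[[1]]),
  drug_factors = if (!is.null(opt$options$factor))
    as.numeric(strsplit(opt$options$factor, ",")[[1]]),
  outdir = opt$options$outdir
)

t0 <- proc.time()[3]
message(sprintf("[%s] starting %s (n = %d, seed = %d)",
                format(Sys.time(), "%H:%M:%S"), cfg$experiment,
                cfg$n_networks, cfg$base_seed))
res <- run_experiment(cfg)
message(sprintf("[%s] done in %.1f s; results in %s",
                format(Sys.time(), "%H:%M:%S"), proc.time()[3] - t0,
                cfg$outdir))
if (!is.null(res$summary)) print(res$summary)
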