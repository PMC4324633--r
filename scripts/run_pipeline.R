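#!/usr/bin/env Rscript
# Thin command-line wrapper over the revtax pipeline.
#
#   Simulate a synthetic survey:
#     Rscript scripts/run_pipeline.R simulate --seed 1 --out data_dir
#     Rscript scripts/run_pipeline.R simulate --preset paper-like --seed 1 --out data_dir
#
#   Run the full analysis on FASTA + metadata + station tables:
#     Rscript scripts/run_pipeline.R run --fasta f.fasta --metadata m.tsv \
#       --stations s.tsv --out results_dir [--threshold 0.97]
#       [--min-overlap 400] [--permutations-anosim 999]
#       [--permutations-mantel 5000] [--geo-mode euclidean_degrees]
#       [--seed 1] [--aligned]

suppressPackageStartupMessages({
  library(optparse)
  library(revtax)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || !args[1] %in% c("simulate", "run")) {
  stop("usage: run_pipeline.R <simulate|run> [options]; see script header")
}
cmd <- args[1]

if (cmd == "simulate") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--seed", type = "integer", default = 1),
    make_option("--preset", type = "character", default = "default"),
    make_option("--out", type = "character", default = "simulated")
  )), args = args[-1])
  if (opts$preset == "paper-like") {
    study <- simulate_study(opts$seed)
    for (grp in names(study))
      write_dataset(study[[grp]], file.path(opts$out, grp))
  } else {
    write_dataset(simulate_dataset(sim_config(seed = opts$seed)), opts$out)
  }
  cat("simulated dataset written to", opts$out, "\n")
} else {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--fasta", type = "character"),
    make_option("--metadata", type = "character"),
    make_option("--stations", type = "character"),
    make_option("--out", type = "character", default = "results"),
    make_option("--threshold", type = "double", default = 0.97),
    make_option("--min-overlap", type = "integer", default = 400L,
                dest = "min_overlap"),
    make_option("--permutations-anosim", type = "integer", default = 999L,
                dest = "perm_anosim"),
    make_option("--permutations-mantel", type = "integer", default = 5000L,
                dest = "perm_mantel"),
    make_option("--geo-mode", type = "character",
                default = "euclidean_degrees", dest = "geo_mode"),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--aligned", action = "store_true", default = FALSE)
  )), args = args[-1])
  records <- join_metadata(read_fasta(opts$fasta), opts$metadata)
  stations <- read_station_table(opts$stations)
  cfg <- pipeline_config(
    cluster = cluster_config(opts$threshold, opts$min_overlap),
    aligned = opts$aligned,
    n_permutations_anosim = opts$perm_anosim,
    n_permutations_mantel = opts$perm_mantel,
    geo_mode = opts$geo_mode, seed = opts$seed)
  res <- run_pipeline(records, stations, cfg)
  write_results_bundle(res, opts$out)
  cat("results bundle written to", opts$out, "\n")
}
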