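#!/usr/bin/env Rscript
# Thin command-line wrapper over ampliphase::run_pipeline().
#
#   Rscript scripts/pipeline.R [--n 300] [--seed 1] [--stages simulate,genotype,haplotype,validate]
#                              [--out run_dir] [--observations obs.fasta]
#                              [--min-support 4] [--bootstrap-B 100]
#
# Exit codes: 0 success, 2 validation deviations present, 3 stage failure.

suppressMessages(library(ampliphase))
suppressMessages(library(optparse))

opts <- parse_args(OptionParser(option_list = list(
  make_option("--n", type = "integer", default = 300L),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--stages", type = "character",
              default = "simulate,genotype,haplotype,validate"),
  make_option("--out", type = "character", default = NULL),
  make_option("--observations", type = "character", default = NULL,
              help = "consensus FASTA (individual|assay headers) replacing simulation"),
  make_option("--min-support", type = "integer", default = 4L,
              dest = "min_support"),
  make_option("--bootstrap-B", type = "integer", default = 100L,
              dest = "bootstrap_B"))))

obs <- if (!is.null(opts$observations))
  read_observations_fasta(opts$observations) else NULL

cfg <- pipeline_config(
  n = opts$n, seed = opts$seed,
  stages = strsplit(opts$stages, ",")[[1]],
  min_support = opts$min_support,
  bootstrap_B = opts$bootstrap_B,
  observations = obs,
  output_dir = opts$out)

report <- tryCatch(run_pipeline(cfg), error = function(e) {
  message("stage failure: ", conditionMessage(e))
  quit(status = 3L)
})
print(report)
if (!is.null(report$deviations) && nrow(report$deviations) > 0L)
  quit(status = 2L)
quit(status = 0L)
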