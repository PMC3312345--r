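#!/usr/bin/env Rscript
# The model-comparison analysis: for each simulated block, fit both cost
# models by cross-validated trajectory MSE (45 train / 5 test out of a random
# 50-trial draw per fold) and test the paired test-error differences with the
# exact two-sided sign test. Reads the data written by 01_simulate.R and
# writes per-fold error tables and a summary under results/fits/.
#
# Folds default to 25 (the full design uses 100); the noiseless blocks use
# the same fold count but rely on the Bellman solver per evaluation, which
# dominates the runtime of this script.

suppressPackageStartupMessages({
  library(optparse)
  library(steercost)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--data-dir", type = "character", default = "results/data",
              dest = "data_dir"),
  make_option("--out-dir", type = "character", default = "results/fits",
              dest = "out_dir"),
  make_option("--folds", type = "integer", default = 25L),
  make_option("--blocks", type = "character",
              default = "one_std_nu_0.04,one_ext_nu_0.04,two_ext_nu_0.04,one_ext_nu_0",
              help = "comma-separated block stems to analyse")
)))
dir.create(opts$out_dir, showWarnings = FALSE, recursive = TRUE)

stems <- strsplit(opts$blocks, ",")[[1]]
rows <- list()
for (stem in stems) {
  cfg <- read_task_config(file.path(opts$data_dir, paste0(stem, ".yaml")))
  blk <- read_trials(file.path(opts$data_dir, paste0(stem, ".csv")), cfg)
  t0 <- Sys.time()
  cmp <- cross_validate(blk, n_folds = opts$folds, seed = opts$seed)
  el <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  cat(sprintf("%-22s median diff %9.4g  IQR [%9.4g, %9.4g]  sign p %8.3g  (%.0f s)\n",
              stem, cmp$median, cmp$q25, cmp$q75, cmp$sign_test_p, el))
  write.csv(data.frame(fold = seq_along(cmp$paired_diffs),
                       diff = cmp$paired_diffs),
            file.path(opts$out_dir, paste0("folds_", stem, ".csv")),
            row.names = FALSE)
  rows[[stem]] <- data.frame(block = stem, median_diff = cmp$median,
                             q25 = cmp$q25, q75 = cmp$q75,
                             sign_test_p = cmp$sign_test_p,
                             n_folds = opts$folds)
}
summary_df <- do.call(rbind, rows)
write.csv(summary_df, file.path(opts$out_dir, "comparison_summary.csv"),
          row.names = FALSE)

jsonlite::write_json(
  list(command = "03_fit", seed = opts$seed, folds = opts$folds,
       blocks = stems,
       package_version = as.character(packageVersion("steercost")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
  file.path(opts$out_dir, "manifest_03.json"), auto_unbox = TRUE, pretty = TRUE)
cat("done; fits under", opts$out_dir, "\n")
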