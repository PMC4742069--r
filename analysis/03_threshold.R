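#!/usr/bin/env Rscript
# Data-driven expression threshold from replicate partitioning: each gene's
# reads split between the two footprint replicates like a binomial draw, so
# below some mean count the observed replicate-fraction SD is pure counting
# noise. The threshold is the first run of bins whose observed SD stays
# a factor above the binomial prediction, i.e. where biological variability
# becomes detectable over sampling noise.

source("analysis/config.R")

counts <- read_count_table(file.path(RESULTS_DIR, "counts.tsv"))
rep1 <- counts[, "rpf_exercise_1"]
rep2 <- counts[, "rpf_exercise_2"]
libs <- library_sizes(counts)[c("rpf_exercise_1", "rpf_exercise_2")]

rf <- replicate_fraction(rep1, rep2)
sel <- local({
  bins <- add_predicted_sd(bin_fraction_sd(rf$fraction, rf$total),
                           p = libs[1] / sum(libs))
  select_threshold(bins, mean_library_size = mean(libs))
})

utils::write.table(sel$bins, file.path(RESULTS_DIR, "threshold_bins.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(sel[c("found", "threshold_mean_count", "threshold_rpm",
                           "bin_index")],
                     file.path(RESULTS_DIR, "threshold.json"),
                     auto_unbox = TRUE, digits = NA)

if (sel$found) {
  cat(sprintf("expression threshold: mean count %.1f = %.1f RPM (bin %d of %d)\n",
              sel$threshold_mean_count, sel$threshold_rpm, sel$bin_index,
              nrow(sel$bins)))
} else {
  cat("no bin run exceeded the binomial prediction; threshold not found\n")
}
cat("wrote threshold_bins.tsv, threshold.json to", RESULTS_DIR, "\n")
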