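#!/usr/bin/env Rscript
# Translational efficiency (footprint RPM / mRNA RPM) per condition for
# genes above the expression threshold, the TOP vs non-TOP shift test
# (Kolmogorov-Smirnov on log TE ratios), and a PCA of log2 RPM profiles.
# Acute exercise lowers mTOR output, so TOP-motif genes should shift to
# lower TE after exercise while bulk genes stay put.

source("analysis/config.R")

ann <- load_annotation(file.path(RESULTS_DIR, "annotation.tsv"))
counts <- read_count_table(file.path(RESULTS_DIR, "counts.tsv"))
thr <- jsonlite::read_json(file.path(RESULTS_DIR, "threshold.json"),
                           simplifyVector = TRUE)

rpm <- rpm_normalize(counts)
conditions <- setNames(SAMPLES$condition, SAMPLES$sample_id)
keep <- if (isTRUE(thr$found)) {
  threshold_genes(rpm, thr$threshold_rpm)
} else ann$gene_id

is_rpf <- startsWith(colnames(rpm), "rpf_")
te <- translational_efficiency(rpm[, is_rpf], rpm[, !is_rpf], conditions, keep)
shift <- top_shift_test(te, ann)
pca <- pca_profiles(rpm, te$gene_id)

utils::write.table(te, file.path(RESULTS_DIR, "te.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(sample_id = rownames(pca$scores), pca$scores),
                   file.path(RESULTS_DIR, "pca_scores.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(n_genes_above_threshold = length(keep),
       ks_D = shift$ks$D, ks_p_value = shift$ks$p_value,
       median_log_te_ratio_top = shift$median_top,
       median_log_te_ratio_other = shift$median_other,
       top_suppressed = shift$top_suppressed,
       pca_variance_explained = pca$var_explained),
  file.path(RESULTS_DIR, "te_summary.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("%d genes above threshold; %d with finite TE\n",
            length(keep), nrow(te)))
cat(sprintf("TOP shift: D = %.3f, p = %.3g; median log2 TE ratio TOP %.2f vs other %.2f (%s)\n",
            shift$ks$D, shift$ks$p_value, shift$median_top / log(2),
            shift$median_other / log(2),
            ifelse(shift$top_suppressed, "TOP suppressed", "no suppression")))
cat("wrote te.tsv, pca_scores.tsv, te_summary.json to", RESULTS_DIR, "\n")
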