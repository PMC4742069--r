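#!/usr/bin/env Rscript
# Expression-panel regression: which transcripts track SLC25A25 protein
# across animals? Per-group Pearson correlations, then OLS with backward
# elimination on the pooled early groups (no-exercise, 0 h, 1 h; n = 18),
# dropping the least significant predictor while its p-value exceeds
# alpha_stay.

source("analysis/config.R")

panel <- read_panel(file.path(RESULTS_DIR, "panel.tsv"))

edges <- group_correlations(panel, groups = unique(panel$group))
res <- backward_eliminate(panel)

utils::write.table(edges, file.path(RESULTS_DIR, "panel_correlations.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(res$trace, file.path(RESULTS_DIR, "elimination_trace.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(res$final$coefficients,
                   file.path(RESULTS_DIR, "final_model.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

removed <- res$trace$removed[!is.na(res$trace$removed)]
cat(sprintf("backward elimination removed %d predictor(s): %s\n",
            length(removed), paste(removed, collapse = ", ")))
cat(sprintf("final model (R^2 = %.3f, n = %d):\n",
            res$final$r_squared, res$final$n))
print(res$final$coefficients, digits = 3)
cat("wrote panel_correlations.tsv, elimination_trace.tsv, final_model.tsv to",
    RESULTS_DIR, "\n")
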