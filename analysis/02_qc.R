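#!/usr/bin/env Rscript
# Sequencing-validity diagnostics on the simulated libraries: replicate
# correlation on the log2 RPM scale, triplet periodicity of footprint 5'
# ends, and the metagene density around the start codon with a peak call.
# Footprints should phase with the coding frame and pile up 4 codons
# upstream of the AUG; mRNA-Seq fragments should do neither.

source("analysis/config.R")

ann <- load_annotation(file.path(RESULTS_DIR, "annotation.tsv"))
counts <- read_count_table(file.path(RESULTS_DIR, "counts.tsv"))
rpm <- rpm_normalize(counts)
abund <- load_abundances(CFG, ann)

rpf <- simulate_sample_reads(CFG, ann, abund,
                             list(assay = "rpf", condition = "control",
                                  replicate = 1))
mrna <- simulate_sample_reads(CFG, ann, abund,
                              list(assay = "mrna", condition = "control",
                                   replicate = 1))

fp_rpf <- frame_periodicity(rpf, ann)$global$fractions
fp_mrna <- frame_periodicity(mrna, ann)$global$fractions
prof <- metagene_profile(rpf, ann)
peak <- find_start_peak(prof)
prof_mrna <- metagene_profile(mrna, ann)
peak_mrna <- find_start_peak(prof_mrna)
r_rep <- replicate_correlation(rpm[, "rpf_control_1"], rpm[, "rpf_control_2"])

utils::write.table(prof, file.path(RESULTS_DIR, "metagene_profile.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(frame_fractions_rpf = as.list(fp_rpf),
       frame_fractions_mrna = as.list(fp_mrna),
       peak_rpf = peak, peak_mrna = peak_mrna,
       replicate_correlation_log2 = r_rep),
  file.path(RESULTS_DIR, "qc_summary.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("RPF frame fractions: 0 = %.3f, +1 = %.3f, -1 = %.3f (mRNA-Seq: %.3f/%.3f/%.3f)\n",
            fp_rpf[1], fp_rpf[2], fp_rpf[3], fp_mrna[1], fp_mrna[2], fp_mrna[3]))
cat(sprintf("RPF start peak: %s at %d nt = %d codons (mRNA-Seq peak: %s)\n",
            ifelse(peak$found, "found", "absent"), peak$peak_nt,
            peak$peak_codon, ifelse(peak_mrna$found, "found", "absent")))
cat(sprintf("replicate Pearson r (log2 RPM): %.4f\n", r_rep))
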