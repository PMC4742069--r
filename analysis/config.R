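# Shared settings for the numbered analysis scripts. Every script sources
# this file, so the whole chain is reproducible from one seed; stages that
# need raw reads re-simulate them deterministically from the same config
# instead of storing multi-million-row read tables on disk.

library(riboshift)

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

CFG <- sim_config(seed = 20160L)          # study-shaped defaults
PANEL_CFG <- panel_config(seed = 20160L)

SAMPLES <- expand.grid(assay = c("rpf", "mrna"),
                       condition = c("control", "exercise"),
                       replicate = 1:2, stringsAsFactors = FALSE)
SAMPLES$sample_id <- with(SAMPLES, paste(assay, condition, replicate, sep = "_"))

simulate_sample_reads <- function(cfg, ann, abund, row) {
  ab <- if (row$assay == "rpf") abund[[row$condition]]$ribo[, row$replicate]
        else abund[[row$condition]]$rna[, row$replicate]
  sid <- paste0(row$condition, "_rep", row$replicate)
  reads <- if (row$assay == "rpf") simulate_rpf_reads(cfg, ann, ab, sid)
           else simulate_mrna_reads(cfg, ann, ab, sid)
  filter_by_length(reads)
}

load_abundances <- function(cfg, ann) {
  list(control = simulate_abundances(cfg, ann, "control"),
       exercise = simulate_abundances(cfg, ann, "exercise"))
}
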