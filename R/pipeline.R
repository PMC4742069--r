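#' Run the full simulated analysis chain
#'
#' Orchestrates simulate -> count -> QC -> threshold -> translational
#' efficiency -> panel regression as one seeded, reproducible run. Each
#' enabled stage appears in the report with a pass/fail status; a stage
#' failure aborts with the failing stage named (partial outputs already
#' written are retained). When `outdir` is given, stage outputs (TSV/JSON
#' only) and a provenance JSON recording the seed and configuration are
#' written there.
#'
#' @param config A [sim_config()] (drives the simulation; its `seed` is the
#'   root seed of the run).
#' @param pconfig A [panel_config()] for the regression stage (defaults to
#'   one derived from the same seed).
#' @param stages Character subset of
#'   `c("qc", "threshold", "te", "pca", "regress")`.
#' @param threshold_rpm `"auto"` (select from the data) or a numeric RPM
#'   override.
#' @param outdir Optional output directory.
#' @return A list of class `run_report` with one entry per enabled stage
#'   plus `seed` and `stage_status`.
#' @export
run_pipeline <- function(config = sim_config(),
                         pconfig = panel_config(seed = config$seed),
                         stages = c("qc", "threshold", "te", "pca", "regress"),
                         threshold_rpm = "auto",
                         outdir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  report <- list(seed = config$seed)
  status <- stats::setNames(rep("skipped", length(stages)), stages)
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- simulate (always; everything downstream consumes it) ---------------
  ann <- simulate_annotation(config)
  ab_ctrl <- simulate_abundances(config, ann, "control")
  ab_ex <- simulate_abundances(config, ann, "exercise")
  samples <- list()
  for (cond in c("control", "exercise")) {
    ab <- if (cond == "control") ab_ctrl else ab_ex
    for (r in seq_len(config$n_replicates)) {
      sid <- paste0(cond, "_rep", r)
      samples[[paste0("rpf_", sid)]] <-
        simulate_rpf_reads(config, ann, ab$ribo[, r], sid)
      samples[[paste0("mrna_", sid)]] <-
        simulate_mrna_reads(config, ann, ab$rna[, r], sid)
    }
  }
  samples <- lapply(samples, filter_by_length)
  counts <- do.call(cbind_counts, Map(function(rd, sid)
    count_reads(rd, ann, sid), samples, names(samples)))
  rpm <- rpm_normalize(counts)
  if (!is.null(outdir)) {
    write_annotation(ann, file.path(outdir, "annotation.tsv"))
    write_count_table(counts, file.path(outdir, "counts.tsv"))
  }

  is_rpf <- startsWith(colnames(counts), "rpf_")
  conditions <- ifelse(grepl("control", colnames(counts)), "control", "exercise")
  names(conditions) <- colnames(counts)

  # --- qc ------------------------------------------------------------------
  if ("qc" %in% stages) {
    report$qc <- run_stage("qc_metrics", {
      fp <- frame_periodicity(samples$rpf_control_rep1, ann)
      prof <- metagene_profile(samples$rpf_control_rep1, ann)
      peak <- find_start_peak(prof)
      r_rep <- replicate_correlation(rpm[, "rpf_control_rep1"],
                                     rpm[, "rpf_control_rep2"])
      list(frame_fractions = fp$global$fractions,
           periodicity_present = fp$global$fractions["0"] > 0.5,
           peak = peak, replicate_r = r_rep)
    })
    status["qc"] <- "pass"
  }

  # --- threshold -----------------------------------------------------------
  thr <- NULL
  if ("threshold" %in% stages || identical(threshold_rpm, "auto")) {
    report$threshold <- run_stage("expression_threshold", {
      a <- counts[, "rpf_exercise_rep1"]; b <- counts[, "rpf_exercise_rep2"]
      rf <- replicate_fraction(a, b)
      bins <- add_predicted_sd(bin_fraction_sd(rf$fraction, rf$total),
                               p = sum(a) / (sum(a) + sum(b)))
      select_threshold(bins, mean(c(sum(a), sum(b))))
    })
    thr <- report$threshold
    if ("threshold" %in% stages) status["threshold"] <- "pass"
  }
  thr_rpm <- if (identical(threshold_rpm, "auto")) {
    if (!is.null(thr) && thr$found) thr$threshold_rpm else 0
  } else as.numeric(threshold_rpm)
  gene_set <- threshold_genes(rpm[, is_rpf, drop = FALSE], thr_rpm)
  report$threshold_rpm_used <- thr_rpm
  report$n_genes_passing <- length(gene_set)

  # --- te ------------------------------------------------------------------
  if ("te" %in% stages) {
    report$te <- run_stage("translational_analysis", {
      te <- translational_efficiency(rpm[, is_rpf, drop = FALSE],
                                     rpm[, !is_rpf, drop = FALSE],
                                     conditions, gene_set)
      shift <- top_shift_test(te, ann)
      if (!is.null(outdir)) {
        utils::write.table(te, file.path(outdir, "te.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
      list(te = te, top_shift = shift)
    })
    status["te"] <- "pass"
  }

  # --- pca -----------------------------------------------------------------
  if ("pca" %in% stages) {
    report$pca <- run_stage("pca", pca_profiles(rpm, gene_set))
    status["pca"] <- "pass"
  }

  # --- regress -------------------------------------------------------------
  if ("regress" %in% stages) {
    report$regress <- run_stage("panel_regression", {
      panel <- simulate_panel(pconfig)
      if (!is.null(outdir)) write_panel(panel, file.path(outdir, "panel.tsv"))
      list(correlations = group_correlations(panel, c("NoEx", "0h", "1h")),
           elimination = backward_eliminate(panel))
    })
    status["regress"] <- "pass"
  }

  report$stage_status <- status
  if (!is.null(outdir)) {
    prov <- list(seed = config$seed,
                 config = config[setdiff(names(config), "footprint_length_dist")],
                 footprint_length_dist = as.list(config$footprint_length_dist),
                 stages = stages,
                 threshold_rpm_used = thr_rpm,
                 package_version = as.character(utils::packageVersion("riboshift")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  class(report) <- "run_report"
  report
}
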