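#' Per-gene replicate read fraction
#'
#' For each gene, the fraction of its pooled reads observed in replicate A:
#' `f = a / (a + b)`. Under perfect reproducibility with equal library
#' sizes the fraction is 0.5, and pure counting noise makes the observed
#' split Binomial(a + b, p). Genes with no reads in either replicate are
#' excluded (count reported via message).
#'
#' @param counts_a,counts_b Raw count vectors for the two replicates, same
#'   gene order (names taken from `counts_a` if present).
#' @return data.frame with `gene_id`, `fraction`, `total` (a + b).
#' @export
replicate_fraction <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == length(counts_b))
  total <- as.numeric(counts_a) + as.numeric(counts_b)
  keep <- total > 0
  if (any(!keep)) {
    message(sum(!keep), " gene(s) with zero total count excluded from ",
            "replicate-fraction analysis")
  }
  ids <- names(counts_a)
  if (is.null(ids)) ids <- sprintf("gene%05d", seq_along(counts_a))
  data.frame(gene_id = ids[keep],
             fraction = as.numeric(counts_a)[keep] / total[keep],
             total = total[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bin genes by mean count and compute the observed SD of the fraction
#'
#' Genes are assigned by mean count (`total / 2`) to `n_bins` log10-spaced
#' bins between the 1st and 99th percentile of mean counts; per bin the
#' sample SD of the replicate fraction is the observed inter-replicate
#' variation. Bins with fewer than `min_genes` genes are dropped with a
#' warning.
#'
#' @param fractions,totals As returned by [replicate_fraction()] (vectors).
#' @param n_bins Number of log-spaced bins.
#' @param min_genes Minimum genes per retained bin.
#' @return A data.frame of class `bin_stats`, ordered by count, with
#'   columns `bin_index`, `count_low`, `count_high` (mean-count bin edges),
#'   `mean_total` (mean of a + b in the bin), `n_genes`, `observed_sd`.
#' @export
bin_fraction_sd <- function(fractions, totals, n_bins = 20L, min_genes = 5L) {
  stopifnot(length(fractions) == length(totals))
  if (length(fractions) < n_bins) {
    stop("bin_fraction_sd: fewer genes than bins")
  }
  mean_count <- totals / 2
  lims <- stats::quantile(mean_count, c(0.01, 0.99), names = FALSE)
  if (lims[1] <= 0) lims[1] <- min(mean_count[mean_count > 0])
  if (lims[2] <= lims[1]) {  # (near-)constant counts: a single bin
    n_bins <- 1L
    lims <- range(mean_count)
    if (lims[2] <= lims[1]) lims[2] <- lims[1] * (1 + 1e-9)
  }
  breaks <- 10^seq(log10(lims[1]), log10(lims[2]), length.out = n_bins + 1L)
  breaks[1] <- -Inf; breaks[length(breaks)] <- Inf
  edges <- 10^seq(log10(lims[1]), log10(lims[2]), length.out = n_bins + 1L)

  bin <- cut(mean_count, breaks = breaks, labels = FALSE, right = FALSE)
  out <- do.call(rbind, lapply(seq_len(n_bins), function(i) {
    sel <- which(bin == i)
    data.frame(bin_index = i,
               count_low = edges[i], count_high = edges[i + 1L],
               mean_total = mean(totals[sel]),
               n_genes = length(sel),
               observed_sd = if (length(sel) >= 2) stats::sd(fractions[sel]) else NA_real_)
  }))
  small <- out$n_genes < min_genes
  if (any(small)) {
    warning(sum(small), " bin(s) with fewer than ", min_genes,
            " genes dropped")
    out <- out[!small, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("bin_stats", "data.frame")
  out
}

#' Binomial-partitioning prediction of the fraction SD
#'
#' Counting statistics alone predict that a gene with `n_total` pooled
#' reads splits between replicates as Binomial(n_total, p), giving the
#' fraction an SD of `sqrt(p (1 - p) / n_total)`. `p` defaults to 0.5 and
#' should be set to `L_A / (L_A + L_B)` when library sizes differ, so
#' unequal depth is not mistaken for biological variation.
#'
#' @param mean_total Mean pooled count per gene in a bin (a + b).
#' @param p Expected replicate-A fraction.
#' @return Predicted SD of the fraction.
#' @export
predict_binomial_sd <- function(mean_total, p = 0.5) {
  stopifnot(p > 0, p < 1)
  if (any(mean_total <= 0)) stop("predict_binomial_sd: mean_total must be > 0")
  sqrt(p * (1 - p) / mean_total)
}

#' Add the binomial prediction to a bin table
#' @param bins A `bin_stats` data.frame.
#' @param p Expected replicate-A fraction (see [predict_binomial_sd()]).
#' @return `bins` with a `predicted_sd` column.
#' @export
add_predicted_sd <- function(bins, p = 0.5) {
  bins$predicted_sd <- predict_binomial_sd(bins$mean_total, p)
  bins
}

#' Select a minimum-expression threshold from binned fraction SDs
#'
#' Operationalizes "variation between biological replicates becomes stably
#' larger than predicted from counting statistics": the threshold is the
#' lower mean-count edge of the first bin from which at least `run_length`
#' consecutive bins all have `observed_sd >= excess_factor * predicted_sd`,
#' converted to RPM with the mean library size of the two replicates.
#'
#' @param bins A `bin_stats` data.frame with a `predicted_sd` column
#'   (see [add_predicted_sd()]), ordered by count.
#' @param mean_library_size Mean of the two replicates' library sizes, used
#'   for the count-to-RPM conversion.
#' @param excess_factor k: required excess of observed over predicted SD.
#' @param run_length m: number of consecutive excess bins required.
#' @return List with `found`, `threshold_rpm`, `threshold_mean_count`,
#'   `bin_index`, and the annotated `bins` table (`excess` ratio column).
#' @export
select_threshold <- function(bins, mean_library_size,
                             excess_factor = 1.2, run_length = 3L) {
  if (is.null(bins$predicted_sd)) {
    stop("select_threshold: bins must carry predicted_sd (see add_predicted_sd)")
  }
  if (nrow(bins) < run_length) {
    stop("select_threshold: fewer bins than run_length")
  }
  bins$excess <- bins$observed_sd / bins$predicted_sd
  ok <- !is.na(bins$excess) & bins$excess >= excess_factor

  start <- NA_integer_
  run <- rle(ok)
  ends <- cumsum(run$lengths)
  hit <- which(run$values & run$lengths >= run_length)
  if (length(hit) > 0) {
    start <- ends[hit[1]] - run$lengths[hit[1]] + 1L
  }
  if (is.na(start)) {
    return(list(found = FALSE, threshold_rpm = NA_real_,
                threshold_mean_count = NA_real_, bin_index = NA_integer_,
                bins = bins))
  }
  cnt <- bins$count_low[start]
  list(found = TRUE,
       threshold_rpm = cnt / mean_library_size * 1e6,
       threshold_mean_count = cnt,
       bin_index = bins$bin_index[start],
       bins = bins)
}

#' Run one simulated replicate-partitioning threshold experiment
#'
#' Draws two replicate footprint count columns for one condition from the
#' simulator's counting model, computes the per-gene replicate fraction,
#' bins it, adds the binomial prediction (with `p` from the realized
#' library sizes), and selects a threshold.
#'
#' @param config A [sim_config()]; `mouse_cv` sets the biological
#'   variance, `depth_rpf` the library sizes.
#' @param n_bins Number of log-spaced bins.
#' @return The [select_threshold()] result (bins table included).
#' @export
simulate_threshold_experiment <- function(config, n_bins = 20L) {
  ann <- simulate_annotation(config)
  ab <- simulate_abundances(config, ann, "control")
  a <- simulate_counts(ann, ab$ribo[, 1], config$depth_rpf, "rep1",
                       seed = derive_seed(config$seed, "thr_rep1"))
  b <- simulate_counts(ann, ab$ribo[, 2], config$depth_rpf, "rep2",
                       seed = derive_seed(config$seed, "thr_rep2"))
  rf <- suppressMessages(replicate_fraction(a[, 1], b[, 1]))
  bins <- suppressWarnings(
    add_predicted_sd(bin_fraction_sd(rf$fraction, rf$total, n_bins = n_bins),
                     p = sum(a) / (sum(a) + sum(b))))
  select_threshold(bins, mean(c(sum(a), sum(b))))
}

#' Genes passing an RPM threshold
#'
#' Default rule: a gene passes when its mean RPM across all provided
#' samples exceeds `threshold_rpm`. Alternatives: `"all"` (every sample
#' must exceed) and `"any"`.
#'
#' @param rpm Numeric matrix of RPM values (genes x samples).
#' @param threshold_rpm Threshold in RPM.
#' @param rule One of `"mean"`, `"all"`, `"any"`.
#' @return Character vector of passing gene ids.
#' @export
threshold_genes <- function(rpm, threshold_rpm, rule = c("mean", "all", "any")) {
  rule <- match.arg(rule)
  pass <- switch(rule,
                 mean = rowMeans(rpm) > threshold_rpm,
                 all = apply(rpm > threshold_rpm, 1, all),
                 any = apply(rpm > threshold_rpm, 1, any))
  rownames(rpm)[pass]
}
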