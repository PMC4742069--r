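#' Pearson correlation of two replicates on the log2 scale
#'
#' Reproducibility diagnostic: RPM values of the same genes in two
#' biological replicates are log2-transformed after adding a pseudocount
#' (to admit zeros) and their Pearson correlation is returned.
#'
#' @param rpm_a,rpm_b Numeric vectors of per-gene RPM for the two
#'   replicates, same gene order.
#' @param pseudocount Positive value added before log2 (default 0.5 RPM).
#' @return Pearson r on log2 values.
#' @export
replicate_correlation <- function(rpm_a, rpm_b, pseudocount = 0.5) {
  stopifnot(length(rpm_a) == length(rpm_b), pseudocount > 0)
  if (length(rpm_a) < 3) stop("replicate_correlation: need at least 3 genes")
  stats::cor(log2(rpm_a + pseudocount), log2(rpm_b + pseudocount))
}

#' Triplet periodicity of footprint 5' ends
#'
#' Each read's 5' end is assigned to a frame relative to the main coding
#' frame: `frame = five_prime_pos mod 3`, labelled `0` (in frame), `+1`,
#' `-1`. Genuine ribosome footprints phase strongly with frame 0; mRNA-Seq
#' fragments do not. Fractions are computed pooled over all reads and per
#' gene (genes with no reads are omitted from the per-gene table).
#'
#' The frame sign convention (`pos mod 3 == 1` labelled `+1`,
#' `== 2` labelled `-1`) is fixed here; the main-frame fraction itself does
#' not depend on it.
#'
#' @param reads `aligned_reads` (already length-filtered).
#' @param annotation `gene_annotation` (unused for the arithmetic but kept
#'   for interface symmetry / gene universe checks).
#' @return List with `global` (named fractions `0`, `+1`, `-1` plus
#'   `n_reads`) and `per_gene` (data.frame gene_id, fractions, n_reads).
#' @export
frame_periodicity <- function(reads, annotation = NULL) {
  if (nrow(reads) == 0) stop("frame_periodicity: no reads")
  frame <- ((reads$five_prime_pos %% 3L) + 3L) %% 3L
  lab <- c("0", "+1", "-1")[frame + 1L]
  lab <- factor(lab, levels = c("0", "+1", "-1"))

  global_counts <- table(lab)
  global <- list(fractions = as.numeric(global_counts) / nrow(reads),
                 n_reads = nrow(reads))
  names(global$fractions) <- levels(lab)

  tab <- table(reads$gene_id, lab)
  n_per_gene <- rowSums(tab)
  per_gene <- data.frame(gene_id = rownames(tab),
                         frac_0 = tab[, "0"] / n_per_gene,
                         frac_plus1 = tab[, "+1"] / n_per_gene,
                         frac_minus1 = tab[, "-1"] / n_per_gene,
                         n_reads = as.integer(n_per_gene),
                         stringsAsFactors = FALSE, row.names = NULL)
  list(global = global, per_gene = per_gene)
}

#' Metagene density profile around the start codon
#'
#' 5'-end counts are cumulated over all eligible genes at each position
#' relative to the start codon, then divided by the mean of those sums over
#' the first `norm_len` positions of the window, so the profile is a
#' self-normalized density (mean 1 over the normalization window when it
#' spans the whole window). Genes whose CDS does not span the window's
#' downstream end are excluded (their count is reported in attribute
#' `n_excluded_genes`).
#'
#' @param reads `aligned_reads`.
#' @param annotation `gene_annotation`.
#' @param window Integer pair `(from, to)` of positions relative to the
#'   start codon, inclusive; default `c(-25, 114)` = 140 positions anchored
#'   at the upstream extension.
#' @param norm_len Number of leading window positions defining the
#'   normalization mean (default 140).
#' @param per_gene_norm If `TRUE`, each gene's positional counts are
#'   divided by the gene's own mean over the window before summation, so
#'   highly expressed genes do not dominate.
#' @return A data.frame of class `metagene_profile` with columns `position`
#'   and `density`.
#' @export
metagene_profile <- function(reads, annotation, window = c(-25L, 114L),
                             norm_len = 140L, per_gene_norm = FALSE) {
  window <- as.integer(window)
  positions <- seq(window[1], window[2])
  norm_len <- min(as.integer(norm_len), length(positions))

  eligible <- annotation$cds_length >= window[2] + 1L &
    annotation$upstream_extension >= -window[1]
  n_excluded <- sum(!eligible)
  if (!any(eligible)) {
    stop("metagene_profile: no gene spans the window ",
         window[1], "..", window[2])
  }
  if (n_excluded > 0) {
    message(n_excluded, " gene(s) shorter than the metagene window excluded")
  }
  keep_genes <- annotation$gene_id[eligible]
  r <- reads[reads$gene_id %in% keep_genes &
               reads$five_prime_pos >= window[1] &
               reads$five_prime_pos <= window[2], , drop = FALSE]

  if (per_gene_norm) {
    tab <- table(factor(r$gene_id, levels = keep_genes),
                 factor(r$five_prime_pos, levels = positions))
    gene_mean <- rowMeans(tab)
    nz <- gene_mean > 0
    sums <- colSums(tab[nz, , drop = FALSE] / gene_mean[nz])
  } else {
    sums <- as.numeric(table(factor(r$five_prime_pos, levels = positions)))
  }
  norm <- mean(sums[seq_len(norm_len)])
  if (norm == 0) stop("metagene_profile: no reads in the normalization window")
  out <- data.frame(position = positions, density = sums / norm)
  class(out) <- c("metagene_profile", "data.frame")
  attr(out, "n_excluded_genes") <- n_excluded
  out
}

#' Call a start-codon ribosome dwell peak
#'
#' The profile's maximum is called a peak when it is at least `min_fold`
#' times the median density; otherwise "no peak". Codon position is the
#' floor division of the nt position by 3 (toward -Inf), so -12 nt is
#' -4 codons.
#'
#' @param profile A `metagene_profile`.
#' @param min_fold Peak threshold as fold over the median density.
#' @return List with `found` (logical), `peak_nt`, `peak_codon` (both `NA`
#'   when no peak), `max_density`, `median_density`.
#' @export
find_start_peak <- function(profile, min_fold = 3) {
  stopifnot(nrow(profile) > 0)
  i <- which.max(profile$density)
  med <- stats::median(profile$density)
  found <- profile$density[i] >= min_fold * med && profile$density[i] > 0
  pos <- if (found) profile$position[i] else NA_integer_
  list(found = found,
       peak_nt = pos,
       peak_codon = if (found) as.integer(floor(pos / 3)) else NA_integer_,
       max_density = profile$density[i],
       median_density = med)
}
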