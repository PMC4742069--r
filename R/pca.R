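#' PCA of expression profiles
#'
#' Principal component analysis of samples over thresholded genes:
#' `log2(RPM + 0.5)` per gene, mean-centered per gene, decomposed by SVD
#' (via [stats::prcomp()] without rescaling). Component signs are fixed so
#' the loading of the alphabetically first gene is non-negative, making
#' scores reproducible across platforms.
#'
#' @param rpm Numeric RPM matrix (genes x samples).
#' @param gene_set Gene ids to include (from the expression threshold).
#' @param n_components Number of components to return.
#' @param pseudocount Added before log2.
#' @return List of class `pca_scores`: `scores` (samples x components),
#'   `loadings` (genes x components), `var_explained` (fractions).
#' @export
pca_profiles <- function(rpm, gene_set, n_components = 3L, pseudocount = 0.5) {
  stopifnot(all(gene_set %in% rownames(rpm)))
  if (ncol(rpm) < 3) stop("pca_profiles: need at least 3 samples")
  if (ncol(rpm) < n_components) {
    stop("pca_profiles: fewer samples than requested components")
  }
  gene_set <- sort(gene_set)
  x <- t(log2(rpm[gene_set, , drop = FALSE] + pseudocount))  # samples x genes
  x <- scale(x, center = TRUE, scale = FALSE)

  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]

  # sign convention: first (alphabetical) gene's loading non-negative
  flip <- ifelse(loadings[1, ] < 0, -1, 1)
  scores <- sweep(scores, 2, flip, "*")
  loadings <- sweep(loadings, 2, flip, "*")

  out <- list(scores = scores, loadings = loadings,
              var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
  class(out) <- "pca_scores"
  out
}
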