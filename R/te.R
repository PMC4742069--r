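#' Translational efficiency per gene and condition
#'
#' TE is the ratio of normalized footprint abundance to normalized mRNA
#' abundance: replicate RPM columns are averaged within each condition
#' first, then `te = mean RPF RPM / mean mRNA RPM`. Genes with zero mRNA
#' RPM in either condition are excluded (count via message). The log ratio
#' `log(te_exercise / te_control)` (natural log) quantifies the
#' translational shift.
#'
#' @param rpf_rpm,mrna_rpm RPM matrices (genes x samples) from
#'   [rpm_normalize()], same gene order.
#' @param conditions Named character vector mapping each column name of the
#'   matrices to `"control"` or `"exercise"`.
#' @param gene_set Gene ids (from the expression threshold) to include.
#' @param per_replicate If `TRUE`, TE is computed per replicate and then
#'   averaged per condition, instead of averaging RPM first.
#' @return A data.frame of class `te_result` with columns `gene_id`,
#'   `te_control`, `te_exercise`, `log_ratio`.
#' @export
translational_efficiency <- function(rpf_rpm, mrna_rpm, conditions, gene_set,
                                     per_replicate = FALSE) {
  if (length(gene_set) == 0) stop("translational_efficiency: empty gene set")
  stopifnot(all(gene_set %in% rownames(rpf_rpm)),
            all(gene_set %in% rownames(mrna_rpm)))
  cond_of <- function(m) conditions[colnames(m)]
  if (anyNA(cond_of(rpf_rpm)) || anyNA(cond_of(mrna_rpm))) {
    stop("translational_efficiency: every column needs a condition label")
  }

  te_for <- function(cond) {
    rp <- rpf_rpm[gene_set, cond_of(rpf_rpm) == cond, drop = FALSE]
    mr <- mrna_rpm[gene_set, cond_of(mrna_rpm) == cond, drop = FALSE]
    if (per_replicate) {
      stopifnot(ncol(rp) == ncol(mr))
      rowMeans(rp / mr)
    } else {
      rowMeans(rp) / rowMeans(mr)
    }
  }
  te_c <- te_for("control")
  te_e <- te_for("exercise")

  ok <- is.finite(te_c) & is.finite(te_e) & te_c > 0 & te_e > 0
  if (any(!ok)) {
    message(sum(!ok), " gene(s) with zero mRNA or footprint signal excluded ",
            "from TE analysis")
  }
  out <- data.frame(gene_id = gene_set[ok],
                    te_control = te_c[ok], te_exercise = te_e[ok],
                    log_ratio = log(te_e[ok] / te_c[ok]),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("te_result", "data.frame")
  out
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum over all observed points of the absolute difference
#' between the two right-continuous empirical CDFs; the p-value comes from
#' the asymptotic Kolmogorov distribution evaluated at
#' `sqrt(n1 n2 / (n1 + n2)) * D`. Ties are handled by evaluating both ECDFs
#' at the pooled sorted values. Exact small-sample p-values are not
#' computed; at the group sizes this test is used for (tens to hundreds)
#' the asymptotic form is adequate.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return List of class `ks_result`: `D`, `p_value`, `n1`, `n2`.
#' @export
ks_two_sample <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("ks_two_sample: need at least 2 values per sample")

  pts <- sort(unique(c(x, y)))
  sx <- sort(x); sy <- sort(y)
  ecdf1 <- findInterval(pts, sx) / n1
  ecdf2 <- findInterval(pts, sy) / n2
  D <- max(abs(ecdf1 - ecdf2))

  lambda <- sqrt(n1 * n2 / (n1 + n2)) * D
  out <- list(D = D, p_value = kolmogorov_sf(lambda), n1 = n1, n2 = n2)
  class(out) <- "ks_result"
  out
}

# Survival function of the Kolmogorov distribution,
# Q(lambda) = 2 * sum_{k>=1} (-1)^{k-1} exp(-2 k^2 lambda^2), clamped to
# (0, 1]; the alternating series is truncated when terms fall below 1e-12.
kolmogorov_sf <- function(lambda) {
  if (lambda <= 0) return(1)
  s <- 0
  for (k in 1:100) {
    term <- (-1)^(k - 1) * exp(-2 * k^2 * lambda^2)
    s <- s + term
    if (abs(term) < 1e-12) break
  }
  min(max(2 * s, 0), 1)
}

#' Run one simulated TE-shift experiment at the count level
#'
#' Generates annotation and per-replicate abundances for both conditions,
#' draws count tables for every sample via the multinomial counting model
#' (no read positions, so deep libraries stay cheap), computes RPM and TE
#' over all genes, and applies the TOP shift test. One call is one fully
#' seeded in-silico experiment; vary `config$seed` to replicate it.
#'
#' @param config A [sim_config()]; `depth_rpf` / `depth_mrna` set the
#'   library sizes.
#' @return List: `te` (a `te_result`), `shift` (from [top_shift_test()]),
#'   `annotation`.
#' @export
simulate_te_experiment <- function(config) {
  ann <- simulate_annotation(config)
  ab <- list(control = simulate_abundances(config, ann, "control"),
             exercise = simulate_abundances(config, ann, "exercise"))
  tabs <- list(); conditions <- character()
  for (cond in c("control", "exercise")) {
    for (r in seq_len(config$n_replicates)) {
      for (assay in c("rpf", "mrna")) {
        sid <- paste(assay, cond, r, sep = "_")
        abv <- if (assay == "rpf") ab[[cond]]$ribo[, r] else ab[[cond]]$rna[, r]
        depth <- if (assay == "rpf") config$depth_rpf else config$depth_mrna
        tabs[[sid]] <- simulate_counts(ann, abv, depth, sid,
                                       seed = derive_seed(config$seed, sid))
        conditions[sid] <- cond
      }
    }
  }
  counts <- do.call(cbind_counts, tabs)
  rpm <- rpm_normalize(counts)
  is_rpf <- startsWith(colnames(rpm), "rpf_")
  te <- suppressMessages(
    translational_efficiency(rpm[, is_rpf, drop = FALSE],
                             rpm[, !is_rpf, drop = FALSE],
                             conditions, ann$gene_id))
  list(te = te, shift = top_shift_test(te, ann), annotation = ann,
       rpm = rpm, conditions = conditions)
}

#' TOP vs non-TOP translational-efficiency shift test
#'
#' Compares the distributions of log TE ratios (exercise / control) between
#' TOP-motif genes and all other genes with the two-sample
#' Kolmogorov-Smirnov test, and reports both group medians so the direction
#' of the shift (TOP translationally suppressed when mTOR signaling falls)
#' is explicit.
#'
#' @param te A `te_result` data.frame.
#' @param annotation `gene_annotation` providing `is_top`.
#' @return List: `ks` (a `ks_result`), `median_top`, `median_other`,
#'   `top_suppressed` (logical: TOP median below non-TOP median),
#'   `n_top`, `n_other`.
#' @export
top_shift_test <- function(te, annotation) {
  is_top <- annotation$is_top[match(te$gene_id, annotation$gene_id)]
  if (anyNA(is_top)) stop("top_shift_test: TE genes missing from annotation")
  v_top <- te$log_ratio[is_top]
  v_other <- te$log_ratio[!is_top]
  if (length(v_top) < 2 || length(v_other) < 2) {
    stop("top_shift_test: each group needs at least 2 genes")
  }
  ks <- ks_two_sample(v_top, v_other)
  m_top <- stats::median(v_top)
  m_other <- stats::median(v_other)
  list(ks = ks, median_top = m_top, median_other = m_other,
       top_suppressed = m_top < m_other,
       n_top = length(v_top), n_other = length(v_other))
}
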