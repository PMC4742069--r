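#' Simulation configuration for paired Ribo-seq / mRNA-Seq experiments
#'
#' Bundles every knob of the synthetic footprint generator. The generator
#' emulates the design of a two-condition mouse experiment: 2 biological
#' replicates per condition, each replicate a pool of 3 mice; ~30-nt
#' ribosome-protected fragments whose 5' ends phase with the reading frame
#' (frame-0 probability `frame0_bias`) and pile up at a start-codon dwell
#' peak whose 5' ends sit `peak_offset_nt` upstream of the start codon
#' (default -12 nt = 4 codons, i.e. P-site at the AUG with a 12-nt 5'
#' flank); mRNA-Seq fragments are uniform with no phasing and no peak.
#'
#' Counting noise is multinomial across genes at fixed depth, so library
#' sizes are exact and replicate disagreement at low counts follows binomial
#' partitioning. Biological noise is lognormal per mouse with coefficient of
#' variation `mouse_cv`; a replicate is the arithmetic mean of its mice, so
#' the replicate-level variance scales as `mouse_cv^2 / n_mice_per_replicate`.
#'
#' @param seed Integer root seed; fixes every stochastic draw.
#' @param n_genes Number of genes.
#' @param cds_length_range CDS length range in nt (rounded to codon
#'   multiples).
#' @param top_fraction Fraction of genes flagged as TOP-motif genes.
#' @param footprint_length_dist Named probability vector over footprint
#'   lengths 26..34 nt (mode 30).
#' @param frame0_bias Probability q that a body 5' end falls on frame 0;
#'   the remaining mass splits evenly over the other two frames. Must lie in
#'   (1/3, 1].
#' @param start_peak_fold Weight of the start-codon point mass relative to a
#'   single uniform body position (>= 1; 1 = no enrichment).
#' @param peak_offset_nt 5'-end position of the start-codon peak.
#' @param depth_rpf,depth_mrna Reads per sample.
#' @param n_mice_per_replicate,n_replicates Pooling design.
#' @param mouse_cv Lognormal inter-mouse coefficient of variation.
#' @param effects `NULL`, or a data.frame `gene_id, transcription_fold,
#'   translation_fold` giving per-gene exercise effects (genes not listed
#'   keep fold 1). The default plants one exemplar gene with a 4-fold
#'   transcriptional and an additional 4.5-fold translational induction
#'   (18-fold ribosome loading), the translation-dominant pattern the
#'   analysis is designed to resolve.
#' @param top_te_fold Multiplier (< 1 suppresses) on TOP genes' ribosome
#'   loading under exercise, emulating mTOR-dependent translational
#'   repression of TOP mRNAs.
#' @param upstream_extension nt of reference upstream of the start codon.
#' @param base_sdlog sdlog of the lognormal base-expression distribution.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 1010L,
                       cds_length_range = c(300L, 2400L),
                       top_fraction = 59 / 1010,
                       footprint_length_dist = default_footprint_dist(),
                       frame0_bias = 0.8,
                       start_peak_fold = 20,
                       peak_offset_nt = -12L,
                       depth_rpf = 2e5,
                       depth_mrna = 2e5,
                       n_mice_per_replicate = 3L,
                       n_replicates = 2L,
                       mouse_cv = 0.1,
                       effects = NULL,
                       top_te_fold = 0.7,
                       upstream_extension = 25L,
                       base_sdlog = 1) {
  stopifnot(frame0_bias > 1 / 3, frame0_bias <= 1,
            start_peak_fold >= 1,
            depth_rpf >= 0, depth_mrna >= 0,
            top_fraction >= 0, top_fraction <= 1,
            mouse_cv >= 0, top_te_fold > 0,
            abs(sum(footprint_length_dist) - 1) < 1e-9)
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              cds_length_range = as.integer(cds_length_range),
              top_fraction = top_fraction,
              footprint_length_dist = footprint_length_dist,
              frame0_bias = frame0_bias, start_peak_fold = start_peak_fold,
              peak_offset_nt = as.integer(peak_offset_nt),
              depth_rpf = depth_rpf, depth_mrna = depth_mrna,
              n_mice_per_replicate = as.integer(n_mice_per_replicate),
              n_replicates = as.integer(n_replicates),
              mouse_cv = mouse_cv, effects = effects,
              top_te_fold = top_te_fold,
              upstream_extension = as.integer(upstream_extension),
              base_sdlog = base_sdlog)
  class(cfg) <- "sim_config"
  cfg
}

#' Default footprint length distribution (26..34 nt, mode 30)
#' @return Named probability vector.
#' @export
default_footprint_dist <- function() {
  w <- c(1, 2, 5, 10, 20, 10, 5, 2, 1)
  names(w) <- as.character(26:34)
  w / sum(w)
}

# Deterministic per-stage seed derivation from the root seed; keeps all
# derived seeds inside 32-bit integer range.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

#' Simulate a gene annotation
#'
#' CDS lengths are drawn uniformly in `cds_length_range` and rounded down to
#' codon multiples; `round(top_fraction * n_genes)` genes are flagged TOP.
#'
#' @param config A [sim_config()].
#' @return A `gene_annotation` data.frame.
#' @export
simulate_annotation <- function(config) {
  set.seed(derive_seed(config$seed, "annotation"))
  n <- config$n_genes
  len <- sample(seq(config$cds_length_range[1], config$cds_length_range[2]),
                n, replace = TRUE)
  len <- (len %/% 3L) * 3L
  n_top <- round(config$top_fraction * n)
  is_top <- rep(FALSE, n)
  if (n_top > 0) is_top[sample.int(n, n_top)] <- TRUE
  as_gene_annotation(data.frame(
    gene_id = sprintf("g%04d", seq_len(n)),
    cds_length = len,
    upstream_extension = config$upstream_extension,
    is_top = is_top,
    stringsAsFactors = FALSE))
}

# Per-gene exercise effect folds aligned to the annotation. The default
# plants one exemplar translation-dominant gene (first non-TOP gene):
# transcription x4, translation x4.5 on top of that.
effect_folds <- function(config, annotation) {
  n <- nrow(annotation)
  tf <- rep(1, n)
  trf <- rep(1, n)
  eff <- config$effects
  if (is.null(eff)) {
    ex <- which(!annotation$is_top)[1]
    eff <- data.frame(gene_id = annotation$gene_id[ex],
                      transcription_fold = 4, translation_fold = 4.5)
  }
  idx <- match(eff$gene_id, annotation$gene_id)
  if (anyNA(idx)) stop("effects reference gene ids absent from annotation")
  tf[idx] <- eff$transcription_fold
  trf[idx] <- eff$translation_fold
  list(transcription = tf, translation = trf)
}

#' Simulate expected per-replicate abundances
#'
#' Per mouse, each gene's abundance is its base expression times a lognormal
#' factor with CV `mouse_cv`; a replicate pools `n_mice_per_replicate` mice
#' by arithmetic mean. Under the exercise condition, RNA abundance is
#' multiplied by the gene's `transcription_fold` and ribosome loading
#' additionally by `translation_fold`; TOP genes' ribosome loading is
#' further multiplied by `top_te_fold`.
#'
#' @param config A [sim_config()].
#' @param annotation Annotation from [simulate_annotation()].
#' @param condition `"control"` or `"exercise"`.
#' @return List with matrices `rna` and `ribo` (genes x replicates) of
#'   expected relative abundances, plus the condition label.
#' @export
simulate_abundances <- function(config, annotation, condition = "control") {
  condition <- match.arg(condition, c("control", "exercise"))
  n <- nrow(annotation)

  # Base expression is drawn once per gene, shared by both conditions.
  set.seed(derive_seed(config$seed, "base_expression"))
  base <- stats::rlnorm(n, meanlog = log(100), sdlog = config$base_sdlog)

  folds <- effect_folds(config, annotation)
  rna_base <- base
  ribo_base <- base
  if (condition == "exercise") {
    rna_base <- rna_base * folds$transcription
    ribo_base <- ribo_base * folds$transcription * folds$translation
    ribo_base[annotation$is_top] <- ribo_base[annotation$is_top] *
      config$top_te_fold
  }

  # Lognormal with mean 1 and CV = mouse_cv.
  sdlog <- sqrt(log(1 + config$mouse_cv^2))
  meanlog <- -sdlog^2 / 2
  mouse_factor <- function(tag) {
    set.seed(derive_seed(config$seed, tag))
    if (config$mouse_cv == 0) return(rep(1, n))
    m <- matrix(stats::rlnorm(n * config$n_mice_per_replicate, meanlog, sdlog),
                nrow = n)
    rowMeans(m)
  }

  reps <- seq_len(config$n_replicates)
  rna <- sapply(reps, function(r)
    rna_base * mouse_factor(paste0("rna_", condition, "_rep", r)))
  ribo <- sapply(reps, function(r)
    ribo_base * mouse_factor(paste0("ribo_", condition, "_rep", r)))
  dimnames(rna) <- dimnames(ribo) <-
    list(annotation$gene_id, paste0(condition, "_rep", reps))
  list(rna = rna, ribo = ribo, condition = condition)
}

# Multinomial gene totals at fixed depth, proportional to abundance.
multinomial_gene_counts <- function(abundance, depth) {
  stopifnot(all(abundance >= 0), any(abundance > 0))
  as.integer(stats::rmultinom(1, size = depth, prob = abundance))
}

#' Simulate gene-level counts without read positions
#'
#' Counts-only shortcut sharing the read generator's across-gene model: a
#' single multinomial of size `depth` with probabilities proportional to
#' `abundance`. Used where only count tables matter (thresholding,
#' translational efficiency) so deep libraries stay cheap.
#'
#' @param annotation `gene_annotation` (gene order of the result).
#' @param abundance Per-gene expected abundance (one replicate's column).
#' @param depth Library size.
#' @param sample_id Column name.
#' @param seed Integer seed.
#' @return A one-column `count_table`.
#' @export
simulate_counts <- function(annotation, abundance, depth, sample_id, seed) {
  set.seed(seed)
  m <- matrix(multinomial_gene_counts(abundance, depth), ncol = 1,
              dimnames = list(annotation$gene_id, sample_id))
  as_count_table(m)
}

#' Simulate ribosome-protected-fragment reads for one sample
#'
#' Gene totals are multinomial at `depth_rpf` proportional to ribosome
#' loading. Within a gene, body 5' ends fall on frame 0 with probability
#' `frame0_bias` and on each other frame with probability `(1 - q)/2`,
#' uniformly across codon starts; an additional point mass at
#' `peak_offset_nt` carries `start_peak_fold` times the weight of one
#' uniform body position. Lengths are drawn from `footprint_length_dist`.
#' Body positions are restricted to `0 .. cds_length - 34` so every drawn
#' length fits inside the CDS.
#'
#' @param config A [sim_config()].
#' @param annotation `gene_annotation`.
#' @param abundance Per-gene expected ribosome loading (one replicate).
#' @param sample_id Sample label (also salts the derived seed).
#' @param seed Integer seed; defaults to a value derived from
#'   `config$seed` and `sample_id`.
#' @return An `aligned_reads` data.frame with exactly `depth_rpf` rows.
#' @export
simulate_rpf_reads <- function(config, annotation, abundance, sample_id,
                               seed = derive_seed(config$seed,
                                                  paste0("rpf_", sample_id))) {
  set.seed(seed)
  max_len <- max(as.integer(names(config$footprint_length_dist)))
  if (any(annotation$cds_length < max_len + 3L)) {
    stop("simulate_rpf_reads: all CDS must be at least ", max_len + 3L, " nt")
  }
  counts <- multinomial_gene_counts(abundance, config$depth_rpf)
  total <- sum(counts)
  gene_idx <- rep.int(seq_len(nrow(annotation)), counts)

  cds <- annotation$cds_length[gene_idx]
  n_body <- cds - max_len + 1L                      # uniform body positions
  p_peak <- config$start_peak_fold / (n_body + config$start_peak_fold)
  at_peak <- stats::runif(total) < p_peak

  q <- config$frame0_bias
  frame <- sample(c(0L, 1L, 2L), total, replace = TRUE,
                  prob = c(q, (1 - q) / 2, (1 - q) / 2))
  n_slots <- (cds - max_len - frame) %/% 3L + 1L    # codon starts per frame
  pos <- frame + 3L * as.integer(floor(stats::runif(total) * n_slots))
  pos[at_peak] <- config$peak_offset_nt

  len <- sample(as.integer(names(config$footprint_length_dist)), total,
                replace = TRUE, prob = config$footprint_length_dist)
  out <- data.frame(gene_id = annotation$gene_id[gene_idx],
                    five_prime_pos = pos, length = len,
                    stringsAsFactors = FALSE)
  class(out) <- c("aligned_reads", "data.frame")
  out
}

#' Simulate mRNA-Seq fragment reads for one sample
#'
#' Positions are uniform over the extended reference
#' (`-upstream_extension .. cds_length - 34`) with no frame bias and no
#' start-codon peak; gene totals are multinomial at `depth_mrna`
#' proportional to RNA abundance.
#'
#' @inheritParams simulate_rpf_reads
#' @param abundance Per-gene expected RNA abundance (one replicate).
#' @return An `aligned_reads` data.frame.
#' @export
simulate_mrna_reads <- function(config, annotation, abundance, sample_id,
                                seed = derive_seed(config$seed,
                                                   paste0("mrna_", sample_id))) {
  set.seed(seed)
  if (config$depth_mrna == 0) {
    out <- data.frame(gene_id = character(), five_prime_pos = integer(),
                      length = integer(), stringsAsFactors = FALSE)
    class(out) <- c("aligned_reads", "data.frame")
    return(out)
  }
  max_len <- max(as.integer(names(config$footprint_length_dist)))
  counts <- multinomial_gene_counts(abundance, config$depth_mrna)
  total <- sum(counts)
  gene_idx <- rep.int(seq_len(nrow(annotation)), counts)

  lo <- -annotation$upstream_extension[gene_idx]
  hi <- annotation$cds_length[gene_idx] - max_len
  pos <- lo + as.integer(floor(stats::runif(total) * (hi - lo + 1L)))
  len <- sample(as.integer(names(config$footprint_length_dist)), total,
                replace = TRUE, prob = config$footprint_length_dist)
  out <- data.frame(gene_id = annotation$gene_id[gene_idx],
                    five_prime_pos = pos, length = len,
                    stringsAsFactors = FALSE)
  class(out) <- c("aligned_reads", "data.frame")
  out
}
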