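rpm_mat <- function(values, samples, genes = paste0("g", seq_len(nrow(values)))) {
  dimnames(values) <- list(genes, samples)
  values
}

test_that("translational efficiency is the ratio of condition-mean RPMs", {
  conds <- c(rc = "control", re = "exercise")
  rpf <- rpm_mat(matrix(c(200, 100, 400, 100), nrow = 2), c("rc", "re"))
  mrna <- rpm_mat(matrix(c(100, 100, 100, 100), nrow = 2), c("rc", "re"))
  te <- translational_efficiency(rpf, mrna, conds, c("g1", "g2"))
  expect_equal(te$te_control, c(2, 1))
  expect_equal(te$te_exercise, c(4, 1))
  expect_equal(te$log_ratio, c(log(2), 0))

  # identical tables: all TE 1, all log ratios 0
  te1 <- translational_efficiency(mrna, mrna, conds, c("g1", "g2"))
  expect_equal(te1$te_control, c(1, 1))
  expect_equal(te1$log_ratio, c(0, 0))

  expect_error(translational_efficiency(rpf, mrna, conds, character()),
               "empty gene set")
})

test_that("TE excludes zero-mRNA genes and is invariant to library scaling", {
  ann <- toy_annotation()
  conds <- c(a1 = "control", a2 = "control", b1 = "exercise", b2 = "exercise")
  set.seed(5)
  counts <- matrix(rpois(12, 100) + 1L, nrow = 3,
                   dimnames = list(ann$gene_id, names(conds)))
  rpf <- as_count_table(counts)
  mrna <- as_count_table(counts[, c(2, 1, 4, 3)][, names(conds)] + 5L)
  te0 <- translational_efficiency(rpm_normalize(rpf), rpm_normalize(mrna),
                                  conds, ann$gene_id)
  # multiply all counts of one sample by 7: RPM normalization cancels it
  scaled <- counts; scaled[, 1] <- scaled[, 1] * 7L
  te_s <- translational_efficiency(rpm_normalize(as_count_table(scaled)),
                                   rpm_normalize(mrna), conds, ann$gene_id)
  expect_equal(te_s$log_ratio, te0$log_ratio, tolerance = 1e-12)

  mz <- counts; mz[1, ] <- 0L
  expect_message(
    tz <- translational_efficiency(rpm_normalize(rpf),
                                   rpm_normalize(as_count_table(mz)),
                                   conds, ann$gene_id),
    "excluded")
  expect_false("g1" %in% tz$gene_id)
})

test_that("KS statistic handles degenerate, disjoint, and tied samples", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  expect_equal(same$p_value, 1)

  disj <- ks_two_sample(c(0, 0, 0), c(1, 1, 1))
  expect_equal(disj$D, 1)

  const <- ks_two_sample(c(2, 2), c(2, 2))
  expect_equal(const$D, 0)
  expect_equal(const$p_value, 1)

  # symmetry
  set.seed(1)
  x <- rnorm(8); y <- rnorm(13, 0.5)
  expect_equal(ks_two_sample(x, y)$D, ks_two_sample(y, x)$D)
  expect_true(ks_two_sample(x, y)$D >= 0 && ks_two_sample(x, y)$D <= 1)
})

test_that("KS D matches an exhaustive ECDF max-gap scan and ks.test", {
  brute_D <- function(x, y) {
    pts <- c(x, y)
    max(vapply(pts, function(t) abs(mean(x <= t) - mean(y <= t)), 0))
  }
  set.seed(404)
  for (i in 1:50) {
    n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
    x <- round(rnorm(n1), sample(0:2, 1))  # rounding induces ties
    y <- round(rnorm(n2, 0.3), sample(0:2, 1))
    res <- ks_two_sample(x, y)
    expect_equal(res$D, brute_D(x, y), tolerance = 1e-12)
  }
  # asymptotic p agrees with the reference implementation on larger samples
  x <- rnorm(80); y <- rnorm(120, 0.2)
  ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  res <- ks_two_sample(x, y)
  expect_equal(res$D, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("TOP shift test reports direction and validates groups", {
  ann <- as_gene_annotation(data.frame(
    gene_id = paste0("g", 1:40), cds_length = 300L,
    upstream_extension = 25L, is_top = rep(c(TRUE, FALSE), each = 20)))
  set.seed(8)
  te <- data.frame(gene_id = ann$gene_id,
                   te_control = 1, te_exercise = 1,
                   log_ratio = c(rnorm(20, -1), rnorm(20, 0)),
                   stringsAsFactors = FALSE)
  res <- top_shift_test(te, ann)
  expect_lt(res$ks$p_value, 0.01)
  expect_true(res$top_suppressed)
  expect_equal(res$n_top, 20L)

  all_false <- ann; all_false$is_top <- FALSE
  expect_error(top_shift_test(te, all_false), "at least 2 genes")
})

test_that("planted TOP suppression is detected through the simulated count chain", {
  cfg <- sim_config(seed = 14, n_genes = 300, top_fraction = 0.2,
                    top_te_fold = 0.5, depth_rpf = 5e5, depth_mrna = 5e5,
                    effects = data.frame(gene_id = character(),
                                         transcription_fold = numeric(),
                                         translation_fold = numeric()))
  ann <- simulate_annotation(cfg)
  ab_c <- simulate_abundances(cfg, ann, "control")
  ab_e <- simulate_abundances(cfg, ann, "exercise")
  tabs <- list()
  for (r in 1:2) {
    tabs[[paste0("rpf_c", r)]] <- simulate_counts(ann, ab_c$ribo[, r], cfg$depth_rpf,
                                                  paste0("rpf_c", r), 10 + r)
    tabs[[paste0("rpf_e", r)]] <- simulate_counts(ann, ab_e$ribo[, r], cfg$depth_rpf,
                                                  paste0("rpf_e", r), 20 + r)
    tabs[[paste0("mrna_c", r)]] <- simulate_counts(ann, ab_c$rna[, r], cfg$depth_mrna,
                                                   paste0("mrna_c", r), 30 + r)
    tabs[[paste0("mrna_e", r)]] <- simulate_counts(ann, ab_e$rna[, r], cfg$depth_mrna,
                                                   paste0("mrna_e", r), 40 + r)
  }
  cond <- c(rpf_c1 = "control", rpf_c2 = "control",
            rpf_e1 = "exercise", rpf_e2 = "exercise",
            mrna_c1 = "control", mrna_c2 = "control",
            mrna_e1 = "exercise", mrna_e2 = "exercise")
  rpf <- rpm_normalize(do.call(cbind_counts,
                               tabs[c("rpf_c1", "rpf_c2", "rpf_e1", "rpf_e2")]))
  mrna <- rpm_normalize(do.call(cbind_counts,
                                tabs[c("mrna_c1", "mrna_c2", "mrna_e1", "mrna_e2")]))
  te <- suppressMessages(
    translational_efficiency(rpf, mrna, cond, ann$gene_id))
  res <- top_shift_test(te, ann)
  expect_lt(res$ks$p_value, 0.01)
  expect_true(res$top_suppressed)
  # planted 2-fold TE suppression recovered on the median log scale
  expect_equal(res$median_top - res$median_other, log(0.5), tolerance = 0.15)
})

test_that("PCA scores are reproducible, sign-fixed, and match an eigen oracle", {
  set.seed(12)
  rpm <- matrix(rlnorm(40, log(100), 1), nrow = 10,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  genes <- rownames(rpm)
  pc <- pca_profiles(rpm, genes, n_components = 3)
  expect_true(sum(pc$var_explained) <= 1 + 1e-9)

  # oracle: eigendecomposition of the sample covariance of the log matrix
  x <- t(log2(rpm[sort(genes), ] + 0.5))
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(xc) / (nrow(xc) - 1))
  scores_oracle <- xc %*% ev$vectors[, 1:3]
  for (j in 1:3) {
    s <- if (ev$vectors[1, j] < 0) -1 else 1  # same sign rule
    expect_equal(unname(pc$scores[, j]), unname(s * scores_oracle[, j]),
                 tolerance = 1e-8)
  }

  # gene order must not matter
  pc_shuffled <- pca_profiles(rpm[sample(10), ], genes)
  expect_equal(pc_shuffled$scores, pc$scores, tolerance = 1e-9)

  # identical samples collapse to identical scores
  rpm_dup <- cbind(rpm[, c(1, 1)], rpm[, 3:4])
  colnames(rpm_dup) <- paste0("s", 1:4)
  pc_dup <- pca_profiles(rpm_dup, genes, n_components = 2)
  expect_equal(pc_dup$scores[1, ], pc_dup$scores[2, ], tolerance = 1e-9)

  expect_error(pca_profiles(rpm[, 1:2], genes), "at least 3 samples")
  expect_error(pca_profiles(rpm, genes, n_components = 5), "fewer samples")
})
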