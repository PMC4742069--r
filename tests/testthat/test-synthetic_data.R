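small_cfg <- function(...) {
  sim_config(seed = 11, n_genes = 50, depth_rpf = 2e4, depth_mrna = 2e4,
             cds_length_range = c(300L, 900L), ...)
}

test_that("simulated annotation is seeded, codon-rounded, and honors top_fraction", {
  cfg <- sim_config(seed = 5, n_genes = 10, top_fraction = 0.2)
  ann1 <- simulate_annotation(cfg)
  ann2 <- simulate_annotation(cfg)
  expect_identical(ann1, ann2)
  expect_equal(sum(ann1$is_top), 2L)
  expect_true(all(ann1$cds_length %% 3 == 0))
  expect_true(all(ann1$cds_length >= 297 & ann1$cds_length <= 2400))

  none <- simulate_annotation(sim_config(seed = 5, n_genes = 10,
                                         top_fraction = 0))
  expect_equal(sum(none$is_top), 0L)
})

test_that("abundances: zero mouse CV is exact and injected folds compose multiplicatively", {
  cfg <- small_cfg(mouse_cv = 0, effects = data.frame(
    gene_id = "g0002", transcription_fold = 4, translation_fold = 4.5),
    top_te_fold = 1)
  ann <- simulate_annotation(cfg)
  ctrl <- simulate_abundances(cfg, ann, "control")
  ex <- simulate_abundances(cfg, ann, "exercise")

  # cv = 0: replicates equal each other and the base exactly
  expect_equal(ctrl$rna[, 1], ctrl$rna[, 2])
  expect_equal(ctrl$rna[, 1], ctrl$ribo[, 1])

  ratio_rna <- ex$rna[, 1] / ctrl$rna[, 1]
  ratio_ribo <- ex$ribo[, 1] / ctrl$ribo[, 1]
  expect_equal(unname(ratio_rna["g0002"]), 4)
  expect_equal(unname(ratio_ribo["g0002"]), 18)  # 4 x 4.5
  expect_equal(unname(ratio_ribo[names(ratio_ribo) != "g0002"]),
               rep(1, nrow(ann) - 1))

  # top_te_fold = 1: TOP genes behave as non-TOP under exercise
  expect_true(all(abs(ratio_ribo[ann$is_top] - 1) < 1e-12))
})

test_that("TOP suppression multiplies ribosome loading under exercise only", {
  cfg <- small_cfg(mouse_cv = 0, top_te_fold = 0.5, top_fraction = 0.2,
                   effects = data.frame(gene_id = character(),
                                        transcription_fold = numeric(),
                                        translation_fold = numeric()))
  ann <- simulate_annotation(cfg)
  ctrl <- simulate_abundances(cfg, ann, "control")
  ex <- simulate_abundances(cfg, ann, "exercise")
  ratio <- ex$ribo[, 1] / ctrl$ribo[, 1]
  expect_equal(unname(ratio[ann$is_top]), rep(0.5, sum(ann$is_top)))
  expect_equal(unname(ratio[!ann$is_top]), rep(1, sum(!ann$is_top)))
  expect_equal(ex$rna[, 1], ctrl$rna[, 1])  # RNA untouched
})

test_that("read simulators conserve depth, stay in bounds, and are seed-deterministic", {
  cfg <- small_cfg()
  ann <- simulate_annotation(cfg)
  ab <- simulate_abundances(cfg, ann, "control")
  rpf <- simulate_rpf_reads(cfg, ann, ab$ribo[, 1], "control_rep1")
  mrna <- simulate_mrna_reads(cfg, ann, ab$rna[, 1], "control_rep1")

  expect_equal(nrow(rpf), as.integer(cfg$depth_rpf))
  expect_equal(nrow(mrna), as.integer(cfg$depth_mrna))
  # all simulated reads pass the bounds validator unchanged
  expect_equal(nrow(validate_reads(rpf, ann)), nrow(rpf))
  expect_equal(attr(validate_reads(mrna, ann), "n_rejected"), 0L)
  expect_true(all(rpf$length >= 26 & rpf$length <= 34))

  rpf2 <- simulate_rpf_reads(cfg, ann, ab$ribo[, 1], "control_rep1")
  expect_identical(rpf, rpf2)
  rpf_other <- simulate_rpf_reads(cfg, ann, ab$ribo[, 1], "control_rep2")
  expect_false(identical(rpf$five_prime_pos, rpf_other$five_prime_pos))

  empty <- simulate_mrna_reads(sim_config(seed = 1, n_genes = 5,
                                          depth_mrna = 0),
                               ann[1:5, ], ab$rna[1:5, 1], "s")
  expect_equal(nrow(empty), 0L)
})

test_that("degenerate frame bias q = 1 puts every body 5' end on frame 0", {
  cfg <- small_cfg(frame0_bias = 1, start_peak_fold = 1)
  ann <- simulate_annotation(cfg)
  ab <- simulate_abundances(cfg, ann, "control")
  rpf <- simulate_rpf_reads(cfg, ann, ab$ribo[, 1], "s1")
  body <- rpf$five_prime_pos[rpf$five_prime_pos != cfg$peak_offset_nt]
  expect_true(all(body %% 3 == 0))
})

test_that("relative abundance is recovered by read counts within multinomial error", {
  # two genes, one at twice the abundance of the other
  ann <- as_gene_annotation(data.frame(gene_id = c("gA", "gB"),
                                       cds_length = 600L,
                                       upstream_extension = 25L,
                                       is_top = FALSE))
  cfg <- sim_config(seed = 3, n_genes = 2, depth_mrna = 3e4)
  mrna <- simulate_mrna_reads(cfg, ann, c(gA = 2, gB = 1), "s1")
  ct <- count_reads(mrna, ann, "s1")
  n <- sum(ct)
  p_hat <- ct["gA", 1] / n
  se <- sqrt(2 / 3 * 1 / 3 / n)  # binomial SE at p = 2/3
  expect_lt(abs(p_hat - 2 / 3), 4 * se)
})

test_that("synthetic panel is seeded and planted coefficients are exact at zero noise", {
  pc <- panel_config(seed = 9, noise_sd = 0, predictor_cv = 0.2)
  p1 <- simulate_panel(pc)
  p2 <- simulate_panel(pc)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 30L)
  expect_equal(unname(table(p1$group)[pc$groups]), rep(6L, 5),
               ignore_attr = TRUE)

  # response is an exact linear function of the planted predictors
  beta <- default_panel_coefficients()
  X <- as.matrix(p1[, names(beta)])
  expect_equal(p1$Slc25a25_protein,
               pc$intercept + as.numeric(X %*% beta), tolerance = 1e-12)
})

test_that("panel TSV round-trips and rejects missing responses", {
  pan <- simulate_panel(panel_config(seed = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(pan, path)
  back <- read_panel(path)
  expect_equal(back$Slc25a25_protein, pan$Slc25a25_protein, tolerance = 1e-9)

  bad <- pan; bad$Slc25a25_protein[1] <- NA
  bad_path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(bad, bad_path)
  expect_error(read_panel(bad_path), "missing response")
})
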