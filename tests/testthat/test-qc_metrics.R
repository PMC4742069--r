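test_that("replicate correlation is 1 for identical and scaled columns", {
  x <- c(10, 200, 3000, 40, 5)
  expect_equal(replicate_correlation(x, x), 1)
  # a global scale factor is a shift in log space
  expect_equal(replicate_correlation(x, 2 * x, pseudocount = 1e-12), 1,
               tolerance = 1e-9)
  expect_error(replicate_correlation(c(1, 2), c(1, 2)), "at least 3")
})

test_that("replicate correlation matches the direct Pearson formula", {
  set.seed(101)
  a <- rlnorm(50, log(100), 1)
  b <- a * rlnorm(50, 0, 0.3)
  pc <- 0.5
  la <- log2(a + pc); lb <- log2(b + pc)
  # brute-force Pearson from first principles
  r_oracle <- sum((la - mean(la)) * (lb - mean(lb))) /
    sqrt(sum((la - mean(la))^2) * sum((lb - mean(lb))^2))
  expect_equal(replicate_correlation(a, b, pc), r_oracle, tolerance = 1e-12)
})

test_that("frame periodicity maps positions mod 3 to frames 0/+1/-1", {
  ann <- toy_annotation()
  fp <- frame_periodicity(toy_reads("g1", c(0, 3, 6, -12)), ann)
  expect_equal(unname(fp$global$fractions["0"]), 1)

  fp3 <- frame_periodicity(toy_reads("g1", c(0, 1, 2)), ann)
  expect_equal(unname(fp3$global$fractions), rep(1 / 3, 3))
  expect_equal(sum(fp3$global$fractions), 1)
  # labels: pos 1 -> +1, pos 2 -> -1
  fpl <- frame_periodicity(toy_reads("g1", c(1, 1, 2)), ann)
  expect_equal(unname(fpl$global$fractions["+1"]), 2 / 3)
  expect_equal(unname(fpl$global$fractions["-1"]), 1 / 3)

  expect_error(frame_periodicity(toy_reads(character(), integer()), ann),
               "no reads")
})

test_that("frame fractions are invariant to read order and per-gene output drops empty genes", {
  ann <- toy_annotation()
  reads <- toy_reads(c("g1", "g2", "g1", "g2"), c(0, 1, 3, 2))
  fp <- frame_periodicity(reads, ann)
  fp_rev <- frame_periodicity(reads[4:1, ], ann)
  expect_equal(fp$global, fp_rev$global)
  expect_setequal(fp$per_gene$gene_id, c("g1", "g2"))
  expect_equal(rowSums(fp$per_gene[, c("frac_0", "frac_plus1", "frac_minus1")]),
               rep(1, 2), ignore_attr = TRUE)
})

test_that("metagene density self-normalizes to 1 for uniform coverage", {
  ann <- wide_annotation(n = 3)
  pos <- rep(-25:114, times = 3)
  reads <- toy_reads(rep(ann$gene_id, each = 140), pos)
  prof <- metagene_profile(reads, ann)
  expect_equal(prof$density, rep(1, 140))
  expect_s3_class(prof, "metagene_profile")
})

test_that("a point mass concentrates the whole normalization mass at one position", {
  ann <- wide_annotation(n = 1)
  reads <- toy_reads(rep("g01", 10), rep(-12L, 10))
  prof <- metagene_profile(reads, ann)
  expect_equal(prof$density[prof$position == -12], 140)  # window length
  expect_equal(sum(prof$density), 140)
  peak <- find_start_peak(prof)
  expect_true(peak$found)
  expect_equal(peak$peak_nt, -12L)
  expect_equal(peak$peak_codon, -4L)
})

test_that("metagene profile is invariant to duplicating all reads", {
  ann <- wide_annotation(n = 2)
  set.seed(7)
  reads <- toy_reads(sample(ann$gene_id, 300, replace = TRUE),
                     sample(-25:114, 300, replace = TRUE))
  p1 <- metagene_profile(reads, ann)
  p2 <- metagene_profile(rbind(reads, reads), ann)
  expect_equal(p1$density, p2$density, tolerance = 1e-12)
})

test_that("genes shorter than the window are excluded, all-short is an error", {
  ann <- as_gene_annotation(data.frame(
    gene_id = c("long", "short"), cds_length = c(300L, 60L),
    upstream_extension = 25L, is_top = FALSE))
  reads <- toy_reads(c("long", "short"), c(0L, 0L))
  expect_message(prof <- metagene_profile(reads, ann), "excluded")
  expect_equal(attr(prof, "n_excluded_genes"), 1L)

  expect_error(
    suppressMessages(metagene_profile(reads, ann[ann$gene_id == "short", ])),
    "no gene spans")
})

test_that("simulated footprints place the metagene argmax at the configured peak offset", {
  cfg <- sim_config(seed = 21, n_genes = 60, depth_rpf = 3e4)
  ann <- simulate_annotation(cfg)
  ab <- simulate_abundances(cfg, ann, "control")
  rpf <- simulate_rpf_reads(cfg, ann, ab$ribo[, 1], "s1")
  prof <- metagene_profile(rpf, ann)
  expect_equal(prof$position[which.max(prof$density)], -12L)

  # cross-check the profile against a hand-computed histogram on a subset
  sub <- rpf[1:100, ]
  prof_sub <- metagene_profile(sub, ann)
  hist_oracle <- vapply(-25:114, function(p) sum(sub$five_prime_pos == p), 0)
  expect_equal(prof_sub$density, hist_oracle / mean(hist_oracle),
               tolerance = 1e-12)
})

test_that("flat profiles yield no peak and mRNA-Seq profiles stay peakless", {
  flat <- structure(data.frame(position = -25:114, density = 1),
                    class = c("metagene_profile", "data.frame"))
  expect_false(find_start_peak(flat)$found)

  cfg <- sim_config(seed = 33, n_genes = 60, depth_mrna = 3e4)
  ann <- simulate_annotation(cfg)
  ab <- simulate_abundances(cfg, ann, "control")
  mrna <- simulate_mrna_reads(cfg, ann, ab$rna[, 1], "s1")
  expect_false(find_start_peak(metagene_profile(mrna, ann))$found)
  # and no triplet phasing: each frame close to 1/3
  fr <- frame_periodicity(mrna, ann)$global$fractions
  se <- sqrt((1 / 3) * (2 / 3) / cfg$depth_mrna)
  expect_true(all(abs(fr - 1 / 3) < 4 * se))
})
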