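---
title: "Methods: thresholding, translational efficiency, and panel regression in riboshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thresholding, translational efficiency, and panel regression in riboshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboshift)
```

riboshift implements the statistical core of a paired ribosome-profiling
(Ribo-seq) + mRNA-Seq analysis of acute exercise in skeletal muscle: library
quality control, a data-driven minimum-expression threshold, translational
efficiency (TE) and its shift in TOP-motif genes, and a small expression-panel
regression. This vignette documents the models and the choices behind each
default; the README shows the worked example.

## Coordinate model and synthetic data

All read positions are transcript coordinates: nucleotide 0 is the A of the
AUG, negative positions are 5' UTR. An annotation row gives `cds_length`
(a multiple of 3) and `upstream_extension` (default 25 nt of mapped UTR).

The generator (`sim_config()` + `simulate_rpf_reads()` etc.) produces data
with exactly the structure the analysis assumes, at the scale of the motivating
experiment. Defaults, fixed a priori:

* `n_genes = 1010`, of which `top_fraction = 59/1010` carry a 5' TOP motif —
  a muscle-sized well-expressed transcriptome with a realistic TOP class size.
* `depth_rpf = depth_mrna = 2e5` reads per library, the scale of a
  small-benchtop semiconductor sequencing run.
* Each replicate is a pool of `n_mice_per_replicate = 3` animals; each
  animal contributes an independent lognormal abundance factor with
  coefficient of variation `mouse_cv = 0.1`. Averaging 3 mice per pool and
  differencing two pools gives a biological replicate-fraction SD of
  `mouse_cv / (2 * sqrt(6))` ≈ 0.02 at high counts (see below).
* Footprints: lengths 26–34 with the mode at 30 nt; a fraction
  `frame0_bias = 0.8` of 5' ends fall in the coding frame; a dwell peak of
  weight `start_peak_fold = 20` (relative to one body codon slot) sits at
  `peak_offset_nt = -12`, i.e. 4 codons upstream of the AUG, the offset
  expected for the 5' end of an initiating 80S footprint.
* mRNA-Seq fragments are uniform over the transcript with no frame structure
  and no start peak — the negative control for both QC statistics.

Counts are multinomial at fixed library size, so library sizes are exact and
genes compete compositionally, as in real RPM data. `simulate_counts()` skips
read positions entirely, which keeps deep (1e6+) simulated libraries cheap.
Sub-seeds for each sample are derived deterministically from the master seed
(`derive_seed()`), so every experiment is reproducible from one integer.

## Quality control

`frame_periodicity()` reports the fraction of 5' ends in frames 0 / +1 / −1
(position mod 3). `metagene_profile()` averages per-position density over the
window −25..+114 nt, normalizing by the mean over those 140 positions;
`find_start_peak()` flags the maximum if it exceeds `min_fold = 3` times the
median of the profile, reporting it in nt and codons.
`replicate_correlation()` is Pearson on `log2(RPM + 0.5)`.

For the periodicity *recovery* check (simulated bias vs estimated fraction)
the simulations use `start_peak_fold = 1`: the start-peak point mass sits in
frame 0 by construction and would otherwise inflate the frame-0 fraction by a
few 1e-3, confounding a tolerance-level comparison. The peak and periodicity
properties are therefore validated in isolation.

## Binomial-partitioning expression threshold

If a gene has `N` reads total across two replicate libraries and every read
independently lands in replicate 1 with probability `p` (the replicate's share
of the summed library size, ≈ 0.5), the replicate fraction `f = a / (a + b)`
has SD `sqrt(p (1 − p) / N)` — pure counting noise. Biological variability
between replicate pools adds an `N`-independent floor `σ_b`. The observed SD
of `f`, binned by mean count (20 log-spaced bins between the 1st and 99th
percentiles), therefore tracks the binomial prediction at low counts and
detaches from it at high counts.

`select_threshold()` calls the threshold at the first of `run_length = 3`
consecutive bins whose observed SD exceeds `excess_factor = 1.2` times the
prediction, converting the bin's lower count edge to RPM via the mean library
size. Setting observed² = counting + biological variance gives the closed-form
crossover

  N\* = p (1 − p) (k² − 1) / σ_b²,

which at `k = 1.2`, `p = 0.5`, `σ_b = 0.02` is `N* = 275` total reads — the
oracle used in the tests (with a one-bin tolerance, since the estimate is
quantized to bin edges). With `mouse_cv = 0` there is no floor and no
threshold is found.

## Translational efficiency and the TOP shift

`translational_efficiency()` computes per condition
`TE = mean(RPF RPM) / mean(mRNA RPM)` (replicates averaged before the ratio;
`per_replicate = TRUE` averages per-replicate ratios instead) and the natural
log ratio exercise/control. `top_shift_test()` compares log TE ratios of
TOP-motif genes against all other genes with a two-sample Kolmogorov–Smirnov
test and reports both medians, so the *direction* (TOP suppressed when mTOR
signaling drops after exercise) is explicit, not just a p-value.

The KS statistic is the supremum difference of the two right-continuous
ECDFs evaluated on the pooled points (ties handled exactly); the p-value is
the asymptotic Kolmogorov survival function at
`sqrt(n1 n2 / (n1 + n2)) D`, an alternating series truncated at 1e-12.
`stats::ks.test()` is used in the test suite only as a cross-check.

## Expression-panel regression

`simulate_panel()` generates a 5-group (no-exercise, 0 h, 1 h, 2 h, 4 h
post-exercise), 6-animals-per-group panel: 8 transcript-level predictors plus
a protein response generated as intercept + planted linear combination +
Gaussian noise. Four predictors carry nonzero planted coefficients
(Pmpca +2.81, Immp2l −3.32, Nrf2 −0.59, Mmp2 +0.275; intercept 1.825); four
are pure noise.

`backward_eliminate()` fits OLS (via `stats::lm` behind `ols_fit()`, with an
explicit rank check that names collinear columns) on the pooled early groups
(default NoEx/0h/1h, n = 18) and repeatedly drops the predictor with the
largest p-value while that p-value exceeds `alpha_stay = 0.3`, down to
`min_predictors`. With `alpha_stay = 0.3` the number of removals is
stochastic — a pure-noise p-value is uniform, so each noise predictor
survives with probability 0.3. The deterministic property, and what the
tests assert, is the *ordering*: with `alpha_stay = 0` and
`min_predictors = 4`, the four removed predictors are exactly the four noise
predictors, and the surviving coefficients match the planted values.

## Limitations

* The KS p-value is asymptotic; below ~10 observations per group prefer the
  exact test.
* The threshold estimate is quantized to bin edges; its sampling variability
  is about one bin width.
* The simulator plants effects multiplicatively on abundances, so RPM
  compositionality deflates an observed fold on a gene with library share `s`
  by `1 / (1 + (fold − 1) s)`; planted-effect recovery checks use
  well-expressed but small-share genes.
* `pca_profiles()` fixes component signs by the first alphabetical gene's
  loading, which is a convention, not an inference.
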