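#' Configuration for the synthetic qPCR/western expression panel
#'
#' Emulates a per-mouse panel of eight transcript measurements (relative
#' expression units, qPCR-style) plus Slc25a25 protein densitometry across
#' five time-point groups (no exercise; immediately after; 1, 2, 4 h post
#' exercise). Protein abundance is generated as a linear combination of the
#' predictors plus Gaussian noise, so regression analyses downstream have a
#' planted ground truth.
#'
#' The default coefficient vector plants signal on four predictors —
#' Pmpca +2.81, Immp2l -3.32, Nrf2 -0.59, Mmp2 +0.275 — and zero on the
#' remaining four (Slc25a25_mRNA, Atrogin1, MuRF1, Yme1l1), the
#' mitochondrial-proteolysis structure the regression module is designed to
#' recover. Default group means follow the qualitative time courses of the
#' emulated experiment (e.g. ~7-fold Slc25a25 mRNA induction immediately
#' after exercise, ~3-fold Nrf2, Immp2l dip at 1 h).
#'
#' @param seed Integer seed.
#' @param n_per_group Mice per group (>= 2).
#' @param groups Ordered group labels.
#' @param group_means Variables x groups matrix of predictor means.
#' @param coefficients Named vector linking predictors to protein abundance.
#' @param intercept Intercept of the planted linear model.
#' @param predictor_cv Relative spread of predictor values around their
#'   group mean.
#' @param noise_sd SD of the Gaussian noise on protein abundance.
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(seed = 1L,
                         n_per_group = 6L,
                         groups = c("NoEx", "0h", "1h", "2h", "4h"),
                         group_means = default_panel_means(groups),
                         coefficients = default_panel_coefficients(),
                         intercept = 1.825,
                         predictor_cv = 0.15,
                         noise_sd = 0.05) {
  stopifnot(n_per_group >= 2, noise_sd >= 0, predictor_cv >= 0,
            identical(colnames(group_means), groups),
            all(names(coefficients) %in% rownames(group_means)))
  cfg <- list(seed = as.integer(seed), n_per_group = as.integer(n_per_group),
              groups = groups, group_means = group_means,
              coefficients = coefficients, intercept = intercept,
              predictor_cv = predictor_cv, noise_sd = noise_sd)
  class(cfg) <- "panel_config"
  cfg
}

#' Panel predictor variables
#' @return Character vector of the eight predictor names.
#' @export
panel_predictors <- function() {
  c("Slc25a25_mRNA", "Mmp2", "Nrf2", "Atrogin1", "MuRF1",
    "Pmpca", "Yme1l1", "Immp2l")
}

#' Default planted regression coefficients
#' @return Named numeric vector over [panel_predictors()].
#' @export
default_panel_coefficients <- function() {
  b <- c(Slc25a25_mRNA = 0, Mmp2 = 0.275, Nrf2 = -0.59, Atrogin1 = 0,
         MuRF1 = 0, Pmpca = 2.81, Yme1l1 = 0, Immp2l = -3.32)
  b[panel_predictors()]
}

#' Default predictor group means
#' @param groups Group labels (5 time points).
#' @return Matrix predictors x groups, NoEx normalized to 1.
#' @export
default_panel_means <- function(groups = c("NoEx", "0h", "1h", "2h", "4h")) {
  m <- rbind(
    Slc25a25_mRNA = c(1, 7.0, 4.0, 2.0, 1.5),
    Mmp2          = c(1, 2.0, 1.8, 1.5, 1.2),
    Nrf2          = c(1, 3.0, 2.5, 1.8, 1.3),
    Atrogin1      = c(1, 0.8, 0.7, 0.8, 0.9),
    MuRF1         = c(1, 0.8, 0.7, 0.8, 0.9),
    Pmpca         = c(1, 1.0, 1.2, 1.6, 1.3),
    Yme1l1        = c(1, 1.0, 1.1, 1.5, 1.3),
    Immp2l        = c(1, 0.9, 0.6, 0.8, 0.9))
  colnames(m) <- groups
  m
}

#' Simulate an expression panel
#'
#' Per mouse, each predictor is drawn as
#' `group_mean * (1 + Normal(0, predictor_cv))`; the response
#' `Slc25a25_protein` is `intercept + X %*% coefficients +
#' Normal(0, noise_sd)`.
#'
#' @param pconfig A [panel_config()].
#' @return An `expression_panel` data.frame with columns `mouse_id`,
#'   `group`, `Slc25a25_protein`, and one column per predictor.
#' @export
simulate_panel <- function(pconfig) {
  set.seed(derive_seed(pconfig$seed, "panel"))
  vars <- rownames(pconfig$group_means)
  n_total <- pconfig$n_per_group * length(pconfig$groups)
  group <- rep(pconfig$groups, each = pconfig$n_per_group)

  X <- sapply(vars, function(v) {
    mu <- pconfig$group_means[v, group]
    mu * (1 + stats::rnorm(n_total, 0, pconfig$predictor_cv))
  })
  beta <- rep(0, length(vars)); names(beta) <- vars
  beta[names(pconfig$coefficients)] <- pconfig$coefficients
  protein <- pconfig$intercept + as.numeric(X %*% beta) +
    stats::rnorm(n_total, 0, pconfig$noise_sd)

  out <- data.frame(mouse_id = sprintf("m%03d", seq_len(n_total)),
                    group = group, Slc25a25_protein = protein,
                    X, stringsAsFactors = FALSE, check.names = FALSE)
  class(out) <- c("expression_panel", "data.frame")
  out
}

#' Read an expression panel from TSV
#' @param path TSV with columns mouse_id, group, Slc25a25_protein and the
#'   predictor columns.
#' @return An `expression_panel` data.frame.
#' @export
read_panel <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("mouse_id", "group", "Slc25a25_protein")
  if (!all(required %in% names(tab))) {
    stop("panel format error: need columns ", paste(required, collapse = ", "))
  }
  if (any(is.na(tab$Slc25a25_protein))) {
    stop("panel validation error: missing response values")
  }
  class(tab) <- c("expression_panel", "data.frame")
  tab
}

#' Write an expression panel to TSV
#' @param panel An `expression_panel`.
#' @param path Output path.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
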