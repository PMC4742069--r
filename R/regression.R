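#' Per-group correlations between protein abundance and predictors
#'
#' Within each requested group, the Pearson correlation between
#' `Slc25a25_protein` and each predictor is computed, returned as an edge
#' list suitable for network export. A constant column in a group makes r
#' undefined; it is reported as `NA` with a note in the `note` column.
#'
#' @param panel An `expression_panel`.
#' @param groups Group labels to include (each needs >= 3 mice).
#' @param predictors Predictor column names (default [panel_predictors()],
#'   intersected with the panel's columns).
#' @return data.frame with columns `group`, `predictor`, `r`, `n`, `note`.
#' @export
group_correlations <- function(panel, groups,
                               predictors = intersect(panel_predictors(),
                                                      names(panel))) {
  stopifnot(all(groups %in% panel$group))
  out <- do.call(rbind, lapply(groups, function(g) {
    sub <- panel[panel$group == g, , drop = FALSE]
    if (nrow(sub) < 3) stop("group_correlations: group '", g, "' has < 3 mice")
    do.call(rbind, lapply(predictors, function(p) {
      x <- sub[[p]]; y <- sub$Slc25a25_protein
      constant <- stats::sd(x) == 0 || stats::sd(y) == 0
      data.frame(group = g, predictor = p,
                 r = if (constant) NA_real_ else stats::cor(x, y),
                 n = nrow(sub),
                 note = if (constant) "constant column" else "",
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Ordinary least-squares fit with coefficient inference
#'
#' Least-squares fit of `y` on the columns of `X` with an intercept
#' (optional), standard errors from the residual variance, t statistics and
#' two-sided p-values on `n - p - 1` (or `n - p`) degrees of freedom. The
#' fit is delegated to [stats::lm()]; rank deficiency is detected first and
#' reported with the offending columns named.
#'
#' @param X Numeric predictor matrix with column names.
#' @param y Response vector.
#' @param intercept Include an intercept (default `TRUE`).
#' @return List of class `regression_model`: `coefficients` data.frame
#'   (`term`, `estimate`, `std_error`, `t_value`, `p_value`), `r_squared`,
#'   `sigma`, `df_residual`, `n`, `intercept`.
#' @export
ols_fit <- function(X, y, intercept = TRUE) {
  X <- as.matrix(X)
  stopifnot(!is.null(colnames(X)), length(y) == nrow(X))
  n <- nrow(X); p <- ncol(X)
  if (n <= p + as.integer(intercept)) {
    stop("ols_fit: need n > number of predictors",
         if (intercept) " + 1" else "")
  }
  M <- if (intercept) cbind(`(Intercept)` = 1, X) else X
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    dropped <- colnames(M)[qrM$pivot[(qrM$rank + 1):ncol(M)]]
    stop("ols_fit: rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }

  dat <- data.frame(.y = y, X, check.names = FALSE)
  fml <- stats::reformulate(sprintf("`%s`", colnames(X)), response = ".y",
                            intercept = intercept)
  fit <- stats::lm(fml, data = dat)
  sm <- summary(fit)
  co <- sm$coefficients
  terms <- gsub("`", "", rownames(co))

  out <- list(
    coefficients = data.frame(term = terms,
                              estimate = co[, 1], std_error = co[, 2],
                              t_value = co[, 3], p_value = co[, 4],
                              stringsAsFactors = FALSE, row.names = NULL),
    r_squared = sm$r.squared,
    sigma = sm$sigma,
    df_residual = fit$df.residual,
    n = n,
    intercept = intercept)
  class(out) <- "regression_model"
  out
}

#' Backward elimination of the least significant predictor
#'
#' Starting from the full model, the predictor with the largest p-value is
#' removed and the model refit, repeatedly, while that largest p-value
#' exceeds `alpha_stay` and more than `min_predictors` predictors remain.
#' The full removal trace is returned so any alternative stopping rule can
#' be audited against it.
#'
#' @param panel An `expression_panel`.
#' @param groups Groups pooled into the regression (no group covariate by
#'   default, mirroring a pooled design; set `group_covariate = TRUE` to
#'   add group indicator columns).
#' @param predictors Predictor columns (default all of
#'   [panel_predictors()] present in the panel).
#' @param alpha_stay A predictor whose p-value is below this stays; the
#'   default 0.3 lets moderately supported predictors survive.
#' @param min_predictors Elimination never goes below this many predictors.
#' @param intercept Passed to [ols_fit()].
#' @param group_covariate Add group indicator variables to the design.
#' @return List of class `elimination_trace`: `final` (a
#'   `regression_model`), `trace` (data.frame `step`, `removed`,
#'   `p_removed`, `r_squared`, `n_predictors`), `models` (list of all
#'   fitted models), `predictors_final`.
#' @export
backward_eliminate <- function(panel, groups = c("NoEx", "0h", "1h"),
                               predictors = intersect(panel_predictors(),
                                                      names(panel)),
                               alpha_stay = 0.3, min_predictors = 1L,
                               intercept = TRUE, group_covariate = FALSE) {
  sub <- panel[panel$group %in% groups, , drop = FALSE]
  y <- sub$Slc25a25_protein
  X <- as.matrix(sub[, predictors, drop = FALSE])
  if (group_covariate && length(groups) > 1) {
    gm <- stats::model.matrix(~ factor(sub$group, levels = groups))[, -1,
                                                                    drop = FALSE]
    colnames(gm) <- paste0("group_", groups[-1])
    X <- cbind(X, gm)
  }

  current <- colnames(X)
  models <- list()
  trace <- data.frame(step = integer(), removed = character(),
                      p_removed = numeric(), r_squared = numeric(),
                      n_predictors = integer(), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    fit <- ols_fit(X[, current, drop = FALSE], y, intercept = intercept)
    models[[length(models) + 1L]] <- fit
    co <- fit$coefficients
    co <- co[co$term %in% current, , drop = FALSE]  # never remove intercept
    co$p_value[is.nan(co$p_value)] <- 1  # 0/0 t under an exact fit
    worst <- which.max(co$p_value)
    trace <- rbind(trace, data.frame(
      step = step, removed = NA_character_, p_removed = NA_real_,
      r_squared = fit$r_squared, n_predictors = length(current),
      stringsAsFactors = FALSE))
    if (co$p_value[worst] <= alpha_stay || length(current) <= min_predictors) {
      break
    }
    trace$removed[nrow(trace)] <- co$term[worst]
    trace$p_removed[nrow(trace)] <- co$p_value[worst]
    current <- setdiff(current, co$term[worst])
    step <- step + 1L
  }

  out <- list(final = models[[length(models)]], trace = trace,
              models = models, predictors_final = current)
  class(out) <- "elimination_trace"
  out
}
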