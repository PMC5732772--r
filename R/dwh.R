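#' Durbin-Wu-Hausman endogeneity test (contrast form)
#'
#' Compares the OLS and 2SLS estimates of the same exposure effect. Under
#' exogeneity both are consistent and OLS is efficient, so the contrast
#' `H = (beta_TSLS - beta_OLS)^2 / (se_TSLS^2 - se_OLS^2)` is asymptotically
#' chi-square with 1 degree of freedom (one endogenous regressor). A
#' significant p favours the 2SLS estimate; a non-significant one means the
#' two estimators do not differ beyond sampling error.
#'
#' The variance difference can be non-positive in finite samples; in that
#' case the test falls back to the augmented-regression form
#' ([dwh_augmented()]), which requires the raw data via `data`, and the
#' fallback is recorded in the result.
#'
#' @param ols A `regression_result` from [ols_fit()].
#' @param tsls A `tsls_result` from [tsls_fit()] on the same subjects and
#'   adjustment set.
#' @param data Optional list with elements `y`, `x`, `z` and optionally
#'   `covariates`, used only for the fallback.
#' @param alpha Significance level for the decision rule (default 0.05).
#' @return An object of class `dwh_result`: `statistic`, `df` (1), `p`,
#'   `method` (`"contrast"` or `"augmented"`), `fallback` and `decision`
#'   (`"use_tsls"` if `p < alpha`, else `"either"`).
#' @export
dwh_contrast <- function(ols, tsls, data = NULL, alpha = 0.05) {
  if (!identical(ols$n, tsls$n)) {
    stop("OLS and TSLS fits use different n (", ols$n, " vs ", tsls$n, ")")
  }
  dvar <- tsls$se^2 - ols$se^2
  if (dvar <= 0) {
    if (is.null(data)) {
      stop("non-positive variance difference; supply `data` for the ",
           "augmented-regression fallback")
    }
    out <- dwh_augmented(data$y, data$x, data$z, data$covariates,
                         alpha = alpha)
    out$fallback <- TRUE
    return(out)
  }
  statistic <- (tsls$beta - ols$beta)^2 / dvar
  p <- stats::pchisq(statistic, df = 1, lower.tail = FALSE)
  new_dwh(statistic, p, "contrast", fallback = FALSE, alpha = alpha)
}

#' Durbin-Wu-Hausman endogeneity test (augmented-regression form)
#'
#' The regression-based equivalent of the Hausman contrast: take the
#' residuals `v` of the first-stage regression of exposure on instrument and
#' covariates, then refit the outcome model with `v` added. If the exposure
#' is exogenous the coefficient on `v` is zero; the test statistic is its
#' squared t statistic, referred to chi-square with 1 df. Numerically
#' well-behaved even when the contrast's variance difference is non-positive.
#'
#' @param y Outcome vector.
#' @param x Exposure vector.
#' @param z Instrument vector.
#' @param covariates Optional covariate matrix (both equations).
#' @param alpha Significance level for the decision rule.
#' @return A `dwh_result`; see [dwh_contrast()].
#' @export
dwh_augmented <- function(y, x, z, covariates = NULL, alpha = 0.05) {
  covariates <- as_covariate_matrix(covariates, length(y))
  check_complete(y = y, x = x, z = z, covariates = covariates)
  Z <- design_with_intercept(z, covariates, term = "instrument")
  check_design_rank(Z, length(x))
  v <- x - as.numeric(Z %*% qr.coef(qr(Z), x))
  if (stats::sd(v) < 1e-10 * max(stats::sd(x), 1)) {
    stop("degenerate endogeneity test: first-stage residuals are ",
         "(numerically) zero — instrument coincides with exposure")
  }
  aug <- cbind(covariates, v_endog = v)
  fit <- ols_fit(y, x, aug, term = "exposure")
  t_v <- fit$coefficients["v_endog", "t value"]
  statistic <- t_v^2
  p <- stats::pchisq(statistic, df = 1, lower.tail = FALSE)
  new_dwh(statistic, p, "augmented", fallback = FALSE, alpha = alpha)
}

new_dwh <- function(statistic, p, method, fallback, alpha) {
  structure(list(statistic = statistic, df = 1L, p = p, method = method,
                 fallback = fallback, alpha = alpha,
                 decision = if (p < alpha) "use_tsls" else "either"),
            class = "dwh_result")
}

#' @export
print.dwh_result <- function(x, ...) {
  cat(sprintf(
    "Durbin-Wu-Hausman test (%s form%s): chi2(1) = %.4f, p = %.4g -> %s\n",
    x$method, if (x$fallback) ", contrast fallback" else "",
    x$statistic, x$p,
    if (x$decision == "use_tsls") "OLS inconsistent, use 2SLS"
    else "no detectable endogeneity"))
  invisible(x)
}
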