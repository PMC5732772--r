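#' First-stage instrument-strength diagnostics
#'
#' Quantifies how strongly the instrument (risk score or single-SNP dosage)
#' predicts the exposure. The headline `f_stat` and `r2` come from the
#' univariate regression of exposure on instrument alone, for which the exact
#' identity `F = (R2 / (1 - R2)) * (n - 2)` holds; the covariate-adjusted
#' (partial) F for the instrument is computed alongside. Instruments with
#' `f_stat < 10` are flagged weak, the conventional threshold below which
#' instrumental-variable estimates are prone to weak-instrument bias.
#'
#' @param exposure Exposure vector (serum urate, umol/L).
#' @param z Instrument vector (risk score or dosage).
#' @param covariates Optional covariate matrix for the partial F.
#' @return An object of class `instrument_strength`: `f_stat`, `r2`,
#'   `partial_f`, `p` (univariate first-stage p), `n`, `weak_instrument`.
#' @export
first_stage <- function(exposure, z, covariates = NULL) {
  fs <- first_stage_impl(exposure, z, covariates, allow_perfect = FALSE)
  fs
}

first_stage_impl <- function(exposure, z, covariates, allow_perfect) {
  covariates <- as_covariate_matrix(covariates, length(exposure))
  check_complete(exposure = exposure, z = z, covariates = covariates)
  n <- length(exposure)
  if (n < 3L) stop("too few observations for a first stage")
  if (stats::sd(z) == 0) stop("constant instrument")
  r2 <- stats::cor(exposure, z)^2
  if (!allow_perfect && r2 > 1 - 1e-12) {
    stop("degenerate first stage: instrument explains all exposure variance")
  }
  f_stat <- (r2 / (1 - r2)) * (n - 2)
  p <- stats::pf(f_stat, 1, n - 2, lower.tail = FALSE)

  partial_f <- f_stat
  if (!is.null(covariates)) {
    fit <- ols_fit(exposure, z, covariates, term = "instrument")
    partial_f <- fit$stat^2
  }
  structure(list(f_stat = f_stat, r2 = r2, partial_f = partial_f, p = p,
                 n = n, weak_instrument = f_stat < 10),
            class = "instrument_strength")
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf(
    "First stage (n = %d): F = %.2f, R2 = %.4f, partial F = %.2f, p = %.3g%s\n",
    x$n, x$f_stat, x$r2, x$partial_f, x$p,
    if (x$weak_instrument) "  [WEAK: F < 10]" else ""))
  invisible(x)
}

#' Two-stage least squares (instrumental-variable) fit
#'
#' The Mendelian-randomization estimator. Stage one regresses the exposure on
#' the instrument plus covariates; stage two regresses the outcome on the
#' fitted exposure plus the same covariates. The coefficient on the fitted
#' exposure is the causal-effect estimate. Its variance uses the residual
#' variance of the *structural* equation — residuals taken at the actual
#' (not fitted) exposure — combined with the stage-two cross-product inverse,
#' the classical 2SLS covariance; naive second-stage residuals would
#' understate it. Inference uses the t distribution on `n - k` degrees of
#' freedom of the stage-two design (`df = "t"`, the small-sample convention)
#' or the standard normal (`df = "normal"`).
#'
#' With a single instrument and no covariates the estimate reduces exactly to
#' the Wald ratio `cov(z, y) / cov(z, x)`.
#'
#' @param y Outcome vector (total bilirubin, umol/L).
#' @param x Exposure vector (serum urate, umol/L).
#' @param z Instrument vector.
#' @param covariates Optional covariate matrix included in both stages.
#' @param df `"t"` (default) or `"normal"` inference.
#' @return An object of class `tsls_result`: `beta`, `se`, `stat`, `p`, `n`,
#'   `df`, `adjusted_for` and `first_stage` (an `instrument_strength`).
#' @export
tsls_fit <- function(y, x, z, covariates = NULL, df = c("t", "normal")) {
  df <- match.arg(df)
  covariates <- as_covariate_matrix(covariates, length(y))
  check_complete(y = y, x = x, z = z, covariates = covariates)
  n <- length(y)
  if (length(x) != n || length(z) != n) stop("y, x, z lengths differ")

  fs <- first_stage_impl(x, z, covariates, allow_perfect = TRUE)

  Z <- design_with_intercept(z, covariates, term = "instrument")
  check_design_rank(Z, n)
  x_hat <- as.numeric(Z %*% qr.coef(qr(Z), x))

  X2 <- design_with_intercept(x_hat, covariates, term = "exposure")
  check_design_rank(X2, n)
  k <- ncol(X2)
  # solve on mean-centred columns: with a weak first stage the fitted
  # exposure is nearly flat around a large mean and an uncentred solve
  # loses digits to cancellation
  X2c <- X2[, -1L, drop = FALSE]
  mu <- colMeans(X2c)
  Xc <- sweep(X2c, 2L, mu)
  qrc <- qr(Xc)
  slopes <- qr.coef(qrc, y - mean(y))
  beta_vec <- c(mean(y) - sum(mu * slopes), slopes)
  names(beta_vec) <- colnames(X2)
  # slope block of (X2'X2)^-1 equals the inverse of the centred
  # cross-products; the intercept entry follows from the means
  kc <- k - 1L
  XtXc_inv <- matrix(NA_real_, kc, kc)
  piv <- qrc$pivot
  XtXc_inv[piv, piv] <- chol2inv(qr.R(qrc))
  XtX_inv <- rbind(
    c(1 / n + as.numeric(mu %*% XtXc_inv %*% mu), -as.numeric(mu %*% XtXc_inv)),
    cbind(-as.numeric(XtXc_inv %*% mu), XtXc_inv))

  # structural residuals: actual exposure, 2SLS coefficients
  X_actual <- design_with_intercept(x, covariates, term = "exposure")
  resid_struct <- y - as.numeric(X_actual %*% beta_vec)
  sigma2 <- sum(resid_struct^2) / (n - k)
  se_vec <- sqrt(sigma2 * diag(XtX_inv))

  beta <- beta_vec[["exposure"]]
  se <- se_vec[[which(colnames(X2) == "exposure")]]
  stat <- beta / se
  p <- if (df == "t") 2 * stats::pt(-abs(stat), n - k)
       else 2 * stats::pnorm(-abs(stat))

  structure(list(beta = beta, se = se, stat = stat, p = p, n = n,
                 df = if (df == "t") n - k else Inf,
                 first_stage = fs,
                 adjusted_for = colnames(covariates),
                 coefficients = beta_vec,
                 residuals = resid_struct),
            class = "tsls_result")
}

#' @export
print.tsls_result <- function(x, ...) {
  cat("Two-stage least squares (n = ", x$n, ", adjusted for: ",
      if (length(x$adjusted_for)) paste(x$adjusted_for, collapse = ", ")
      else "none", ")\n", sep = "")
  cat(sprintf("  causal beta = %.4g, se = %.4g, t = %.3f, p = %.3g\n",
              x$beta, x$se, x$stat, x$p))
  cat(sprintf("  first stage: F = %.2f, R2 = %.4f%s\n",
              x$first_stage$f_stat, x$first_stage$r2,
              if (x$first_stage$weak_instrument) "  [WEAK: F < 10]" else ""))
  invisible(x)
}
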