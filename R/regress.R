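#' Ordinary least squares fit for one exposure term
#'
#' The conventional-epidemiology arm: OLS of an outcome on an exposure with
#' optional covariate adjustment, always including an intercept. Standard
#' errors are classical homoskedastic ones,
#' `sqrt(sigma2 * [(X'X)^-1]_jj)` with `sigma2 = RSS / (n - k)`; p-values are
#' two-sided from the t distribution on `n - k` degrees of freedom. The fit
#' itself is delegated to [stats::lm()]; this wrapper adds rank and sample
#' size guards and extracts the exposure term.
#'
#' @param y Outcome vector.
#' @param x Exposure vector.
#' @param covariates Optional covariate matrix/data frame (numeric columns),
#'   or `NULL` for a crude fit.
#' @param term Label for the exposure term in the result.
#' @return An object of class `regression_result`: a list with `term`,
#'   `beta`, `se`, `stat`, `p`, `n`, `df`, `r2`, `adjusted_for` and the full
#'   `coefficients` table.
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- 2 * x + rnorm(50)
#' ols_fit(y, x)
#' @export
ols_fit <- function(y, x, covariates = NULL, term = "exposure") {
  covariates <- as_covariate_matrix(covariates, length(y))
  check_complete(y = y, x = x, covariates = covariates)
  X <- design_with_intercept(x, covariates, term)
  check_design_rank(X, length(y))

  dd <- as.data.frame(X[, -1L, drop = FALSE])
  dd$.y <- y
  fit <- stats::lm(.y ~ ., data = dd)
  sm <- summary(fit)
  co <- sm$coefficients
  if (!term %in% rownames(co)) stop("exposure term lost in fit")  # nocov

  structure(list(term = term,
                 beta = co[term, "Estimate"],
                 se = co[term, "Std. Error"],
                 stat = co[term, "t value"],
                 p = co[term, "Pr(>|t|)"],
                 n = length(y),
                 df = fit$df.residual,
                 r2 = sm$r.squared,
                 adjusted_for = colnames(covariates),
                 coefficients = co),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat("OLS fit (n = ", x$n, ", adjusted for: ",
      if (length(x$adjusted_for)) paste(x$adjusted_for, collapse = ", ")
      else "none", ")\n", sep = "")
  cat(sprintf("  %s: beta = %.4g, se = %.4g, t = %.3f, p = %.3g, R2 = %.4f\n",
              x$term, x$beta, x$se, x$stat, x$p, x$r2))
  invisible(x)
}

#' Instrument-confounder independence check
#'
#' Regresses a measured confounder on the genetic risk score, crude and
#' covariate-adjusted, producing one row pair of the instrument-validity
#' table. Under the core Mendelian-randomization assumption the score should
#' show no association with any measured confounder. A binary confounder
#' (sex) is handled through the same linear-probability convention as the
#' design matrices (male = 1, female = 0).
#'
#' @param grs A `grs_vector` (see [weighted_grs()]) or a numeric score vector.
#' @param confounder Numeric vector, or a character/factor sex vector.
#' @param adjust Optional covariate matrix for the adjusted fit (typically
#'   the other confounders), or `NULL` for crude-only.
#' @param name Confounder label used in the output.
#' @return A data frame with rows `crude` and (if `adjust` is given)
#'   `adjusted`: columns `confounder`, `model`, `beta`, `se`, `stat`, `p`,
#'   `n`.
#' @export
confounder_check <- function(grs, confounder, adjust = NULL,
                             name = "confounder") {
  score <- if (is.data.frame(grs)) grs$score else as.numeric(grs)
  if (is.character(confounder) || is.factor(confounder)) {
    confounder <- as.numeric(as.character(confounder) == "male")
  }
  if (stats::sd(confounder) == 0) {
    stop("constant confounder '", name, "': nothing to regress")
  }
  rows <- list(fit_row(name, "crude",
                       ols_fit(confounder, score, NULL, term = "grs")))
  if (!is.null(adjust)) {
    rows <- c(rows, list(fit_row(name, "adjusted",
                                 ols_fit(confounder, score, adjust,
                                         term = "grs"))))
  }
  do.call(rbind, rows)
}

fit_row <- function(name, model, fit) {
  data.frame(confounder = name, model = model, beta = fit$beta, se = fit$se,
             stat = fit$stat, p = fit$p, n = fit$n,
             stringsAsFactors = FALSE)
}

# --- shared design-matrix helpers ------------------------------------------

as_covariate_matrix <- function(covariates, n) {
  if (is.null(covariates) || (is.matrix(covariates) && ncol(covariates) == 0L))
    return(NULL)
  if (is.data.frame(covariates)) {
    for (col in names(covariates)) {
      if (is.character(covariates[[col]]) || is.factor(covariates[[col]])) {
        covariates[[col]] <-
          as.numeric(as.character(covariates[[col]]) == "male")
      }
    }
    covariates <- as.matrix(covariates)
  }
  if (is.null(dim(covariates))) covariates <- matrix(covariates, ncol = 1L)
  if (nrow(covariates) != n) stop("covariate rows do not match n")
  if (is.null(colnames(covariates))) {
    colnames(covariates) <- paste0("c", seq_len(ncol(covariates)))
  }
  covariates
}

design_with_intercept <- function(x, covariates, term = "exposure") {
  X <- cbind(`(Intercept)` = rep(1, length(x)), x, covariates)
  colnames(X)[2L] <- term
  X
}

check_design_rank <- function(X, n) {
  k <- ncol(X)
  if (n <= k) {
    stop("too few observations: n = ", n, " with ", k, " model columns")
  }
  qrX <- qr(X)
  if (qrX$rank < k) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):k]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  invisible(qrX)
}

check_complete <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    if (!is.null(args[[nm]]) && anyNA(args[[nm]])) {
      stop("missing values in ", nm, "; filter to complete cases first")
    }
  }
  invisible(TRUE)
}

#' Build a numeric design matrix from cohort covariate columns
#'
#' Sex is coded male = 1, female = 0 (fixed convention).
#'
#' @param cohort A `cohort_table` or data frame.
#' @param adjust Character vector of covariate column names; entries absent
#'   from the cohort raise an error.
#' @return A numeric matrix with one column per covariate, or `NULL` when
#'   `adjust` is empty.
#' @export
covariate_matrix <- function(cohort, adjust) {
  if (length(adjust) == 0L) return(NULL)
  absent <- setdiff(adjust, names(cohort))
  if (length(absent) > 0L) {
    stop("adjustment column(s) absent from cohort: ",
         paste(absent, collapse = ", "))
  }
  as_covariate_matrix(as.data.frame(cohort)[adjust], nrow(cohort))
}
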