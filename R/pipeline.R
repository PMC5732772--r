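#' Analysis configuration
#'
#' Central defaults for the stratified analysis: the covariate adjustment set
#' (age, sex, BMI, BUN, FBG; sex is dropped automatically inside single-sex
#' subgroups), the hyperuricemia threshold (serum urate strictly greater than
#' 417 umol/L; 417 exactly is "normal"), the significance level, the risk
#' score mode and the minimum subgroup size below which rows are marked
#' insufficient rather than estimated.
#'
#' @param adjust Covariate names for adjusted models.
#' @param su_threshold Hyperuricemia threshold, umol/L (strict `>`).
#' @param alpha Significance level for the endogeneity decision.
#' @param grs_mode `"weighted"` or `"count"` instrument.
#' @param min_n Minimum subgroup size for estimation (default 30).
#' @param impute_missing Mean-impute missing dosages in the score.
#' @return A list of class `mr_config`.
#' @export
mr_config <- function(adjust = c("age", "sex", "bmi", "bun", "fbg"),
                      su_threshold = 417, alpha = 0.05,
                      grs_mode = c("weighted", "count"),
                      min_n = 30, impute_missing = FALSE) {
  grs_mode <- match.arg(grs_mode)
  structure(list(adjust = adjust, su_threshold = su_threshold, alpha = alpha,
                 grs_mode = grs_mode, min_n = min_n,
                 impute_missing = impute_missing),
            class = "mr_config")
}

subgroup_filters <- function(config) {
  thr <- config$su_threshold
  list(
    all            = function(d) rep(TRUE, nrow(d)),
    males          = function(d) d$sex == "male",
    females        = function(d) d$sex == "female",
    normal         = function(d) d$su <= thr,
    normal_males   = function(d) d$su <= thr & d$sex == "male",
    normal_females = function(d) d$su <= thr & d$sex == "female",
    hyperuricemia  = function(d) d$su > thr,
    hyper_males    = function(d) d$su > thr & d$sex == "male",
    hyper_females  = function(d) d$su > thr & d$sex == "female")
}

single_sex <- c("males", "females", "normal_males", "normal_females",
                "hyper_males", "hyper_females")

#' Run the full stratified OLS / 2SLS / endogeneity analysis
#'
#' For each subgroup (all subjects; males; females; and each crossed with the
#' normal / hyperuricemia split at the configured urate threshold) and each
#' model (crude: exposure only; adjusted: plus the configured covariates),
#' fits OLS and 2SLS of bilirubin on serum urate with the genetic risk score
#' as instrument, computes first-stage diagnostics, and compares the two
#' estimators with the Durbin-Wu-Hausman test.
#'
#' Subjects flagged as urate-lowering-drug users and subjects with missing
#' score, exposure, outcome or adjustment covariates are excluded first and
#' counted. Subgroups smaller than `config$min_n` are reported with an
#' `insufficient_n` note instead of estimates.
#'
#' @param cohort A `cohort_table`.
#' @param weights A `snp_weights` table.
#' @param config An [mr_config()].
#' @return A data frame of class `mr_result_table`: one row per (subgroup,
#'   model, estimator) with `beta`, `se`, `stat`, `p`, `n`, `f_stat`, `r2`,
#'   `weak_instrument`, `dwh_p`, `dwh_method`, `note`; attributes `config`
#'   and `exclusions`.
#' @export
run_analysis <- function(cohort, weights, config = mr_config()) {
  validate_cohort(cohort)
  prep <- prepare_analysis_data(cohort, weights, config)
  d <- prep$data

  rows <- list()
  for (sg in names(subgroup_filters(config))) {
    keep <- subgroup_filters(config)[[sg]](d)
    rows <- c(rows, analyse_subgroup(d[keep, , drop = FALSE], sg,
                                     d$.score[keep], config))
  }
  finish_result_table(rows, config, prep$exclusions)
}

prepare_analysis_data <- function(cohort, weights, config) {
  d <- as.data.frame(cohort)
  n0 <- nrow(d)
  on_drug <- d$urate_lowering_drug %in% TRUE
  d <- d[!on_drug, , drop = FALSE]

  score <- genetic_risk_score(as_cohort_table(d, attr(cohort, "snp_ids")),
                              weights, mode = config$grs_mode,
                              impute_missing = config$impute_missing)$score
  d$.score <- score
  cc <- stats::complete.cases(
    d[c("su", "tbil", ".score", setdiff(config$adjust, "sex"))]) &
    !is.na(d$sex)
  d_cc <- d[cc, , drop = FALSE]
  list(data = d_cc,
       exclusions = list(n_input = n0,
                         n_drug_excluded = sum(on_drug),
                         n_incomplete = sum(!cc),
                         n_analysed = nrow(d_cc)))
}

analyse_subgroup <- function(d, sg, z, config) {
  adjust <- config$adjust
  if (sg %in% single_sex) adjust <- setdiff(adjust, "sex")
  out <- list()
  for (model in c("crude", "adjusted")) {
    cov <- if (model == "adjusted") covariate_matrix(d, adjust) else NULL
    adj_names <- if (model == "adjusted") adjust else character(0)
    if (nrow(d) < config$min_n) {
      out <- c(out, result_rows_na(sg, model, nrow(d), "insufficient_n"))
      next
    }
    res <- tryCatch(
      estimate_pair(d$tbil, d$su, z, cov, config$alpha),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      out <- c(out, result_rows_na(sg, model, nrow(d),
                                   paste0("degenerate: ", res)))
    } else {
      out <- c(out, result_rows(sg, model, res, adj_names))
    }
  }
  out
}

estimate_pair <- function(y, x, z, cov, alpha) {
  ols <- ols_fit(y, x, cov)
  fs <- first_stage(x, z, cov)
  ts <- tsls_fit(y, x, z, cov)
  dwh <- dwh_contrast(ols, ts, data = list(y = y, x = x, z = z,
                                           covariates = cov),
                      alpha = alpha)
  list(ols = ols, fs = fs, tsls = ts, dwh = dwh)
}

result_rows <- function(sg, model, res, adjust) {
  base <- data.frame(subgroup = sg, model = model,
                     n = res$ols$n, f_stat = res$fs$f_stat, r2 = res$fs$r2,
                     weak_instrument = res$fs$weak_instrument,
                     dwh_p = res$dwh$p, dwh_method = res$dwh$method,
                     note = "", stringsAsFactors = FALSE)
  list(cbind(data.frame(estimator = "OLS", beta = res$ols$beta,
                        se = res$ols$se, stat = res$ols$stat, p = res$ols$p),
             base),
       cbind(data.frame(estimator = "TLS", beta = res$tsls$beta,
                        se = res$tsls$se, stat = res$tsls$stat,
                        p = res$tsls$p),
             base))
}

result_rows_na <- function(sg, model, n, note) {
  base <- data.frame(subgroup = sg, model = model, n = n, f_stat = NA_real_,
                     r2 = NA_real_, weak_instrument = NA, dwh_p = NA_real_,
                     dwh_method = NA_character_, note = note,
                     stringsAsFactors = FALSE)
  lapply(c("OLS", "TLS"), function(est) {
    cbind(data.frame(estimator = est, beta = NA_real_, se = NA_real_,
                     stat = NA_real_, p = NA_real_), base)
  })
}

finish_result_table <- function(rows, config, exclusions) {
  out <- do.call(rbind, rows)
  front <- c("subgroup", "model", "estimator", "beta", "se", "stat", "p",
             "dwh_p", "dwh_method", "n", "f_stat", "r2", "weak_instrument",
             "note")
  out <- out[front]
  rownames(out) <- NULL
  structure(out, class = c("mr_result_table", "data.frame"),
            config = config, exclusions = exclusions)
}

#' @export
print.mr_result_table <- function(x, digits = 4, ...) {
  ex <- attr(x, "exclusions")
  if (!is.null(ex)) {
    cat("Analysed ", ex$n_analysed, "/", ex$n_input, " subjects (",
        ex$n_drug_excluded, " on urate-lowering drugs, ", ex$n_incomplete,
        " incomplete)\n", sep = "")
  }
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Single-SNP instrument analysis
#'
#' Repeats the first-stage diagnostics, 2SLS fit and Durbin-Wu-Hausman test
#' using each SNP's dosage alone as the instrument, in the given subgroups.
#' Single variants are typically far weaker instruments than the composite
#' score; rows with first-stage F below 10 carry `weak_instrument = TRUE`,
#' and SNPs monomorphic in a subgroup are marked degenerate with no estimate.
#'
#' @param cohort A `cohort_table`.
#' @param weights A `snp_weights` table (one row per SNP to test).
#' @param config An [mr_config()].
#' @param subgroups Subset of the subgroup names used by [run_analysis()]
#'   (default all/males/females).
#' @param model `"adjusted"` (default) or `"crude"`.
#' @return An `mr_result_table` with an extra `snp_id` column; only the TLS
#'   estimator rows are returned (the OLS arm does not depend on the
#'   instrument).
#' @export
per_snp_analysis <- function(cohort, weights, config = mr_config(),
                             subgroups = c("all", "males", "females"),
                             model = c("adjusted", "crude")) {
  model <- match.arg(model)
  validate_cohort(cohort)
  filters <- subgroup_filters(config)
  stopifnot(all(subgroups %in% names(filters)))
  d0 <- as.data.frame(cohort)
  d0 <- d0[!(d0$urate_lowering_drug %in% TRUE), , drop = FALSE]

  rows <- list()
  for (i in seq_len(nrow(weights))) {
    snp <- weights$snp_id[i]
    for (sg in subgroups) {
      adjust <- if (model == "adjusted") {
        if (sg %in% single_sex) setdiff(config$adjust, "sex")
        else config$adjust
      } else character(0)
      keep <- filters[[sg]](d0) &
        stats::complete.cases(d0[c("su", "tbil", snp, adjust)])
      d <- d0[keep, , drop = FALSE]
      z <- d[[snp]]
      row <- per_snp_row(d, z, snp, sg, model, adjust, config)
      rows <- c(rows, list(row))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("mr_result_table", "data.frame"), config = config)
}

per_snp_row <- function(d, z, snp, sg, model, adjust, config) {
  na_row <- function(note, fs = NULL) {
    data.frame(snp_id = snp, subgroup = sg, model = model, estimator = "TLS",
               beta = NA_real_, se = NA_real_, stat = NA_real_, p = NA_real_,
               dwh_p = NA_real_, dwh_method = NA_character_, n = nrow(d),
               f_stat = if (is.null(fs)) NA_real_ else fs$f_stat,
               r2 = if (is.null(fs)) NA_real_ else fs$r2,
               weak_instrument = if (is.null(fs)) NA else fs$weak_instrument,
               note = note, stringsAsFactors = FALSE)
  }
  if (nrow(d) < config$min_n) return(na_row("insufficient_n"))
  if (stats::sd(z) == 0) return(na_row("degenerate: monomorphic SNP"))
  cov <- if (length(adjust)) covariate_matrix(d, adjust) else NULL
  res <- tryCatch(estimate_pair(d$tbil, d$su, z, cov, config$alpha),
                  error = function(e) conditionMessage(e))
  if (is.character(res)) return(na_row(paste0("degenerate: ", res)))
  data.frame(snp_id = snp, subgroup = sg, model = model, estimator = "TLS",
             beta = res$tsls$beta, se = res$tsls$se, stat = res$tsls$stat,
             p = res$tsls$p, dwh_p = res$dwh$p, dwh_method = res$dwh$method,
             n = res$tsls$n, f_stat = res$fs$f_stat, r2 = res$fs$r2,
             weak_instrument = res$fs$weak_instrument, note = "",
             stringsAsFactors = FALSE)
}

#' Instrument diagnostics: strength and confounder independence
#'
#' Produces the two instrument-validity tables: (1) first-stage strength of
#' the risk score for serum urate in all subjects, males and females
#' (univariate F, R2, p, with the covariate-adjusted partial F alongside);
#' (2) association of the score with each measured potential confounder
#' (age, sex, BMI, FBG, BUN), crude and adjusted for the remaining
#' confounders. Instrument validity requires strong F in (1) and null
#' associations in (2).
#'
#' @param cohort A `cohort_table`.
#' @param weights A `snp_weights` table.
#' @param config An [mr_config()].
#' @return A list with data frames `strength` and `confounders`.
#' @export
instrument_diagnostics <- function(cohort, weights, config = mr_config()) {
  validate_cohort(cohort)
  prep <- prepare_analysis_data(cohort, weights, config)
  d <- prep$data

  strength <- do.call(rbind, lapply(c("all", "males", "females"), function(sg) {
    keep <- subgroup_filters(config)[[sg]](d)
    ds <- d[keep, , drop = FALSE]
    adjust <- setdiff(config$adjust, if (sg %in% single_sex) "sex")
    fs <- first_stage(ds$su, ds$.score, covariate_matrix(ds, adjust))
    data.frame(subgroup = sg, f_stat = fs$f_stat, r2 = fs$r2,
               partial_f = fs$partial_f, p = fs$p, n = fs$n,
               weak_instrument = fs$weak_instrument,
               stringsAsFactors = FALSE)
  }))

  conf_names <- intersect(c("age", "sex", "bmi", "fbg", "bun"), config$adjust)
  confounders <- do.call(rbind, lapply(conf_names, function(cf) {
    others <- setdiff(conf_names, cf)
    confounder_check(d$.score, d[[cf]],
                     adjust = covariate_matrix(d, others), name = cf)
  }))
  rownames(confounders) <- NULL
  list(strength = strength, confounders = confounders)
}
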