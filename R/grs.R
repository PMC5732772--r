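#' Weighted genetic risk score
#'
#' Computes the composite instrument: each subject's dosage of the
#' urate-increasing allele at each SNP (0-2), multiplied by that SNP's
#' per-allele effect on serum urate, summed over SNPs. With the shipped
#' four-SNP transporter weights the score is on the umol/L serum-urate scale
#' and ranges from 0 to `2 * sum(weights$weight)`.
#'
#' Subjects with a missing dosage at any SNP receive a missing score
#' (complete-case default) unless `impute_missing = TRUE`, in which case the
#' cohort-mean dosage at that SNP is substituted.
#'
#' @param cohort A `cohort_table` (see [read_cohort()], [simulate_cohort()]).
#' @param weights A `snp_weights` table; every SNP must be a cohort column.
#' @param impute_missing Replace missing dosages with the SNP's mean dosage
#'   instead of dropping the subject's score (default `FALSE`).
#' @return A data frame of class `grs_vector` with columns `subject_id` and
#'   `score` and a `mode` attribute (`"weighted"` or `"count"`).
#' @export
weighted_grs <- function(cohort, weights, impute_missing = FALSE) {
  grs_compute(cohort, weights, weights$weight, "weighted", impute_missing)
}

#' Allele-count genetic risk score
#'
#' The unweighted variant of [weighted_grs()]: the number of urate-increasing
#' alleles carried across the instrument SNPs (0 to `2 * nrow(weights)`).
#' Exposed for sensitivity analysis; the weighted score is the package's
#' default instrument.
#'
#' @inheritParams weighted_grs
#' @return A `grs_vector` data frame; see [weighted_grs()].
#' @export
count_grs <- function(cohort, weights, impute_missing = FALSE) {
  grs_compute(cohort, weights, rep(1, nrow(weights)), "count", impute_missing)
}

grs_compute <- function(cohort, weights, w, mode, impute_missing) {
  if (is.null(weights) || nrow(weights) == 0L) {
    stop("empty weight set: no instrument SNPs")
  }
  absent <- setdiff(weights$snp_id, names(cohort))
  if (length(absent) > 0L) {
    stop("SNP(s) absent from cohort: ", paste(absent, collapse = ", "))
  }
  dos <- as.matrix(as.data.frame(cohort)[weights$snp_id])
  storage.mode(dos) <- "double"
  if (impute_missing) {
    for (j in seq_len(ncol(dos))) {
      miss <- is.na(dos[, j])
      if (any(miss)) dos[miss, j] <- mean(dos[, j], na.rm = TRUE)
    }
  }
  score <- as.numeric(dos %*% w)
  structure(data.frame(subject_id = cohort$subject_id, score = score,
                       stringsAsFactors = FALSE),
            class = c("grs_vector", "data.frame"),
            mode = mode)
}

#' Compute the risk score in a configured mode
#'
#' Dispatcher used by the pipeline: `"weighted"` calls [weighted_grs()],
#' `"count"` calls [count_grs()].
#'
#' @inheritParams weighted_grs
#' @param mode `"weighted"` (default) or `"count"`.
#' @return A `grs_vector` data frame.
#' @export
genetic_risk_score <- function(cohort, weights, mode = c("weighted", "count"),
                               impute_missing = FALSE) {
  mode <- match.arg(mode)
  switch(mode,
         weighted = weighted_grs(cohort, weights, impute_missing),
         count = count_grs(cohort, weights, impute_missing))
}
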