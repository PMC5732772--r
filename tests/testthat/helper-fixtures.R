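# Small in-code fixtures and independent oracles shared across test files.

write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

weights_from_rows <- function(..., orient = TRUE) {
  rows <- c(...)
  read_weights(write_tsv_lines(
    c("snp_id\teffect_allele\tother_allele\tweight", rows)), orient = orient)
}

shipped_weights_path <- function() {
  system.file("extdata", "urate_snp_weights.tsv", package = "uratemr",
              mustWork = TRUE)
}

# minimal phenotype frame with sane covariates for crafted cohorts
mk_pheno <- function(ids, su = 350, tbil = 19, sex = "male", age = 65,
                     bmi = 25, fbg = 5.5, bun = 5.6, drug = 0) {
  data.frame(subject_id = ids, age = age, sex = sex, bmi = bmi, fbg = fbg,
             bun = bun, su = su, tbil = tbil, urate_lowering_drug = drug,
             stringsAsFactors = FALSE)
}

# Moore-Penrose OLS oracle: coefficients via SVD pseudoinverse, classical SEs
pinv_ols <- function(y, X) {
  s <- svd(X)
  coef <- as.numeric(s$v %*% ((t(s$u) %*% y) / s$d))
  res <- y - as.numeric(X %*% coef)
  sigma2 <- sum(res^2) / (length(y) - ncol(X))
  XtX_inv <- s$v %*% diag(1 / s$d^2, length(s$d)) %*% t(s$v)
  list(coef = coef, se = sqrt(sigma2 * diag(XtX_inv)))
}

# Wald-ratio oracle for a single instrument without covariates
wald_ratio <- function(y, x, z) stats::cov(z, y) / stats::cov(z, x)
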