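test_that("identical seeds give bit-identical cohorts", {
  p <- sim_params(n = 200)
  expect_identical(simulate_cohort(p, seed = 9), simulate_cohort(p, seed = 9))
  co_a <- simulate_cohort(p, seed = 9)
  co_b <- simulate_cohort(p, seed = 10)
  expect_false(identical(co_a$su, co_b$su))
})

test_that("default cohort hits the study marginals", {
  p <- sim_params(seed = 73)
  co <- simulate_cohort(p)
  expect_equal(nrow(co), 3753L)
  expect_lt(abs(mean(co$su) - 347.24), 3 * 101.07 / sqrt(3753))
  expect_lt(abs(sd(co$su) / 101.07 - 1), 0.05)
  expect_lt(abs(mean(co$tbil) - 19.25), 3 * 8.21 / sqrt(3753))
  expect_lt(abs(sd(co$tbil) / 8.21 - 1), 0.05)
  expect_lt(abs(mean(co$sex == "male") - 2713 / 3753), 0.03)
  expect_lt(abs(mean(co$age) - 69.43), 3 * 8.96 / sqrt(3753))
  expect_true(all(co$su > 0) && all(co$tbil > 0))
  expect_true(all(c(co$age, co$bmi, co$fbg, co$bun) > 0))
})

test_that("genotypes are at Hardy-Weinberg equilibrium", {
  p <- sim_params(n = 10000, seed = 79)
  co <- simulate_cohort(p)
  for (j in seq_along(p$maf)) {
    f <- p$maf[j]
    obs <- tabulate(co[[p$weights$snp_id[j]]] + 1L, nbins = 3L)
    gof <- chisq.test(obs, p = c((1 - f)^2, 2 * f * (1 - f), f^2))
    expect_gt(gof$p.value, 0.001)
  }
})

test_that("fully exogenous null gives null OLS and TLS and calibrated DWH", {
  p <- sim_params(n = 800, conf_su = 0, beta_causal = 0)
  expect_equal(p$conf_tbil, 0)
  ols <- ts <- rej <- numeric(100)
  for (r in 1:100) {
    co <- simulate_cohort(p, seed = 8000 + r)
    z <- weighted_grs(co, p$weights)$score
    ols[r] <- ols_fit(co$tbil, co$su)$beta
    ts[r] <- tsls_fit(co$tbil, co$su, z)$beta
    rej[r] <- dwh_augmented(co$tbil, co$su, z)$p < 0.05
  }
  expect_lt(abs(mean(ols)), 0.0012)
  expect_lt(abs(mean(ts)), 0.007)
  expect_lt(mean(rej), 0.15)
})

test_that("infeasible variance budgets are refused up front", {
  expect_error(sim_params(conf_su = 101.07), "infeasible serum-urate")
  expect_error(sim_params(grs_r2 = 0.999, conf_su = 30), "infeasible serum-urate")
  expect_error(sim_params(conf_tbil = 50), "infeasible bilirubin")
  expect_error(sim_params(maf = c(0.3, 0.3)), "one minor-allele frequency")
})

test_that("calibration report flags designed weakness", {
  p <- sim_params(n = 100, grs_r2 = 0.001)
  weak <- vapply(1:20, function(r) {
    co <- simulate_cohort(p, seed = 9300 + r)
    z <- weighted_grs(co, p$weights)$score
    first_stage(co$su, z)$weak_instrument
  }, logical(1))
  expect_gt(mean(weak), 0.9)

  cr <- calibration_report(sim_params(n = 600), replicates = 5, seed = 83)
  expect_equal(nrow(cr), 5L)
  s <- attr(cr, "summary")
  expect_true(all(c("f_stat", "tsls_adj", "dwh_p") %in% s$quantity))
  expect_true(all(s$mc_se >= 0))
})

test_that("drug users can be simulated and are excluded downstream", {
  p <- sim_params(n = 500, drug_frac = 0.1, seed = 89)
  co <- simulate_cohort(p)
  n_drug <- sum(co$urate_lowering_drug)
  expect_gt(n_drug, 20)
  res <- run_analysis(co, p$weights, mr_config(min_n = 10))
  expect_equal(attr(res, "exclusions")$n_drug_excluded, n_drug)

  # the io path counts the same exclusions
  df <- as.data.frame(co)
  geno <- df[c("subject_id", p$weights$snp_id)]
  pheno <- df[c("subject_id", "age", "sex", "bmi", "fbg", "bun", "su",
                "tbil", "urate_lowering_drug")]
  co2 <- read_cohort(geno, pheno, p$weights)
  expect_equal(attr(co2, "join_report")$n_drug_excluded, n_drug)
  expect_false(any(co2$urate_lowering_drug))
})
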