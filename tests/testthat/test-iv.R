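# build exposure with an exact fraction of variance explained by z:
# su = z_c + e with e orthogonal to z_c and equal sum of squares -> R2 = 1/2
exact_half_r2 <- function(n, seed) {
  set.seed(seed)
  z <- rnorm(n)
  zc <- z - mean(z)
  e <- residuals(lm(rnorm(n) ~ z))
  e <- e * sqrt(sum(zc^2) / sum(e^2))
  list(z = z, su = 300 + zc + e)
}

test_that("univariate F matches its closed form and the lm oracle", {
  d <- exact_half_r2(12, seed = 31)
  fs <- first_stage(d$su, d$z)
  expect_equal(fs$r2, 0.5, tolerance = 1e-10)
  expect_equal(fs$f_stat, 10, tolerance = 1e-9)  # (0.5/0.5) * (12 - 2)
  expect_equal(fs$weak_instrument, fs$f_stat < 10)  # flag tracks the F value

  set.seed(37)
  for (rep in 1:20) {
    n <- sample(20:100, 1)
    z <- rnorm(n)
    su <- 300 + 3 * z + rnorm(n, 0, 10)
    fs <- first_stage(su, z)
    # exact F-R2 identity
    expect_equal(fs$f_stat, fs$r2 / (1 - fs$r2) * (n - 2), tolerance = 1e-12)
    # and the whole triple against lm's own F
    lmf <- summary(lm(su ~ z))
    expect_equal(fs$f_stat, unname(lmf$fstatistic[1]), tolerance = 1e-9)
    expect_equal(fs$r2, lmf$r.squared, tolerance = 1e-12)
  }
})

test_that("degenerate and weak instruments are flagged", {
  su <- rnorm(50, 300, 50)
  expect_error(first_stage(su, rep(1, 50)), "constant instrument")
  expect_error(first_stage(su, su), "degenerate")

  set.seed(41)
  fvals <- replicate(60, {
    su <- rnorm(200, 300, 50)
    first_stage(su, rnorm(200))$f_stat
  })
  expect_lt(abs(mean(fvals) - 1), 0.5)      # null F has mean ~ 1
  expect_gt(mean(fvals < 10), 0.9)          # essentially always weak
})

test_that("partial F conditions on covariates", {
  set.seed(43)
  n <- 300
  z <- rnorm(n)
  age <- rnorm(n, 65, 9)
  su <- 300 + 4 * z + 2 * age + rnorm(n, 0, 30)
  fs <- first_stage(su, z, covariates = cbind(age = age))
  fit <- summary(lm(su ~ z + age))
  expect_equal(fs$partial_f, unname(fit$coefficients["z", "t value"]^2),
               tolerance = 1e-9)
  expect_equal(fs$f_stat, first_stage(su, z)$f_stat)
})

test_that("2SLS equals the Wald ratio for a single instrument", {
  set.seed(47)
  for (rep in 1:200) {
    n <- sample(15:60, 1)
    z <- rnorm(n)
    x <- 1 + 0.8 * z + rnorm(n)
    y <- 2 - 0.5 * x + rnorm(n)
    fit <- tsls_fit(y, x, z)
    expect_equal(fit$beta, wald_ratio(y, x, z),
                 tolerance = 1e-10)
  }
})

test_that("2SLS collapses to OLS when the instrument is the exposure", {
  set.seed(53)
  n <- 120
  x <- rnorm(n, 300, 60)
  age <- rnorm(n, 65, 9)
  y <- 10 - 0.02 * x + 0.1 * age + rnorm(n, 0, 5)
  # first stage is an exact fit here, so lm warns inside the partial-F step
  ts <- suppressWarnings(tsls_fit(y, x, z = x, covariates = cbind(age = age)))
  ols <- ols_fit(y, x, cbind(age = age))
  expect_equal(ts$beta, ols$beta, tolerance = 1e-10)
  expect_equal(ts$se, ols$se, tolerance = 1e-10)
  expect_equal(ts$p, ols$p, tolerance = 1e-10)
})

test_that("covariate-adjusted 2SLS equals the control-function estimate", {
  set.seed(59)
  n <- 400
  z <- rnorm(n)
  age <- rnorm(n, 65, 9)
  u <- rnorm(n)
  x <- 300 + 5 * z + 1.5 * age + 20 * u + rnorm(n, 0, 40)
  y <- 19 - 0.02 * x + 0.05 * age + 3 * u + rnorm(n, 0, 5)
  covs <- cbind(age = age)
  ts <- tsls_fit(y, x, z, covariates = covs)
  v <- residuals(lm(x ~ z + age))
  cf <- ols_fit(y, x, cbind(covs, v = v))
  expect_equal(ts$beta, cf$beta, tolerance = 1e-9)
})

test_that("2SLS standard errors match the replicate spread at study scale", {
  cr <- calibration_report(sim_params(), replicates = 250, seed = 61)
  expect_lt(abs(sd(cr$tsls_adj) / mean(cr$tsls_adj_se) - 1), 0.10)
})

test_that("2SLS is consistent under confounding while OLS is not", {
  truth <- -0.021
  mean_betas <- function(n, reps, seed) {
    p <- sim_params(n = n)
    ols <- ts <- numeric(reps)
    for (r in seq_len(reps)) {
      co <- simulate_cohort(p, seed = seed + r)
      z <- weighted_grs(co, p$weights)$score
      ols[r] <- ols_fit(co$tbil, co$su)$beta
      ts[r] <- tsls_fit(co$tbil, co$su, z)$beta
    }
    c(ols = mean(ols), tsls = mean(ts))
  }
  small <- mean_betas(500, 40, seed = 6100)
  big <- mean_betas(20000, 10, seed = 6300)
  # OLS stays biased toward the confounded slope at every n
  expect_gt(abs(small["ols"] - truth), 0.015)
  expect_gt(abs(big["ols"] - truth), 0.015)
  # 2SLS homes in on the structural effect
  expect_lt(abs(big["tsls"] - truth), 0.004)
  expect_lt(abs(big["tsls"] - truth), abs(big["ols"] - truth))
})
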