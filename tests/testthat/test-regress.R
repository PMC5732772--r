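test_that("exact and hand-solved fits match the normal equations", {
  x <- 1:10
  fit <- suppressWarnings(ols_fit(3 * x, x))  # lm warns on an exact fit
  expect_equal(fit$beta, 3, tolerance = 1e-10)
  expect_lt(fit$se, 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)

  # frozen from an independent normal-equations solve of the 6-point dataset
  x6 <- c(0, 1, 2, 3, 4, 5)
  y6 <- c(1.1, 1.9, 3.2, 3.8, 5.1, 5.9)
  fit6 <- ols_fit(y6, x6)
  expect_equal(fit6$beta, 0.977142857142857, tolerance = 1e-12)
  expect_equal(fit6$se, 0.039795395078, tolerance = 1e-9)
  expect_equal(fit6$r2, 0.993409206727, tolerance = 1e-9)
  expect_equal(fit6$p, 1.63253785661e-05, tolerance = 1e-6)
  expect_equal(fit6$n, 6L)
  # p is the two-sided t tail at the reported statistic
  expect_equal(fit6$p, 2 * pt(-abs(fit6$stat), fit6$df))
})

test_that("degenerate designs raise errors naming the problem", {
  y <- rnorm(10)
  expect_error(ols_fit(y, rep(1, 10)), "collinear.*exposure")
  x <- rnorm(10)
  expect_error(ols_fit(y, x, cbind(dup = x)), "collinear")
  expect_error(ols_fit(y[1:3], x[1:3], cbind(a = rnorm(3), b = rnorm(3))),
               "too few")
  expect_error(ols_fit(c(y[-1], NA), x), "missing values")
})

test_that("coefficients and SEs agree with a pseudoinverse oracle", {
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(10:50, 1)
    k <- sample(0:5, 1)
    x <- rnorm(n)
    covs <- if (k > 0) matrix(rnorm(n * k), n,
                              dimnames = list(NULL, paste0("c", 1:k)))
            else NULL
    y <- rnorm(n)
    fit <- ols_fit(y, x, covs)
    X <- cbind(1, x, covs)
    oracle <- pinv_ols(y, X)
    expect_equal(fit$beta, oracle$coef[2], tolerance = 1e-10)
    expect_equal(fit$se, oracle$se[2], tolerance = 1e-10)
  }
})

test_that("rescaling the exposure rescales beta and se, leaving p alone", {
  set.seed(11)
  n <- 80
  x <- rnorm(n)
  covs <- cbind(a = rnorm(n))
  y <- 0.5 * x + rnorm(n)
  f1 <- ols_fit(y, x, covs)
  f2 <- ols_fit(y, 10 * x, covs)
  expect_equal(f2$beta, f1$beta / 10, tolerance = 1e-12)
  expect_equal(f2$se, f1$se / 10, tolerance = 1e-12)
  expect_equal(f2$p, f1$p, tolerance = 1e-12)

  # an orthogonal irrelevant covariate leaves the exposure beta unchanged
  ortho <- residuals(lm(rnorm(n) ~ x))
  f3 <- ols_fit(y, x, cbind(ortho = ortho))
  expect_equal(f3$beta, ols_fit(y, x)$beta, tolerance = 1e-8)
})

test_that("confounder check detects identity and rejects constants", {
  set.seed(13)
  score <- rnorm(200, 30, 8)
  res <- suppressWarnings(confounder_check(score, score, adjust = NULL,
                                           name = "self"))
  expect_equal(res$beta[res$model == "crude"], 1, tolerance = 1e-10)
  expect_lt(res$p[res$model == "crude"], 1e-12)
  expect_error(confounder_check(score, rep(2, 200)), "constant confounder")

  # sex handled through the male = 1 linear-probability convention
  sex <- sample(c("male", "female"), 200, TRUE)
  res_sex <- confounder_check(score, sex, adjust = cbind(age = rnorm(200)),
                              name = "sex")
  expect_equal(nrow(res_sex), 2L)
  expect_true(all(res_sex$p >= 0 & res_sex$p <= 1))
})

test_that("confounder check is calibrated under independence", {
  p <- sim_params(seed = 23)
  co <- simulate_cohort(p)
  score <- weighted_grs(co, p$weights)$score
  set.seed(29)
  pvals <- replicate(500, {
    confounder_check(score, rnorm(length(score)))$p[1]
  })
  # independent confounder: uniform p, ~5% below 0.05
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.03)
})
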