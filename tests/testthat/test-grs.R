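test_that("weighted score reproduces hand-computed dosage sums", {
  w <- default_weights()
  ids <- c("A", "B", "C")
  geno <- data.frame(subject_id = ids,
                     rs1481012 = c(2L, 0L, 1L), rs2231137 = c(2L, 0L, 0L),
                     rs16890979 = c(2L, 0L, 0L), rs3799352 = c(2L, 0L, 0L))
  co <- read_cohort(geno, mk_pheno(ids), w)
  s <- weighted_grs(co, w)
  expect_s3_class(s, "grs_vector")
  expect_equal(attr(s, "mode"), "weighted")
  expect_equal(s$score[match(ids, s$subject_id)],
               c(153.220, 0, 27.555), tolerance = 1e-12)
})

test_that("count score sums alleles and matches unit-weight scoring", {
  w <- weights_from_rows("rs1\tA\tG\t10", "rs2\tC\tT\t5",
                         "rs3\tA\tG\t2", "rs4\tC\tT\t1")
  geno <- data.frame(subject_id = c("A", "B"),
                     rs1 = c(2L, 0L), rs2 = c(1L, 0L),
                     rs3 = c(0L, 0L), rs4 = c(1L, 0L))
  co <- read_cohort(geno, mk_pheno(c("A", "B")), w)
  s <- count_grs(co, w)
  expect_equal(s$score[match(c("A", "B"), s$subject_id)], c(4, 0))

  w1 <- weights_from_rows("rs1\tA\tG\t1", "rs2\tC\tT\t1",
                          "rs3\tA\tG\t1", "rs4\tC\tT\t1")
  expect_equal(weighted_grs(co, w1)$score, count_grs(co, w)$score)
  expect_equal(genetic_risk_score(co, w, mode = "count")$score, s$score)
})

test_that("score is monotone in dosage and invariant to SNP order", {
  p <- sim_params(n = 30, seed = 5)
  co <- simulate_cohort(p)
  w <- p$weights
  base <- weighted_grs(co, w)$score
  for (j in seq_len(nrow(w))) {
    snp <- w$snp_id[j]
    i <- which(co[[snp]] < 2L)[1L]
    co2 <- co
    co2[[snp]][i] <- co2[[snp]][i] + 1L
    bumped <- weighted_grs(co2, w)$score
    expect_equal(bumped[i] - base[i], w$weight[j], tolerance = 1e-12)
    expect_equal(bumped[-i], base[-i])
  }
  w_perm <- w[rev(seq_len(nrow(w))), ]
  expect_equal(weighted_grs(co, w_perm)$score, base)
})

test_that("missing dosages give NA scores unless imputation is requested", {
  w <- weights_from_rows("rs1\tA\tG\t10", "rs2\tC\tT\t5")
  geno <- data.frame(subject_id = c("A", "B", "C"),
                     rs1 = c(1L, NA, 2L), rs2 = c(0L, 1L, 2L))
  co <- read_cohort(geno, mk_pheno(c("A", "B", "C")), w)
  s <- weighted_grs(co, w)
  expect_true(is.na(s$score[s$subject_id == "B"]))
  si <- weighted_grs(co, w, impute_missing = TRUE)
  # mean dosage of rs1 over observed subjects is 1.5
  expect_equal(si$score[si$subject_id == "B"], 1.5 * 10 + 1 * 5)
  expect_equal(si$score[si$subject_id != "B"], s$score[s$subject_id != "B"])
})

test_that("simulated HWE cohort matches the expected score mean", {
  p <- sim_params(n = 4000, seed = 17)
  co <- simulate_cohort(p)
  s <- weighted_grs(co, p$weights)$score
  expected_mean <- 2 * sum(p$weights$weight * p$maf)
  expected_sd <- sqrt(sum(p$weights$weight^2 * 2 * p$maf * (1 - p$maf)))
  expect_lt(abs(mean(s) - expected_mean), 4 * expected_sd / sqrt(p$n))
  expect_lt(abs(sd(s) / expected_sd - 1), 0.05)
})

test_that("degenerate weight inputs are rejected", {
  p <- sim_params(n = 20, seed = 1)
  co <- simulate_cohort(p)
  expect_error(weighted_grs(co, p$weights[0, ]), "empty weight")
  w_alien <- weights_from_rows("rs999\tA\tG\t3")
  expect_error(weighted_grs(co, w_alien), "absent from cohort")
})
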