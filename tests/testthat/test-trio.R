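test_that("attenuation reproduces the worked child-coefficient examples", {
  expect_equal(round(attenuation(0.340, 0.223), 1), 34.4)
  expect_equal(round(attenuation(0.129, 0.051), 1), 60.5)
  expect_equal(attenuation(0.25, 0.25), 0)
  expect_error(attenuation(0, 0.1), class = "popconfound_domain_error")
})

test_that("a noiseless phenotype equal to the child score gives unit coefficient and no attenuation", {
  set.seed(111)
  n <- 300
  S <- MASS::mvrnorm(n, rep(0, 3), diag(3))
  d <- tibble::tibble(phenotype = S[, 1], score_child = S[, 1],
                      score_mother = S[, 2], score_father = S[, 3])
  tr <- trio_regression(d, covariates = character(0), n_boot = 0)
  expect_equal(tr$b_child_ind, 1, tolerance = 1e-10)
  expect_equal(tr$attenuation_pct, 0, tolerance = 1e-8)
  # stored attenuation always recomputable from stored coefficients
  expect_equal(tr$attenuation_pct,
               100 * (tr$b_child_ind - tr$b_child_adj) / tr$b_child_ind,
               tolerance = 1e-10)
})

test_that("trio regression guards collinearity and sample size", {
  set.seed(112)
  s <- stats::rnorm(50)
  d <- tibble::tibble(phenotype = stats::rnorm(50), score_child = s,
                      score_mother = s + stats::rnorm(50, sd = 1e-4),
                      score_father = stats::rnorm(50))
  expect_error(trio_regression(d, covariates = character(0), n_boot = 0),
               "collinear")
  d2 <- d[1:5, ]
  d2$score_mother <- stats::rnorm(5)
  expect_error(trio_regression(d2, covariates = character(0), n_boot = 0),
               class = "popconfound_sample_error")
})

test_that("SUR difference test is exact for identical models and calibrated under the null", {
  set.seed(113)
  n <- 400
  d <- tibble::tibble(phenotype = stats::rnorm(n), score_child = stats::rnorm(n),
                      score_mother = stats::rnorm(n), score_father = stats::rnorm(n))
  same <- sur_difference_test(
    dplyr::mutate(d, score_mother = score_child, score_father = score_child),
    covariates = character(0))
  # degenerate duplicated regressors collapse to the same model twice
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)

  ps <- replicate(200, {
    S <- MASS::mvrnorm(500, rep(0, 3), matrix(c(1, .5, .5, .5, 1, 0, .5, 0, 1), 3))
    dd <- tibble::tibble(phenotype = 0.3 * S[, 1] + stats::rnorm(500),
                         score_child = S[, 1], score_mother = S[, 2],
                         score_father = S[, 3])
    sur_difference_test(dd, covariates = character(0))$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  # bootstrap mode agrees in order of magnitude with the analytic mode
  an <- sur_difference_test(d, covariates = character(0))
  bo <- sur_difference_test(d, covariates = character(0), mode = "bootstrap",
                            n_boot = 300, seed = 9)
  expect_lt(abs(an$se - bo$se) / an$se, 0.5)
})

test_that("family bootstrap yields a stable attenuation SE", {
  set.seed(114)
  n <- 1000
  S <- MASS::mvrnorm(n, rep(0, 3), matrix(c(1, .5, .5, .5, 1, 0, .5, 0, 1), 3))
  d <- tibble::tibble(phenotype = 0.4 * S[, 1] + 0.15 * S[, 2] + stats::rnorm(n),
                      score_child = S[, 1], score_mother = S[, 2],
                      score_father = S[, 3])
  t1 <- trio_regression(d, covariates = character(0), n_boot = 1000, seed = 1)
  t2 <- trio_regression(d, covariates = character(0), n_boot = 2000, seed = 2)
  expect_gt(t1$se_attenuation, 0)
  # doubling the replication count moves the SE by well under 5 percent
  expect_lt(abs(t1$se_attenuation - t2$se_attenuation) / t1$se_attenuation, 0.05)
})

test_that("dynastic transmission leaves parental coefficients positive after co-adjustment", {
  coh <- simulate_scenario(preset_config("dynastic", n_founder_couples = 800,
                                         n_snps = 400, n_causal = 200,
                                         offspring_per_couple = 1, seed = 115))
  td <- trio_score_data(coh)
  tr <- trio_regression(td, n_boot = 0)
  expect_gt(tr$b_mother_adj, 0)
  expect_gt(tr$b_father_adj, 0)
  expect_gt(tr$attenuation_pct, 0)
})

test_that("incremental variance explained matches its closed form and extremes", {
  set.seed(116)
  n <- 4000
  score <- stats::rnorm(n)
  noise_cov <- stats::rnorm(n)
  y <- 0.2 * score + stats::rnorm(n)
  d <- tibble::tibble(phenotype = y, score = score, PC1 = noise_cov)
  ve <- variance_explained(d, n_boot = 200, seed = 3)
  expect_lt(abs(ve$incremental_r2 - 0.04 / 1.04), 2 * ve$se)

  d0 <- tibble::tibble(phenotype = stats::rnorm(n), score = stats::rnorm(n),
                       PC1 = noise_cov)
  ve0 <- variance_explained(d0, n_boot = 200, seed = 4)
  expect_lt(abs(ve0$incremental_r2), 2 * max(ve0$se, 1e-4))

  dp <- tibble::tibble(phenotype = y, score = y, PC1 = noise_cov)
  vep <- variance_explained(dp, n_boot = 0)
  base <- summary(stats::lm(phenotype ~ PC1, dp))$r.squared
  expect_equal(vep$incremental_r2, 1 - base, tolerance = 1e-10)
})
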