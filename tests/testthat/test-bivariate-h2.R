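test_that("the bivariate heritability ratio honours its identities", {
  for (h2 in c(0.1, 0.4, 0.9, 1)) {
    expect_equal(bivariate_h2(rg = 1, h2_A = h2, h2_B = h2, r_p = h2), 1)
  }
  expect_equal(bivariate_h2(0, 0.5, 0.7, 0.3), 0)
  expect_error(bivariate_h2(0.5, 0.5, 0.5, 0), class = "popconfound_domain_error")
  expect_error(bivariate_h2(0.5, -0.1, 0.5, 0.3), class = "popconfound_domain_error")
})

test_that("negative environmental confounding pushes the ratio above one", {
  cfg <- preset_config("negative_confounding")
  true_rp <- cfg$rg_true * sqrt(cfg$h2_target * cfg$h2_target_B) +
    cfg$env_corr * sqrt((1 - cfg$h2_target) * (1 - cfg$h2_target_B))
  expect_gt(bivariate_h2(cfg$rg_true, cfg$h2_target, cfg$h2_target_B, true_rp), 1)
})

test_that("Monte-Carlo SE: degenerate, oracle and stability behaviour", {
  z <- mc_standard_error(0.7, 0.5, 0.4, 0.35, 0, 0, 0, 0, n_draws = 1e4)
  expect_identical(z$se, 0)

  expect_error(mc_standard_error(0.7, 0.5, 0.4, 0.35, 0.01, 0.01, 0.01, 0.01,
                                 n_draws = 500))

  # first-order delta-method oracle for small input SEs
  rg <- 0.7; hA <- 0.5; hB <- 0.4; rp <- 0.35
  ses <- c(0.02, 0.02, 0.015, 0.01)
  f <- bivariate_h2(rg, hA, hB, rp)
  grad <- c(sqrt(hA * hB) / rp, f / (2 * hA), f / (2 * hB), -f / rp)
  se_delta <- sqrt(sum((grad * ses)^2))
  mc <- mc_standard_error(rg, hA, hB, rp, ses[1], ses[2], ses[3], ses[4],
                          n_draws = 2e5, seed = 1)
  expect_lt(abs(mc$se - se_delta) / se_delta, 0.10)

  # same seed reproduces exactly; different seeds agree at 1e6 draws
  mc_a <- mc_standard_error(rg, hA, hB, rp, 0.05, 0.05, 0.05, 0.05,
                            n_draws = 1e6, seed = 5)
  mc_b <- mc_standard_error(rg, hA, hB, rp, 0.05, 0.05, 0.05, 0.05,
                            n_draws = 1e6, seed = 5)
  mc_c <- mc_standard_error(rg, hA, hB, rp, 0.05, 0.05, 0.05, 0.05,
                            n_draws = 1e6, seed = 6)
  expect_identical(mc_a$se, mc_b$se)
  expect_lt(abs(mc_a$se - mc_c$se) / mc_a$se, 0.01)
})

test_that("near-zero phenotypic-correlation draws are rejected and counted", {
  mc <- mc_standard_error(0.5, 0.4, 0.4, 0.005, 0.02, 0.02, 0.02, 0.02,
                          n_draws = 5e4, seed = 2)
  expect_gt(mc$rejected_frac, 0)
  expect_lt(mc$rejected_frac, 1)
})

test_that("inflation flags use the stated margins and hedged wording", {
  ok <- flag_inflation(list(h2_ab = 0.85, se_h2_ab = 0.08))
  expect_identical(ok$verdict, "consistent")
  weak <- flag_inflation(list(h2_ab = 1.05, se_h2_ab = 0.10))
  expect_identical(weak$verdict, "exceeds_one_weak")
  strong <- flag_inflation(list(h2_ab = 1.30, se_h2_ab = 0.10))
  expect_identical(strong$verdict, "exceeds_one_strong")
  expect_match(strong$message, "indicator of possible bias")
  expect_no_match(strong$message, "caus")
})

test_that("independence-assumption MC SE is conservative under positive input dependence", {
  # when the inputs are positively dependent the SE of the ratio shrinks;
  # paired simulation with correlated draws versus independent draws
  set.seed(81)
  n <- 2e5
  rho <- 0.6
  z <- MASS::mvrnorm(n, rep(0, 2), matrix(c(1, rho, rho, 1), 2))
  rg_d <- 0.7 + 0.03 * z[, 1]
  rp_d <- 0.35 + 0.02 * z[, 2]       # positively correlated with rg draws
  dep_se <- stats::sd(rg_d * sqrt(0.5 * 0.4) / rp_d)
  ind <- mc_standard_error(0.7, 0.5, 0.4, 0.35, 0.03, 0, 0, 0.02,
                           n_draws = n, seed = 3)
  expect_gte(ind$se, dep_se)
})

test_that("estimate_bivariate_h2 packages a fit's inputs and margin", {
  est <- estimate_bivariate_h2(rg = 0.8, h2_A = 0.5, h2_B = 0.5, r_p = 0.2,
                               se_rg = 0.05, se_h2_A = 0.05, se_h2_B = 0.05,
                               se_rp = 0.02, n_draws = 1e4, seed = 4)
  expect_equal(est$h2_ab, 0.8 * 0.5 / 0.2)
  expect_equal(est$margin, (est$h2_ab - 1) / est$se_h2_ab)
  td <- tidy(est)
  expect_identical(td$term[1], "h2_AB")
})
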