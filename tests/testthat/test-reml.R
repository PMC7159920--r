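test_that("rotated AI-REML matches a dense-likelihood oracle", {
  set.seed(71)
  n <- 80
  dos <- fix_null$cohort$dosages[1:n, ]
  g <- compute_grm(dos)
  ph <- fix_null$phen[1:n, ]
  X <- cbind(1, stats::rnorm(n))
  fit <- reml_univariate(ph$trait_a, X[, 2, drop = FALSE], g)
  ora <- oracle_reml_uni(ph$trait_a, X, g$values)
  expect_equal(fit$sigma2_g, unname(ora["sigma2_g"]), tolerance = 0.02)
  expect_equal(fit$sigma2_e, unname(ora["sigma2_e"]), tolerance = 0.02)
})

test_that("bivariate AI-REML matches the dense oracle on a small fit", {
  # strongly genetically correlated traits at n = 60: the restricted
  # likelihood is nearly flat along rg with its maximum on the boundary,
  # so the meaningful comparison is the maximized log-likelihood itself
  n <- 60
  g <- compute_grm(fix_null$cohort$dosages[1:n, ])
  ph <- fix_null$phen[1:n, ]
  fit <- reml_bivariate(ph$trait_a, ph$trait_b, NULL, g)
  ora <- oracle_reml_biv(ph$trait_a, ph$trait_b, matrix(1, n, 1), g$values)
  expect_gte(fit$loglik, ora[["ll"]] - 0.02)

  # genetically independent trait pair at n = 150: interior optimum, so
  # the parameter estimates themselves must agree with the dense oracle
  n2 <- 150
  g2 <- compute_grm(fix_null$cohort$dosages[1:n2, ])
  ph2 <- fix_null$phen[1:n2, ]
  fit2 <- reml_bivariate(ph2$trait_a, ph2$control, NULL, g2)
  ora2 <- oracle_reml_biv(ph2$trait_a, ph2$control, matrix(1, n2, 1), g2$values)
  expect_gte(fit2$loglik, ora2[["ll"]] - 0.02)
  expect_equal(fit2$sigma2_g_A, unname(ora2["gA"]), tolerance = 0.05)
  expect_equal(fit2$sigma2_g_B, unname(ora2["gB"]), tolerance = 0.05)
  expect_equal(fit2$cov_g, unname(ora2["cg"]), tolerance = 0.05)
})

test_that("null heritability is recovered near zero and truth within 2 SE", {
  g <- fix_null$grm
  ph <- fix_null$phen
  set.seed(73)
  y_null <- stats::rnorm(nrow(ph))
  fit0 <- reml_univariate(y_null, NULL, g)
  expect_lt(fit0$h2, 2 * max(fit0$se_h2, 0.05))

  fit <- reml_univariate(ph$trait_a, NULL, g)
  expect_lt(abs(fit$h2 - 0.6), 2 * fit$se_h2)
  expect_true(fit$converged)
})

test_that("an identity GRM is flagged as non-identifiable", {
  n <- 60
  g <- structure(list(ids = paste0("i", 1:n), values = diag(n),
                      n_snps = matrix(100, n, n)), class = "grm")
  expect_error(reml_univariate(stats::rnorm(n), NULL, g),
               class = "popconfound_identifiability_error")
})

test_that("the restricted log-likelihood ascends and scaling leaves h2 invariant", {
  g <- fix_null$grm
  ph <- fix_null$phen
  fit <- reml_univariate(ph$trait_a, NULL, g)
  expect_true(all(diff(fit$ll_trace) >= -1e-8))

  fit3 <- reml_univariate(3 * ph$trait_a, NULL, g)
  expect_equal(fit3$h2, fit$h2, tolerance = 1e-6)
  expect_equal(fit3$sigma2_g, 9 * fit$sigma2_g, tolerance = 1e-4)

  bfit <- reml_bivariate(ph$trait_a, ph$trait_b, NULL, g)
  expect_true(all(diff(bfit$ll_trace) >= -1e-8))
})

test_that("a duplicated trait yields rg and r_p of one", {
  set.seed(74)
  n <- 120
  g <- compute_grm(fix_null$cohort$dosages[1:n, ])
  y <- fix_null$phen$trait_a[1:n]
  fit <- reml_bivariate(y, y, NULL, g)
  expect_lt(abs(fit$rg - 1), 1e-3)
  expect_equal(fit$r_p, 1)
})

test_that("genetic and environmental correlation are separated", {
  cfg <- sim_config(n_founder_couples = 500, n_snps = 800, n_causal = 400,
                    h2_target = 0.5, h2_target_B = 0.5, rg_true = 0,
                    env_corr = 0.5, seed = 75)
  coh <- simulate_scenario(cfg)
  ph <- cohort_phenotypes(coh, 0)
  g <- grm_with_eigen(compute_grm(coh$dosages))
  fit <- reml_bivariate(ph$trait_a, ph$trait_b, NULL, g)
  expect_lt(abs(fit$rg), 2 * fit$se_rg)
  expect_lt(abs(fit$r_p - 0.25), 0.05)
})

test_that("Haseman-Elston regression agrees with REML and nulls under permutation", {
  g <- fix_null$grm
  ph <- fix_null$phen
  he <- he_regression(ph$trait_a, g)
  fit <- reml_univariate(ph$trait_a, NULL, g)
  expect_lt(abs(he$estimate - fit$h2), 3 * sqrt(he$se^2 + fit$se_h2^2))

  # permutation breaks the phenotype-relatedness link: each permuted
  # estimate is null, so at least 2 of 3 sit within 2 SE of zero
  set.seed(76)
  z <- replicate(3, {
    he0 <- he_regression(sample(ph$trait_a), g)
    abs(he0$estimate) / he0$se
  })
  expect_gte(sum(z < 2), 2)
})

test_that("Haseman-Elston slope equals the hand-computed moment solution", {
  # two-block toy relatedness: 30 sib-like pairs (r = 0.4), unrelated across
  set.seed(77)
  n <- 60
  K <- diag(n)
  for (i in seq(1, n, 2)) K[i, i + 1] <- K[i + 1, i] <- 0.4
  z <- MASS::mvrnorm(1, rep(0, n), K)
  ids <- paste0("i", 1:n)
  g <- structure(list(ids = ids, values = K, n_snps = matrix(1, n, n)),
                 class = "grm")
  he <- he_regression(z, g)
  zc <- (z - mean(z)) / stats::sd(z)
  ut <- upper.tri(K)
  prod <- tcrossprod(zc)[ut]
  k <- K[ut]
  slope_hand <- sum((prod - mean(prod)) * (k - mean(k))) / sum((k - mean(k))^2)
  expect_equal(he$estimate, slope_hand, tolerance = 1e-10)
})

test_that("tidy and glance expose fit results", {
  g <- compute_grm(fix_null$cohort$dosages[1:80, ])
  fit <- reml_univariate(fix_null$phen$trait_a[1:80], NULL, g)
  td <- tidy(fit)
  expect_identical(td$term[1], "h2")
  expect_equal(td$estimate[1], fit$h2)
  gl <- glance(fit)
  expect_identical(gl$nobs, fit$n)
})
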