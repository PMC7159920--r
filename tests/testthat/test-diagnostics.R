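test_that("spousal correlation handles self-pairing, nulls and degenerate input", {
  ids <- paste0("i", 1:20)
  vals <- stats::setNames(stats::rnorm(20), ids)
  self <- tibble::tibble(husband_id = ids, wife_id = ids)
  expect_equal(spousal_correlation(self, vals)$r, 1)

  expect_error(spousal_correlation(self[1:2, ], vals))
  expect_error(spousal_correlation(self, stats::setNames(rep(1, 20), ids)))
})

test_that("the control trait shows no spousal or dynastic signal even under active confounding", {
  coh <- simulate_scenario(preset_config("crp_control", n_founder_couples = 800,
                                         n_snps = 400, n_causal = 200,
                                         offspring_per_couple = 1, seed = 121))
  ph <- coh$phenos
  sp <- spousal_correlation(coh$spouse_pairs, stats::setNames(ph$control, ph$id))
  expect_lt(abs(sp$r), 2 * sp$se)
  # but trait A, which carries the mechanisms, shows both signals
  spa <- spousal_correlation(coh$spouse_pairs, stats::setNames(ph$trait_a, ph$id))
  expect_gt(spa$r, 0.4)

  td <- trio_score_data(coh, weights = cohort_weights(coh, "control"),
                        trait = "control")
  tr <- trio_regression(td, n_boot = 0)
  expect_lt(abs(tr$b_mother_adj), 2.5 * tr$se_mother_adj)
  expect_lt(abs(tr$b_father_adj), 2.5 * tr$se_father_adj)
})

test_that("PC adjustment is idempotent and null without structure", {
  g <- fix_null$grm
  ph <- fix_null$phen
  pcs <- compute_pcs(g, k = 5)
  sc <- stratification_check(ph$trait_a, NULL, g, pcs)
  expect_lt(abs(sc$difference), 2 * sc$joint_se)

  # passing an identical PC set twice changes nothing
  pcm <- pc_matrix(pcs, g$ids)
  sc2 <- stratification_check(ph$trait_a, pcm, g, pcs)
  expect_equal(sc2$estimates$h2[1], sc2$estimates$h2[2], tolerance = 1e-8)
})

test_that("stratification inflates unadjusted heritability and PCs repair it", {
  coh <- simulate_scenario(preset_config("stratification", seed = 122))
  ph <- cohort_phenotypes(coh, 0)
  g <- grm_with_eigen(compute_grm(coh$dosages))
  pcs <- compute_pcs(g, k = 20)
  sc <- stratification_check(inverse_normal_transform(ph$trait_a), NULL, g, pcs)
  expect_gt(sc$estimates$h2[1], sc$estimates$h2[2])
  expect_lt(abs(sc$estimates$h2[2] - 0.4), 2 * sc$estimates$se[2])
})

test_that("irrelevant parental covariates leave heritability unchanged", {
  g <- fix_null$grm
  ph <- fix_null$phen
  set.seed(123)
  noise_par <- cbind(p1 = stats::rnorm(nrow(ph)), p2 = stats::rnorm(nrow(ph)))
  out <- parental_covariate_h2(ph$trait_a, noise_par, NULL, g)
  expect_lt(abs(out$h2[1] - out$h2[2]), 2 * sqrt(sum(out$se^2)))
})

test_that("parental-phenotype adjustment attenuates h2 under dynastic assortative scenarios", {
  coh <- simulate_scenario(preset_config("crp_control", n_founder_couples = 1000,
                                         n_snps = 600, n_causal = 300, seed = 124))
  ph1 <- cohort_phenotypes(coh, 1)
  ph0 <- coh$phenos
  par_mat <- cbind(
    mother = ph0$trait_a[match(ph1$mother_id, ph0$id)],
    father = ph0$trait_a[match(ph1$father_id, ph0$id)])
  g <- grm_with_eigen(compute_grm(coh$dosages[ph1$id, ]))
  out <- parental_covariate_h2(inverse_normal_transform(ph1$trait_a), par_mat, NULL, g)
  expect_lt(out$h2[2], out$h2[1])
})

test_that("the negative-control harness passes clean scenarios and flags injected faults", {
  coh <- simulate_scenario(preset_config("crp_control", n_founder_couples = 600,
                                         n_snps = 400, n_causal = 200,
                                         offspring_per_couple = 1, seed = 125))
  rep_ok <- negative_control_run(coh, n_boot = 100, seed = 1)
  expect_true(all(rep_ok$checks$null_consistent))
  expect_match(rep_ok$verdict, "consistent with no confounding")

  # fault injection: control trait secretly carries the confounded trait
  coh_bad <- coh
  coh_bad$phenos$control <- coh_bad$phenos$trait_a
  rep_bad <- negative_control_run(coh_bad, n_boot = 100, seed = 2)
  expect_false(all(rep_bad$checks$null_consistent))

  # degenerate sample size refuses
  cfg_small <- sim_config(n_founder_couples = 5, n_snps = 50, n_causal = 20,
                          n_generations = 2, offspring_per_couple = 1, seed = 126)
  coh_small <- simulate_scenario(cfg_small)
  expect_error(negative_control_run(coh_small),
               class = "popconfound_sample_error")
})
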