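test_that("random mating yields spousal correlation near zero and disjoint pairs", {
  cfg <- sim_config(n_founder_couples = 800, n_snps = 100, n_causal = 50,
                    h2_target = 0.5, spousal_corr_target = 0, seed = 31)
  coh <- simulate_scenario(cfg)
  coh <- assortative_pairing(coh, generation = 0)
  vals <- stats::setNames(coh$phenos$trait_a, coh$phenos$id)
  sp <- spousal_correlation(coh$spouse_pairs, vals)
  expect_lt(abs(sp$r), 2 / sqrt(sp$n_pairs))
  expect_false(anyDuplicated(c(coh$spouse_pairs$husband_id,
                               coh$spouse_pairs$wife_id)) > 0)
})

test_that("assortment calibrates to the target spousal correlation and induces genetic assortment", {
  cfg <- sim_config(n_founder_couples = 2000, n_snps = 400, n_causal = 200,
                    h2_target = 0.6, spousal_corr_target = 0.56, seed = 32)
  coh <- simulate_scenario(cfg)
  coh <- assortative_pairing(coh, generation = 0)
  ph <- coh$phenos
  sp <- spousal_correlation(coh$spouse_pairs, stats::setNames(ph$trait_a, ph$id))
  expect_gte(sp$r, 0.52)
  expect_lte(sp$r, 0.60)
  # phenotypic sorting induces positive spousal correlation of genetic values
  spg <- spousal_correlation(coh$spouse_pairs, stats::setNames(ph$g_a, ph$id))
  expect_gt(spg$r, 0)
})

test_that("fixed homozygote parents transmit deterministically", {
  cfg <- sim_config(n_founder_couples = 5, n_snps = 6, n_causal = 2, seed = 33)
  dos2 <- matrix(2L, 5, 6)
  dos0 <- matrix(0L, 5, 6)
  coh <- manual_couples_cohort(dos_m = dos2, dos_f = dos0, config = cfg)
  set.seed(1)
  coh <- reproduce(coh, cfg)
  kids <- coh$individuals$id[coh$individuals$generation == 1]
  expect_true(all(coh$dosages[kids, ] == 1L))
  expect_true(all(coh$transmission$trans_m == 1L))
  expect_true(all(coh$transmission$trans_f == 0L))
})

test_that("het x het crosses give the exact Mendelian 1/4:1/2:1/4 distribution", {
  cfg <- sim_config(n_founder_couples = 100, n_snps = 100, n_causal = 10,
                    offspring_per_couple = 1, seed = 34)
  dos1 <- matrix(1L, 100, 100)
  coh <- manual_couples_cohort(dos_m = dos1, dos_f = dos1, config = cfg)
  set.seed(7)
  coh <- reproduce(coh, cfg)
  kids <- coh$individuals$id[coh$individuals$generation == 1]
  d <- as.vector(coh$dosages[kids, ])         # 1e4 child-variant draws
  props <- tabulate(d + 1L, 3) / length(d)
  tol <- 4 * sqrt(0.25 * 0.75 / length(d))    # 4 binomial SEs
  expect_lt(abs(props[1] - 0.25), tol)
  expect_lt(abs(props[2] - 0.50), 2 * tol)
  expect_lt(abs(props[3] - 0.25), tol)
})

test_that("child dosage is exactly transmitted-maternal plus transmitted-paternal", {
  coh <- fix_trio$cohort
  kids <- rownames(coh$transmission$trans_m)
  expect_identical(coh$dosages[kids, ],
                   coh$transmission$trans_m + coh$transmission$trans_f)
  # nontransmitted + transmitted reconstructs each parent's dosage
  info <- coh$individuals[match(kids, coh$individuals$id), ]
  nt_m <- coh$dosages[info$mother_id, ] - coh$transmission$trans_m
  expect_true(all(nt_m >= 0 & nt_m <= 1))
  expect_true(all(coh$transmission$trans_m %in% 0:1))
})

test_that("reproduction requires spouse pairs", {
  cfg <- sim_config(n_founder_couples = 20, n_snps = 30, n_causal = 10, seed = 36)
  coh <- simulate_founders(cfg)
  expect_error(reproduce(coh, cfg), class = "popconfound_state_error")
})
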