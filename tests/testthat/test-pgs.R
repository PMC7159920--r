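test_that("p-value thresholding retains exactly the sub-threshold set", {
  coh <- fix_null$cohort
  w <- cohort_weights(coh, "a")
  pg <- build_pgs(coh$dosages, coh$variant_table, w, p_threshold = 5e-8)
  log <- attr(pg, "retention")
  expect_setequal(log$variant_id[log$status == "retained"],
                  w$variant_id[w$p_value <= 5e-8])
  # placeholder p-values mark exactly the causal set
  expect_setequal(log$variant_id[log$status == "retained"],
                  coh$effects$variant_id[coh$effects$causal])
})

test_that("clumping keeps the smaller p-value of a perfect-LD pair", {
  n <- 200
  set.seed(91)
  x <- stats::rbinom(n, 2, 0.4)
  dos <- cbind(snpA = x, snpB = x, snpC = stats::rbinom(n, 2, 0.4))
  rownames(dos) <- paste0("i", 1:n)
  vt <- tibble::tibble(variant_id = c("snpA", "snpB", "snpC"),
                       chrom = 1L, pos = c(1e5, 1.5e5, 9e6),
                       effect_allele = "A", other_allele = "G")
  w <- tibble::tibble(variant_id = c("snpA", "snpB", "snpC"),
                      effect_allele = "A", weight = c(0.2, 0.3, 0.1),
                      p_value = c(1e-9, 1e-8, 1e-8))
  pg <- build_pgs(dos, vt, w)
  log <- attr(pg, "retention")
  expect_identical(log$status[log$variant_id == "snpA"], "retained")
  expect_identical(log$status[log$variant_id == "snpB"], "clumped")
  expect_identical(log$status[log$variant_id == "snpC"], "retained")
})

test_that("weight harmonization flips mismatched alleles and drops ambiguous ones", {
  n <- 150
  set.seed(92)
  dos <- cbind(s1 = stats::rbinom(n, 2, 0.3), s2 = stats::rbinom(n, 2, 0.3),
               s3 = stats::rbinom(n, 2, 0.3))
  rownames(dos) <- paste0("i", 1:n)
  vt <- tibble::tibble(variant_id = c("s1", "s2", "s3"), chrom = 1L,
                       pos = c(1e6, 2e6, 3e6),
                       effect_allele = c("A", "C", "A"),
                       other_allele = c("G", "T", "T"))
  w <- tibble::tibble(variant_id = c("s1", "s2", "s3"),
                      effect_allele = c("G", "C", "A"),   # s1 needs a flip
                      weight = c(0.5, 0.2, 0.9), p_value = rep(1e-10, 3))
  pg <- build_pgs(dos, vt, w, clump_kb = 0, standardize = FALSE)
  log <- attr(pg, "retention")
  expect_identical(log$status[log$variant_id == "s3"], "strand_ambiguous")
  expect_equal(log$weight[log$variant_id == "s1"], -0.5)
  expect_equal(pg$score, unname(drop(dos[, 1:2] %*% c(-0.5, 0.2))))
})

test_that("degenerate weight sets are refused", {
  coh <- fix_null$cohort
  w <- cohort_weights(coh, "a")
  w0 <- dplyr::mutate(w, weight = 0)
  expect_error(build_pgs(coh$dosages, coh$variant_table, w0),
               class = "popconfound_pgs_error")
  wdup <- dplyr::bind_rows(w, w[1, ])
  expect_error(build_pgs(coh$dosages, coh$variant_table, wdup),
               class = "popconfound_pgs_error")
  whi <- dplyr::mutate(w, p_value = 1)
  expect_error(build_pgs(coh$dosages, coh$variant_table, whi),
               class = "popconfound_pgs_error")
})

test_that("transmitted plus nontransmitted scores reconstruct each parent's score", {
  coh <- fix_trio$cohort
  w <- cohort_weights(coh, "a")
  ns <- nontransmitted_score(coh, w, standardize = FALSE)
  pg <- build_pgs(coh$dosages, coh$variant_table, w, standardize = FALSE)
  parent_score <- stats::setNames(pg$score, pg$id)
  info <- coh$individuals[match(ns$child_id, coh$individuals$id), ]
  expect_equal(unname(ns$t_score_mother + ns$nt_score_mother),
               unname(parent_score[info$mother_id]), tolerance = 1e-10)
  expect_equal(unname(ns$t_score_father + ns$nt_score_father),
               unname(parent_score[info$father_id]), tolerance = 1e-10)
})

test_that("nontransmitted scores are null without dynastic effects and detect kappa > 0", {
  # null: the trio fixture has kappa = 0
  coh <- fix_trio$cohort
  ns <- nontransmitted_score(coh, cohort_weights(coh, "a"))
  ph <- cohort_phenotypes(coh, 1)
  y <- ph$trait_a[match(ns$child_id, ph$id)]
  cf <- summary(stats::lm(y ~ ns$nt_score))$coefficients
  expect_lt(abs(cf[2, 1]), 2.5 * cf[2, 2])

  # dynastic transmission through parental genetic values is detected
  cfg <- sim_config(n_founder_couples = 1000, n_snps = 400, n_causal = 200,
                    h2_target = 0.6, dynastic_kappa_m = 0.3, dynastic_kappa_f = 0.3,
                    dynastic_mode = "parental_genetic_value",
                    n_generations = 2, offspring_per_couple = 1, seed = 93)
  cohk <- simulate_scenario(cfg)
  nsk <- nontransmitted_score(cohk, cohort_weights(cohk, "a"))
  phk <- cohort_phenotypes(cohk, 1)
  yk <- phk$trait_a[match(nsk$child_id, phk$id)]
  cfk <- summary(stats::lm(yk ~ nsk$nt_score))$coefficients
  expect_gt(cfk[2, 1] / cfk[2, 2], 2)
})
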