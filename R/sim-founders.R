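#' Simulate the founder generation
#'
#' Draws founder genotypes under a Balding-Nichols model: each variant has
#' an ancestral frequency uniform on `maf_range`, and each subpopulation's
#' frequency is drawn from a Beta distribution with mean equal to the
#' ancestral frequency and variance `fst * p * (1 - p)`. With `fst = 0`
#' subpopulation frequencies equal the ancestral frequencies exactly.
#' Dosages are binomial(2, subpopulation frequency) per individual;
#' variants are unlinked unless `ld_block_size > 1`, in which case alleles
#' within a block are drawn through a Gaussian copula with latent
#' correlation `ld_rho`.
#'
#' Founders are split into equal-sized subpopulations with balanced sexes;
#' this call seeds the simulation's single random stream from
#' `config$seed`, so repeated calls are byte-identical.
#'
#' @param config A [sim_config()].
#' @return A `cohort` object: generation-0 individuals with no parents,
#'   empty spouse pairs, and no phenotypes yet.
#' @export
simulate_founders <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)

  n_ind <- 2L * config$n_founder_couples
  m <- config$n_snps
  p_anc <- stats::runif(m, config$maf_range[1], config$maf_range[2])

  # Balding-Nichols subpopulation frequencies
  freq <- matrix(p_anc, nrow = m, ncol = config$n_subpops)
  if (config$fst > 0 && config$n_subpops > 1) {
    a <- p_anc * (1 - config$fst) / config$fst
    b <- (1 - p_anc) * (1 - config$fst) / config$fst
    for (s in seq_len(config$n_subpops)) {
      freq[, s] <- stats::rbeta(m, a, b)
    }
    # guard against numerically fixed variants
    freq <- pmin(pmax(freq, 1e-4), 1 - 1e-4)
  }

  subpop <- rep(seq_len(config$n_subpops), length.out = n_ind)
  subpop <- sort(subpop)
  # balanced sexes within subpopulation
  sex <- unlist(lapply(split(seq_along(subpop), subpop), function(idx) {
    rep(c("M", "F"), length.out = length(idx))
  }), use.names = FALSE)

  dos <- matrix(0L, nrow = n_ind, ncol = m)
  if (config$ld_block_size <= 1L || config$ld_rho == 0) {
    for (s in seq_len(config$n_subpops)) {
      rows <- which(subpop == s)
      dos[rows, ] <- matrix(
        stats::rbinom(length(rows) * m, 2L, rep(freq[, s], each = length(rows))),
        nrow = length(rows)
      )
    }
  } else {
    dos <- draw_ld_dosages(freq, subpop, config$ld_block_size, config$ld_rho)
  }

  ids <- sprintf("g0_i%05d", seq_len(n_ind))
  rownames(dos) <- ids
  vids <- sprintf("snp%05d", seq_len(m))
  colnames(dos) <- vids

  alleles <- cbind(sample(c("A", "C"), m, replace = TRUE), NA)
  alleles[, 2] <- ifelse(alleles[, 1] == "A", "G", "T")  # never strand-ambiguous
  variant_table <- tibble::tibble(
    variant_id = vids,
    chrom = 1L + (seq_len(m) - 1L) %/% 1000L,
    pos = 1e4 * (1L + (seq_len(m) - 1L) %% 1000L),
    effect_allele = alleles[, 1],
    other_allele = alleles[, 2],
    founder_freq = p_anc
  )
  for (s in seq_len(config$n_subpops)) {
    variant_table[[paste0("freq_pop", s)]] <- freq[, s]
  }

  individuals <- tibble::tibble(
    id = ids,
    sex = sex,
    generation = 0L,
    subpop = subpop,
    mother_id = NA_character_,
    father_id = NA_character_
  )

  new_cohort(
    dosages = dos,
    variant_table = variant_table,
    individuals = individuals,
    spouse_pairs = tibble::tibble(husband_id = character(), wife_id = character(),
                                  generation = integer()),
    phenos = NULL,
    transmission = NULL,
    config = config
  )
}

# Gaussian-copula block-correlated haplotype draw. Two latent haplotype
# vectors per individual per block; allele present when the latent normal
# falls below qnorm(freq).
draw_ld_dosages <- function(freq, subpop, block_size, rho) {
  m <- nrow(freq)
  n <- length(subpop)
  dos <- matrix(0L, n, m)
  blocks <- split(seq_len(m), (seq_len(m) - 1L) %/% block_size)
  for (idx in blocks) {
    k <- length(idx)
    L <- chol(rho + diag(1 - rho, k))
    for (hap in 1:2) {
      z <- matrix(stats::rnorm(n * k), n, k) %*% L
      thr <- stats::qnorm(t(freq[idx, subpop, drop = FALSE]))
      dos[, idx] <- dos[, idx] + (z < thr)
    }
  }
  storage.mode(dos) <- "integer"
  dos
}

#' Draw per-variant additive effects for the simulated traits
#'
#' Causal variants (a random subset of size `n_causal`) receive effects on
#' the standardized-genotype scale for traits A and B, drawn jointly with
#' correlation `rg_true` and rescaled so the founder-generation genetic
#' variance equals `h2_target` (`h2_target_B`) exactly under
#' Hardy-Weinberg at the ancestral frequencies. The negative-control trait
#' gets its own independent effect set scaled to `h2_control`. Non-causal
#' variants have zero effect. Placeholder discovery p-values are attached:
#' genome-wide-significant (1e-10) for causal variants, uniform on
#' (0.05, 1) for the rest, so p-value thresholding in score construction
#' recovers the causal set.
#'
#' @param config A [sim_config()].
#' @return A tibble (`effect_set`): `variant_id`, `causal`, `beta_a`,
#'   `beta_b`, `beta_control`, `p_value`.
#' @export
draw_effects <- function(config) {
  validate_sim_config(config)
  m <- config$n_snps
  nc <- config$n_causal
  causal_idx <- sort(sample.int(m, nc))

  beta_a <- beta_b <- beta_ctl <- numeric(m)
  if (nc > 0) {
    if (abs(config$rg_true) == 1 || nc < 3) {
      z <- stats::rnorm(nc)
      raw <- cbind(z, sign(config$rg_true) * z)
      if (abs(config$rg_true) != 1) raw[, 2] <- stats::rnorm(nc)
    } else {
      # empirical = TRUE pins the sample correlation of the effect vectors
      # at rg_true exactly, so the realized genetic correlation is the
      # configured one rather than a draw around it
      raw <- MASS::mvrnorm(nc, mu = c(0, 0),
                           Sigma = matrix(c(1, config$rg_true, config$rg_true, 1), 2),
                           empirical = TRUE)
    }
    beta_a[causal_idx] <- scale_to_var(raw[, 1], config$h2_target)
    beta_b[causal_idx] <- scale_to_var(raw[, 2], config$h2_target_B)
    beta_ctl[causal_idx] <- scale_to_var(stats::rnorm(nc), config$h2_control)
  }

  p_value <- stats::runif(m, 0.05, 1)
  p_value[causal_idx] <- 1e-10

  tibble::tibble(
    variant_id = sprintf("snp%05d", seq_len(m)),
    causal = seq_len(m) %in% causal_idx,
    beta_a = beta_a,
    beta_b = beta_b,
    beta_control = beta_ctl,
    p_value = p_value
  )
}

# rescale a raw effect vector so its sum of squares (the genetic variance
# contributed by standardized genotypes) equals exactly v
scale_to_var <- function(raw, v) {
  if (v == 0) return(numeric(length(raw)))
  raw * sqrt(v / sum(raw^2))
}

new_cohort <- function(dosages, variant_table, individuals, spouse_pairs,
                       phenos, transmission, config, effects = NULL) {
  structure(
    list(
      dosages = dosages,
      variant_table = variant_table,
      individuals = individuals,
      spouse_pairs = spouse_pairs,
      phenos = phenos,
      transmission = transmission,
      config = config,
      effects = effects
    ),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  gens <- table(x$individuals$generation)
  cat("<cohort> ", nrow(x$individuals), " individuals, ",
      ncol(x$dosages), " variants\n", sep = "")
  cat("  generations:", paste(sprintf("g%s=%d", names(gens), gens), collapse = ", "), "\n")
  cat("  spouse pairs:", nrow(x$spouse_pairs),
      " | phenotypes:", if (is.null(x$phenos)) "none" else nrow(x$phenos), "\n")
  invisible(x)
}

#' Ids of the individuals in one generation
#' @param cohort A `cohort`.
#' @param generation Generation index (founders are 0).
#' @return Character vector of individual ids.
#' @export
cohort_generation_ids <- function(cohort, generation) {
  cohort$individuals$id[cohort$individuals$generation == generation]
}
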