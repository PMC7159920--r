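#' Pair spouses within a generation, optionally assorting on phenotype
#'
#' Males and females of the target generation are each ranked on
#' `trait_a + u`, where `u` is independent Gaussian noise, and matched by
#' rank within their mating pool (by default the subpopulation;
#' `cross_subpop_mating` moves a fraction of individuals into a pooled
#' cross-subpopulation market). The noise variance is calibrated by
#' numerical search - bisection on a multiplier of the analytic value
#' `var(y) * (1 - rho) / rho`, evaluating realized correlations on
#' averaged trial matchings - until the realized spousal phenotypic
#' correlation is within 0.02 of `spousal_corr_target`. A target of zero
#' skips scoring entirely and pairs uniformly at random.
#'
#' @param cohort A `cohort` with phenotypes for the target generation.
#' @param config A [sim_config()] (defaults to the cohort's).
#' @param generation Generation to pair; default the latest.
#' @return The cohort with the new spouse pairs appended to
#'   `$spouse_pairs`.
#' @export
assortative_pairing <- function(cohort, config = cohort$config,
                                generation = max(cohort$individuals$generation)) {
  rho <- config$spousal_corr_target
  if (rho >= 1) {
    stop(errorCondition("spousal_corr_target must be < 1",
                        class = c("popconfound_config_error", "error")))
  }
  info <- cohort$individuals[cohort$individuals$generation == generation, ]
  if (!any(info$sex == "M") || !any(info$sex == "F")) {
    stop("need at least one male and one female in the generation to pair")
  }
  ph <- cohort$phenos
  y <- stats::setNames(ph$trait_a[match(info$id, ph$id)], info$id)
  if (anyNA(y)) stop("phenotypes must be computed before pairing")

  pool <- info$subpop
  if (config$cross_subpop_mating > 0 && config$n_subpops > 1) {
    mix <- stats::runif(nrow(info)) < config$cross_subpop_mating
    pool[mix] <- 0L
  }

  pairs <- purrr::map_dfr(split(seq_len(nrow(info)), pool), function(rows) {
    males <- info$id[rows][info$sex[rows] == "M"]
    females <- info$id[rows][info$sex[rows] == "F"]
    k <- min(length(males), length(females))
    if (k == 0) return(NULL)
    males <- males[seq_len(k)]
    females <- females[seq_len(k)]
    if (rho == 0) {
      tibble::tibble(husband_id = sample(males), wife_id = sample(females))
    } else {
      var_u <- calibrate_pair_noise(y[males], y[females], rho)
      h <- males[order(y[males] + stats::rnorm(k, sd = sqrt(var_u)))]
      w <- females[order(y[females] + stats::rnorm(k, sd = sqrt(var_u)))]
      tibble::tibble(husband_id = h, wife_id = w)
    }
  })
  pairs$generation <- generation
  stopifnot(!anyDuplicated(c(pairs$husband_id, pairs$wife_id)))
  cohort$spouse_pairs <- dplyr::bind_rows(cohort$spouse_pairs, pairs)
  cohort
}

# bisection on a multiplier of the analytic noise variance; each candidate
# evaluated as the mean realized correlation over a few trial matchings
calibrate_pair_noise <- function(ym, yf, rho, tol = 0.02, n_trial = 3L) {
  vy <- stats::var(c(ym, yf))
  base <- vy * (1 - rho) / rho
  realized <- function(mult) {
    vu <- base * mult
    mean(vapply(seq_len(n_trial), function(i) {
      h <- order(ym + stats::rnorm(length(ym), sd = sqrt(vu)))
      w <- order(yf + stats::rnorm(length(yf), sd = sqrt(vu)))
      stats::cor(ym[h], yf[w])
    }, numeric(1)))
  }
  lo <- 0.1; hi <- 10; mult <- 1
  for (iter in 1:12) {
    r <- realized(mult)
    if (abs(r - rho) <= tol) break
    if (r > rho) lo <- mult else hi <- mult  # more noise lowers correlation
    mult <- sqrt(lo * hi)
  }
  base * mult
}

#' Produce the next generation by Mendelian transmission
#'
#' Each spouse pair of the latest paired generation produces
#' `offspring_per_couple` children. At every variant each parent transmits
#' one of its two alleles with probability 1/2, independently across
#' variants (variants are unlinked), and the transmitted allele count per
#' parent is recorded so nontransmitted-allele scores can be formed later.
#' Offspring inherit the mother's subpopulation label; sexes alternate
#' within a sibship.
#'
#' @param cohort A `cohort` with spouse pairs for its latest generation.
#' @param config A [sim_config()] (defaults to the cohort's).
#' @return The cohort with the new generation appended (phenotypes not yet
#'   computed).
#' @export
reproduce <- function(cohort, config = cohort$config) {
  gen <- max(cohort$individuals$generation)
  pairs <- cohort$spouse_pairs[cohort$spouse_pairs$generation == gen, ]
  if (nrow(pairs) == 0) {
    stop(errorCondition("no spouse pairs for the current generation; run assortative_pairing() first",
                        class = c("popconfound_state_error", "error")))
  }
  m <- ncol(cohort$dosages)
  opc <- config$offspring_per_couple
  n_child <- nrow(pairs) * opc
  child_gen <- gen + 1L

  dos_f <- cohort$dosages[pairs$husband_id, , drop = FALSE]
  dos_m <- cohort$dosages[pairs$wife_id, , drop = FALSE]

  trans_m <- matrix(0L, n_child, m)
  trans_f <- matrix(0L, n_child, m)
  for (j in seq_len(opc)) {
    rows <- seq.int(from = j, by = opc, length.out = nrow(pairs))
    trans_m[rows, ] <- transmit(dos_m)
    trans_f[rows, ] <- transmit(dos_f)
  }

  child_ids <- sprintf("g%d_i%05d", child_gen, seq_len(n_child))
  child_dos <- trans_m + trans_f
  rownames(child_dos) <- child_ids
  colnames(child_dos) <- colnames(cohort$dosages)
  rownames(trans_m) <- rownames(trans_f) <- child_ids
  colnames(trans_m) <- colnames(trans_f) <- colnames(cohort$dosages)

  mums <- rep(pairs$wife_id, each = opc)
  dads <- rep(pairs$husband_id, each = opc)
  kids <- tibble::tibble(
    id = child_ids,
    sex = rep_len(c("M", "F"), n_child),
    generation = child_gen,
    subpop = cohort$individuals$subpop[match(mums, cohort$individuals$id)],
    mother_id = mums,
    father_id = dads
  )

  cohort$dosages <- rbind(cohort$dosages, child_dos)
  cohort$individuals <- dplyr::bind_rows(cohort$individuals, kids)
  cohort$transmission <- list(
    trans_m = rbind(cohort$transmission$trans_m, trans_m),
    trans_f = rbind(cohort$transmission$trans_f, trans_f)
  )
  cohort
}

# one transmitted allele per parent per variant: dosage 0 -> 0, 2 -> 1,
# 1 -> fair coin
transmit <- function(dos) {
  het <- dos == 1L
  t <- (dos == 2L) + 0L
  t[het] <- stats::rbinom(sum(het), 1L, 0.5)
  storage.mode(t) <- "integer"
  t
}
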