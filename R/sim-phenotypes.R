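#' Compute phenotypes for every generation that lacks them
#'
#' Builds, generation by generation, the phenotype model
#' `y = g + subpop_shift + dynastic + e`:
#'
#' * `g` is the additive genetic value, `sum(beta * w)` over standardized
#'   dosages, where standardization always uses the founder (ancestral)
#'   allele frequencies so the variant-substitution scale stays fixed
#'   across generations.
#' * the subpopulation shift applies to traits A and B only;
#' * the dynastic component, zero for founders, is
#'   `kappa_m * mediator(mother) + kappa_f * mediator(father)` with the
#'   mediator (parental phenotype or parental genetic value, per
#'   `dynastic_mode`) standardized by its SD in the parental generation;
#' * residuals of traits A and B are bivariate normal with correlation
#'   `env_corr` and variances `1 - h2`, so founder phenotypes have unit
#'   variance; later generations are deliberately left unscaled so any
#'   variance inflation from assortment or dynastic transmission remains
#'   measurable.
#'
#' The negative-control trait has its own independent effect set and
#' residual, and never receives a dynastic term or subpopulation shift.
#'
#' @param cohort A `cohort`.
#' @param effects Effect tibble from [draw_effects()] (defaults to the one
#'   stored in the cohort).
#' @param config A [sim_config()] (defaults to the cohort's).
#' @return The cohort with `phenos` filled for all generations.
#' @export
make_phenotypes <- function(cohort, effects = cohort$effects, config = cohort$config) {
  if (is.null(effects)) stop("no effect set: call draw_effects() first")
  if (abs(config$env_corr) > 1) {
    stop(errorCondition("env_corr must lie in [-1, 1]",
                        class = c("popconfound_config_error", "error")))
  }
  gens <- sort(unique(cohort$individuals$generation))
  done <- if (is.null(cohort$phenos)) integer() else unique(cohort$phenos$generation)
  effects <- calibrate_effects(cohort, effects, config)
  g_all <- genetic_values(cohort, effects)

  for (gen in setdiff(gens, done)) {
    ids <- cohort_generation_ids(cohort, gen)
    idx <- match(ids, rownames(cohort$dosages))
    n <- length(ids)
    info <- cohort$individuals[match(ids, cohort$individuals$id), ]

    if (gen == 0L && n >= 10) {
      # founder generation defines the phenotype scale: residuals are
      # orthogonalized to the genetic values and given their exact target
      # covariance, so variance fractions hold exactly, not in expectation
      G <- cbind(g_all$a[idx], g_all$b[idx], g_all$ctl[idx])
      e_ab <- founder_resid_pair(n, 1 - config$h2_target, 1 - config$h2_target_B,
                                 config$env_corr, G)
      e_ctl <- founder_resid_one(n, 1 - config$h2_control, G)
    } else {
      e_ab <- draw_resid_pair(n, 1 - config$h2_target, 1 - config$h2_target_B,
                              config$env_corr)
      e_ctl <- stats::rnorm(n, sd = sqrt(max(1 - config$h2_control, 0)))
    }

    shift <- if (config$n_subpops > 1 || any(config$subpop_shift != 0)) {
      config$subpop_shift[info$subpop]
    } else {
      numeric(n)
    }

    dyn <- dynastic_component(cohort, g_all, info, config)

    ph <- tibble::tibble(
      id = ids,
      generation = gen,
      g_a = g_all$a[idx],
      g_b = g_all$b[idx],
      g_control = g_all$ctl[idx],
      e_a = e_ab[, 1],
      e_b = e_ab[, 2],
      e_control = e_ctl,
      dynastic_a = dyn$a,
      dynastic_b = dyn$b
    )
    ph$trait_a <- ph$g_a + shift + ph$dynastic_a + ph$e_a
    ph$trait_b <- ph$g_b + shift + ph$dynastic_b + ph$e_b
    ph$control <- ph$g_control + ph$e_control
    cohort$phenos <- dplyr::bind_rows(cohort$phenos, ph)
  }
  cohort$effects <- effects
  cohort
}

genetic_values <- function(cohort, effects) {
  p <- cohort$variant_table$founder_freq
  sdv <- sqrt(2 * p * (1 - p))
  # W = (X - 2p) / sd; g = W beta computed without materializing W
  gv <- function(beta) {
    b <- beta / sdv
    unname(drop(cohort$dosages %*% b)) - sum(2 * p * b)
  }
  list(a = gv(effects$beta_a), b = gv(effects$beta_b), ctl = gv(effects$beta_control))
}

# rescale effect vectors so the realized founder-generation genetic
# variance equals the configured target exactly (the invariant is stated
# at the founder generation, not in expectation); idempotent via attribute
calibrate_effects <- function(cohort, effects, config) {
  if (isTRUE(attr(effects, "calibrated"))) return(effects)
  f_ids <- cohort_generation_ids(cohort, 0L)
  if (length(f_ids) < 10) {
    attr(effects, "calibrated") <- TRUE
    return(effects)
  }
  g <- genetic_values(cohort, effects)
  idx <- match(f_ids, rownames(cohort$dosages))
  targets <- c(beta_a = config$h2_target, beta_b = config$h2_target_B,
               beta_control = config$h2_control)
  comp <- c(beta_a = "a", beta_b = "b", beta_control = "ctl")
  for (col in names(targets)) {
    v <- stats::var(g[[comp[[col]]]][idx])
    if (v > 0 && targets[[col]] > 0) {
      effects[[col]] <- effects[[col]] * sqrt(targets[[col]] / v)
    }
  }
  attr(effects, "calibrated") <- TRUE
  effects
}

# founder residual pair: orthogonal to the genetic values, sample
# covariance exactly the target
founder_resid_pair <- function(n, va, vb, rho, G) {
  va <- max(va, 0); vb <- max(vb, 0)
  if (va == 0 && vb == 0) return(cbind(numeric(n), numeric(n)))
  E <- cbind(stats::rnorm(n), stats::rnorm(n))
  E <- ortho_resid(E, G)
  if (va == 0 || vb == 0 || abs(rho) >= 1 - 1e-12) {
    e1 <- if (va > 0) E[, 1] / stats::sd(E[, 1]) * sqrt(va) else numeric(n)
    e2 <- if (vb == 0) numeric(n)
      else if (abs(rho) >= 1 - 1e-12 && va > 0) sign(rho) * e1 * sqrt(vb / va)
      else E[, 2] / stats::sd(E[, 2]) * sqrt(vb)
    return(cbind(e1, e2))
  }
  target <- matrix(c(va, rho * sqrt(va * vb), rho * sqrt(va * vb), vb), 2)
  E %*% backsolve(chol(stats::cov(E)), diag(2)) %*% chol(target)
}

founder_resid_one <- function(n, v, G) {
  if (v <= 0) return(numeric(n))
  e <- drop(ortho_resid(cbind(stats::rnorm(n), 0), G)[, 1])
  e / stats::sd(e) * sqrt(v)
}

ortho_resid <- function(E, G) {
  keep <- apply(G, 2, stats::sd) > 0
  Q <- cbind(1, G[, keep, drop = FALSE])
  stats::lm.fit(Q, E)$residuals
}

draw_resid_pair <- function(n, va, vb, rho) {
  va <- max(va, 0); vb <- max(vb, 0)
  if (va == 0 || vb == 0) {
    return(cbind(stats::rnorm(n, sd = sqrt(va)), stats::rnorm(n, sd = sqrt(vb))))
  }
  Sigma <- matrix(c(va, rho * sqrt(va * vb), rho * sqrt(va * vb), vb), 2)
  MASS::mvrnorm(n, mu = c(0, 0), Sigma = Sigma)
}

# kappa_m * standardized maternal mediator + kappa_f * paternal; zero for
# founders (and exactly zero when both kappas are zero, skipping lookups)
dynastic_component <- function(cohort, g_all, info, config) {
  n <- nrow(info)
  zero <- list(a = numeric(n), b = numeric(n))
  if ((config$dynastic_kappa_m == 0 && config$dynastic_kappa_f == 0) ||
      all(is.na(info$mother_id))) {
    return(zero)
  }
  parent_gen <- unique(info$generation) - 1L
  par_ids <- cohort_generation_ids(cohort, parent_gen)

  mediator <- function(trait) {
    if (config$dynastic_mode == "parental_phenotype") {
      ph <- cohort$phenos
      if (is.null(ph) || !all(par_ids %in% ph$id)) {
        stop("parental phenotypes must be computed before offspring phenotypes")
      }
      med <- ph[[trait]][match(par_ids, ph$id)]
    } else {
      key <- c(trait_a = "a", trait_b = "b")[[trait]]
      med <- g_all[[key]][match(par_ids, rownames(cohort$dosages))]
    }
    med <- (med - mean(med)) / stats::sd(med)
    stats::setNames(med, par_ids)
  }

  out <- zero
  for (tr in c("a", "b")) {
    med <- mediator(paste0("trait_", tr))
    out[[tr]] <- config$dynastic_kappa_m * med[info$mother_id] +
      config$dynastic_kappa_f * med[info$father_id]
    out[[tr]] <- unname(out[[tr]])
  }
  out
}
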