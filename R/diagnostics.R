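#' Spousal correlation
#'
#' Product-moment correlation of a per-individual value across spouse
#' pairs, with the normal-theory standard error
#' `sqrt((1 - r^2) / (n - 2))`. Works identically for phenotypes and
#' polygenic scores.
#'
#' @param pairs Tibble with `husband_id`, `wife_id` (e.g.
#'   `cohort$spouse_pairs`).
#' @param values Named numeric vector, one value per individual id.
#' @return Tibble `r`, `se`, `n_pairs`.
#' @export
spousal_correlation <- function(pairs, values) {
  vh <- values[pairs$husband_id]
  vw <- values[pairs$wife_id]
  ok <- !is.na(vh) & !is.na(vw)
  vh <- vh[ok]; vw <- vw[ok]
  if (length(vh) < 3) stop("need at least 3 complete spouse pairs")
  if (stats::sd(vh) == 0 || stats::sd(vw) == 0) {
    stop("zero variance in one margin; correlation undefined")
  }
  r <- stats::cor(vh, vw)
  tibble::tibble(r = r, se = sqrt((1 - r^2) / (length(vh) - 2)),
                 n_pairs = length(vh))
}

#' Heritability before and after principal-component adjustment
#'
#' Runs the univariate GREML fit twice - without and with the principal
#' components appended to the covariates - and reports both with SEs and
#' the difference. Attenuation after PC adjustment is evidence of
#' population stratification; the verdict text keeps that hedge.
#'
#' @param y Phenotype vector (GRM order or named).
#' @param X_base Base covariates (may be `NULL`).
#' @param grm A `grm` (an attached eigendecomposition is reused).
#' @param pcs Tibble from [compute_pcs()] or a matrix of PC scores.
#' @return Object of class `strat_check`: tibble `estimates` plus
#'   `verdict`.
#' @export
stratification_check <- function(y, X_base = NULL, grm, pcs) {
  pcm <- pc_matrix(pcs, grm$ids)
  fit0 <- reml_univariate(y, X_base, grm)
  Xadj <- if (is.null(X_base)) pcm else cbind(as.matrix(X_base), pcm)
  # drop PCs duplicated in the base covariates (idempotence)
  Xadj <- Xadj[, !duplicated(t(Xadj)), drop = FALSE]
  fit1 <- reml_univariate(y, Xadj, grm)
  diff <- fit0$h2 - fit1$h2
  joint_se <- sqrt(fit0$se_h2^2 + fit1$se_h2^2)
  verdict <- if (diff > 2 * joint_se) {
    sprintf(paste("h2 attenuates from %.3f to %.3f after PC adjustment (difference %.3f,",
                  "joint SE %.3f): attenuation after principal-component adjustment",
                  "can provide evidence of population stratification"),
            fit0$h2, fit1$h2, diff, joint_se)
  } else {
    sprintf(paste("h2 %.3f unadjusted vs %.3f PC-adjusted (difference %.3f, joint SE %.3f):",
                  "little indication of stratification as measured by these components"),
            fit0$h2, fit1$h2, diff, joint_se)
  }
  structure(list(
    estimates = tibble::tibble(
      model = c("unadjusted", "pc_adjusted"),
      h2 = c(fit0$h2, fit1$h2),
      se = c(fit0$se_h2, fit1$se_h2)),
    difference = diff, joint_se = joint_se, verdict = verdict,
    fits = list(unadjusted = fit0, pc_adjusted = fit1)
  ), class = "strat_check")
}

#' @export
print.strat_check <- function(x, ...) {
  cat("<strat_check>\n")
  print(x$estimates)
  cat(" ", x$verdict, "\n")
  invisible(x)
}

#' Extract a PC-score matrix aligned to a set of individuals
#' @param pcs Tibble from [compute_pcs()] or a plain matrix of scores.
#' @param ids Individual ids giving the row order.
#' @return Numeric matrix of PC scores.
#' @export
pc_matrix <- function(pcs, ids) {
  if (is.data.frame(pcs)) {
    m <- as.matrix(pcs[match(ids, pcs$id), grep("^PC", names(pcs)), drop = FALSE])
  } else {
    m <- as.matrix(pcs)
  }
  if (nrow(m) != length(ids)) stop("PC scores do not match GRM individuals")
  m
}

#' Heritability with parental phenotypes as covariates
#'
#' Refits the univariate GREML model with parental phenotype columns
#' appended to the covariates, alongside the base fit. Attenuation of h2
#' after conditioning on parental phenotype indicates that part of the
#' estimate reflects pathways through the family environment (dynastic
#' effects and/or assortative mating) rather than within-individual
#' variant substitution.
#'
#' @param y Child phenotype vector (GRM order).
#' @param parental Matrix/tibble of parental phenotype columns, child-wise
#'   (rows aligned with `y`; missing parental data drops the child,
#'   complete-case with the count logged).
#' @param X_base Base covariates.
#' @param grm A `grm` over the children.
#' @return Tibble with the base and adjusted h2, SEs and `n` used.
#' @export
parental_covariate_h2 <- function(y, parental, X_base = NULL, grm) {
  fit0 <- reml_univariate(y, X_base, grm)
  P <- as.matrix(parental)
  Xadj <- if (is.null(X_base)) P else cbind(as.matrix(X_base), P)
  fit1 <- reml_univariate(y, Xadj, grm)   # complete-case drop inside
  tibble::tibble(
    model = c("base", "parental_adjusted"),
    h2 = c(fit0$h2, fit1$h2),
    se = c(fit0$se_h2, fit1$se_h2),
    n = c(fit0$n, fit1$n)
  )
}

#' Negative-control harness
#'
#' Runs the three mechanism probes - spousal correlation, trio
#' attenuation, and the PC-adjustment comparison - on the negative-control
#' trait of a simulated scenario, and checks that each is null within
#' sampling error. The control trait is constructed with no dynastic term,
#' no subpopulation shift, and no assortment, so any signal here flags a
#' machinery problem rather than a population phenomenon. A mechanism
#' probe exceeding its threshold is reported as non-null (the harness is
#' expected to flag injected faults).
#'
#' @param cohort A `cohort` from a scenario with at least two generations
#'   and spouse pairs.
#' @param pcs Optional PC tibble for the trio models.
#' @param n_boot Bootstrap replications for the attenuation SE.
#' @param seed Optional local seed for bootstraps.
#' @param z_crit Critical value for each probe's null check; the default
#'   qnorm(0.995) keeps the family-wise false-alarm rate of the three
#'   simultaneous probes near 3 percent.
#' @return Object of class `control_report`: tibble `checks` (statistic,
#'   se, threshold, null_consistent) and a `verdict` string.
#' @export
negative_control_run <- function(cohort, pcs = NULL, n_boot = 200, seed = NULL,
                                 z_crit = stats::qnorm(0.995)) {
  trios <- cohort_trios(cohort)
  if (nrow(trios) < 10) {
    stop(errorCondition("fewer than 10 trios; control harness refused",
                        class = c("popconfound_sample_error", "error")))
  }
  ph <- cohort$phenos
  ctl <- stats::setNames(ph$control, ph$id)

  sp <- spousal_correlation(cohort$spouse_pairs, ctl)

  td <- trio_score_data(cohort, weights = cohort_weights(cohort, "control"),
                        trait = "control", pcs = pcs)
  tr <- trio_regression(td, n_boot = n_boot, seed = seed)

  checks <- tibble::tibble(
    mechanism = c("assortative_mating", "dynastic_attenuation",
                  "dynastic_parent_coef"),
    statistic = c(sp$r, tr$attenuation_pct,
                  max(abs(c(tr$b_mother_adj, tr$b_father_adj)))),
    se = c(sp$se, tr$se_attenuation,
           max(tr$se_mother_adj, tr$se_father_adj)),
    threshold = z_crit * c(sp$se, tr$se_attenuation,
                           max(tr$se_mother_adj, tr$se_father_adj))
  )
  checks$null_consistent <- abs(checks$statistic) <= checks$threshold
  verdict <- if (all(checks$null_consistent)) {
    "all mechanism probes on the control trait are within sampling error of zero, consistent with no confounding acting on it"
  } else {
    paste("control trait shows a non-null probe:",
          paste(checks$mechanism[!checks$null_consistent], collapse = ", "),
          "- investigate the analysis machinery or the scenario configuration")
  }
  structure(list(checks = checks, spousal = sp, trio = tr, verdict = verdict),
            class = "control_report")
}

#' @export
print.control_report <- function(x, ...) {
  cat("<control_report>\n")
  print(x$checks)
  cat(" ", x$verdict, "\n")
  invisible(x)
}
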