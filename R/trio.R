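#' Trio polygenic-score regressions
#'
#' Fits, on complete mother-father-child trios, the four least-squares
#' models of the trio attenuation design: child score only
#' ("independent"), each single-parent score, and the three scores
#' co-adjusted - all controlling for the supplied covariates (typically
#' the leading principal components). Coefficients are in SD units of the
#' phenotype per SD of score when both are standardized upstream.
#'
#' @param data Tibble with one row per trio: columns `phenotype`,
#'   `score_child`, `score_mother`, `score_father`, plus any covariate
#'   columns named in `covariates`.
#' @param covariates Character vector of covariate column names (default:
#'   all `PC*` columns present).
#' @param n_boot Bootstrap replications for the attenuation SE (resampling
#'   whole trios); 0 skips the bootstrap.
#' @param seed Optional seed applied locally for the bootstrap.
#' @return A `trio_result` with independent/adjusted coefficients and SEs,
#'   attenuation percentage with bootstrap SE, and the SUR difference
#'   p-value.
#' @export
trio_regression <- function(data, covariates = grep("^PC", names(data), value = TRUE),
                            n_boot = 1000, seed = NULL) {
  needed <- c("phenotype", "score_child", "score_mother", "score_father")
  if (!all(needed %in% names(data))) {
    stop("data must contain columns: ", paste(needed, collapse = ", "))
  }
  data <- data[stats::complete.cases(data[, c(needed, covariates)]), ]
  n <- nrow(data)
  if (n < 10) {
    stop(errorCondition("fewer than 10 complete trios; refusing to fit",
                        class = c("popconfound_sample_error", "error")))
  }
  sc <- as.matrix(data[, c("score_child", "score_mother", "score_father")])
  cc <- stats::cor(sc)
  hi <- which(abs(cc) > 0.99 & upper.tri(cc), arr.ind = TRUE)
  if (nrow(hi)) {
    stop(sprintf("collinear scores: %s and %s (|r| > 0.99)",
                 colnames(cc)[hi[1, 1]], colnames(cc)[hi[1, 2]]))
  }

  covs <- if (length(covariates)) as.matrix(data[, covariates, drop = FALSE]) else NULL
  fit <- function(score_cols) {
    X <- cbind(1, as.matrix(data[, score_cols, drop = FALSE]), covs)
    colnames(X)[1] <- "(Intercept)"
    ols_fit(X, data$phenotype)
  }
  m_child <- fit("score_child")
  m_mother <- fit("score_mother")
  m_father <- fit("score_father")
  m_adj <- fit(c("score_child", "score_mother", "score_father"))

  b_ind <- m_child$coef["score_child"]
  b_adj <- m_adj$coef["score_child"]
  att <- attenuation(unname(b_ind), unname(b_adj))

  boot <- if (n_boot > 0) {
    run <- function() bootstrap_attenuation(data, covs, n_boot)
    if (is.null(seed)) run() else withr::with_seed(seed, run())
  } else {
    list(se = NA_real_, dropped = 0L)
  }

  sur <- sur_difference_test(data, covariates)

  structure(list(
    b_child_ind = unname(b_ind), se_child_ind = unname(m_child$se["score_child"]),
    b_mother_ind = unname(m_mother$coef["score_mother"]),
    se_mother_ind = unname(m_mother$se["score_mother"]),
    b_father_ind = unname(m_father$coef["score_father"]),
    se_father_ind = unname(m_father$se["score_father"]),
    b_child_adj = unname(b_adj), se_child_adj = unname(m_adj$se["score_child"]),
    b_mother_adj = unname(m_adj$coef["score_mother"]),
    se_mother_adj = unname(m_adj$se["score_mother"]),
    b_father_adj = unname(m_adj$coef["score_father"]),
    se_father_adj = unname(m_adj$se["score_father"]),
    attenuation_pct = att, se_attenuation = boot$se,
    boot_dropped = boot$dropped, n_boot = as.integer(n_boot),
    p_diff = sur$p_value, n_trios = n
  ), class = "trio_result")
}

ols_fit <- function(X, y) {
  qr_ <- qr(X)
  coef <- qr.coef(qr_, y)
  res <- y - drop(X %*% coef)
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  XtX_inv <- chol2inv(qr.R(qr_))
  se <- sqrt(s2 * diag(XtX_inv))
  names(se) <- colnames(X)
  list(coef = coef, se = se, residuals = res, XtX_inv = XtX_inv, X = X)
}

#' Percent attenuation of the child polygenic-score coefficient
#'
#' `100 * (b_independent - b_adjusted) / b_independent`: how much of the
#' child-score association disappears once both parental scores are
#' controlled. The independent-model coefficient is the denominator.
#'
#' @param b_ind Child coefficient from the child-score-only model.
#' @param b_adj Child coefficient from the three-score model.
#' @return Percentage.
#' @export
#' @examples
#' attenuation(0.340, 0.223)  # 34.4
attenuation <- function(b_ind, b_adj) {
  if (b_ind == 0) {
    stop(errorCondition("independent coefficient is zero: attenuation undefined",
                        class = c("popconfound_domain_error", "error")))
  }
  100 * (b_ind - b_adj) / b_ind
}

# family-level bootstrap: resample whole trios with replacement, refit the
# independent and co-adjusted models, recompute attenuation; replicates
# with |b_ind| < eps are dropped and counted
bootstrap_attenuation <- function(data, covs, n_reps, eps = 1e-8) {
  n <- nrow(data)
  vals <- numeric(n_reps)
  dropped <- 0L
  y <- data$phenotype
  S <- as.matrix(data[, c("score_child", "score_mother", "score_father")])
  for (r in seq_len(n_reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    Xi <- cbind(1, S[idx, 1], if (!is.null(covs)) covs[idx, , drop = FALSE])
    Xa <- cbind(1, S[idx, , drop = FALSE], if (!is.null(covs)) covs[idx, , drop = FALSE])
    bi <- qr.coef(qr(Xi), y[idx])[2]
    ba <- qr.coef(qr(Xa), y[idx])[2]
    if (!is.finite(bi) || abs(bi) < eps) {
      dropped <- dropped + 1L
      vals[r] <- NA_real_
    } else {
      vals[r] <- 100 * (bi - ba) / bi
    }
  }
  list(se = stats::sd(vals, na.rm = TRUE), dropped = dropped)
}

#' Seemingly-unrelated-regression test on the child-score coefficient
#'
#' Tests whether the child polygenic-score coefficient differs between the
#' child-only and the three-score model fit on the identical trios. The
#' cross-model covariance comes from stacking both models' estimating
#' equations: each model's coefficient has influence representation
#' `(X'X)^-1 x_i e_i`, and the variance of the coefficient difference is
#' the empirical variance of the difference of the two influence
#' contributions (robust, sandwich-style). The Wald statistic is compared
#' with the standard normal. A paired family-bootstrap p-value is
#' available as a cross-check (`mode = "bootstrap"`).
#'
#' @param data Trio tibble as in [trio_regression()].
#' @param covariates Covariate column names.
#' @param mode `"analytic"` (default) or `"bootstrap"`.
#' @param n_boot Replications for the bootstrap mode.
#' @param seed Optional local seed for the bootstrap mode.
#' @return List with `difference`, `se`, `z`, `p_value`.
#' @export
sur_difference_test <- function(data, covariates = grep("^PC", names(data), value = TRUE),
                                mode = c("analytic", "bootstrap"), n_boot = 1000,
                                seed = NULL) {
  mode <- match.arg(mode)
  keep <- stats::complete.cases(
    data[, c("phenotype", "score_child", "score_mother", "score_father", covariates)])
  data <- data[keep, ]
  n <- nrow(data)
  covs <- if (length(covariates)) as.matrix(data[, covariates, drop = FALSE]) else NULL
  X1 <- cbind(1, score_child = data$score_child, covs)
  X2 <- cbind(1, score_child = data$score_child,
              score_mother = data$score_mother,
              score_father = data$score_father, covs)
  f1 <- ols_fit(X1, data$phenotype)

  # duplicated regressor sets collapse to the same model twice
  X2u <- X2[, !duplicated(t(X2)), drop = FALSE]
  if (ncol(X2u) == ncol(X1) && all(X2u == X1)) {
    return(list(difference = 0, se = 0, z = 0, p_value = 1))
  }
  X2 <- X2u
  f2 <- ols_fit(X2, data$phenotype)
  d <- unname(f1$coef["score_child"] - f2$coef["score_child"])
  if (mode == "analytic") {
    if1 <- (X1 %*% f1$XtX_inv[, 2]) * f1$residuals   # influence on coef 1
    if2 <- (X2 %*% f2$XtX_inv[, 2]) * f2$residuals
    dif <- drop(if1 - if2)
    se <- sqrt(sum(dif^2)) * sqrt(n / (n - ncol(X2)))  # small-sample factor
    z <- d / se
    return(list(difference = d, se = se, z = z,
                p_value = 2 * stats::pnorm(-abs(z))))
  }
  run <- function() {
    ds <- vapply(seq_len(n_boot), function(r) {
      idx <- sample.int(n, n, replace = TRUE)
      b1 <- qr.coef(qr(X1[idx, , drop = FALSE]), data$phenotype[idx])[2]
      b2 <- qr.coef(qr(X2[idx, , drop = FALSE]), data$phenotype[idx])[2]
      b1 - b2
    }, numeric(1))
    se <- stats::sd(ds)
    z <- d / se
    list(difference = d, se = se, z = z, p_value = 2 * stats::pnorm(-abs(z)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Incremental variance explained by a polygenic score
#'
#' `R2(covariates + score) - R2(covariates)`, with an individual-level
#' bootstrap SE.
#'
#' @param data Tibble with `phenotype`, `score`, and covariate columns.
#' @param covariates Covariate column names (default all `PC*`).
#' @param n_boot Bootstrap replications (default 1000).
#' @param seed Optional local seed.
#' @return Tibble `incremental_r2`, `se`, `n`.
#' @export
variance_explained <- function(data, covariates = grep("^PC", names(data), value = TRUE),
                               n_boot = 1000, seed = NULL) {
  keep <- stats::complete.cases(data[, c("phenotype", "score", covariates)])
  data <- data[keep, ]
  covs <- if (length(covariates)) as.matrix(data[, covariates, drop = FALSE]) else NULL
  inc_r2 <- function(idx) {
    y <- data$phenotype[idx]
    X0 <- cbind(1, if (!is.null(covs)) covs[idx, , drop = FALSE])
    X1 <- cbind(X0, data$score[idx])
    r0 <- y - drop(X0 %*% qr.coef(qr(X0), y))
    r1 <- y - drop(X1 %*% qr.coef(qr(X1), y))
    (sum(r0^2) - sum(r1^2)) / sum((y - mean(y))^2)
  }
  est <- inc_r2(seq_len(nrow(data)))
  run <- function() {
    stats::sd(vapply(seq_len(n_boot), function(r) {
      inc_r2(sample.int(nrow(data), nrow(data), replace = TRUE))
    }, numeric(1)))
  }
  se <- if (n_boot > 0) { if (is.null(seed)) run() else withr::with_seed(seed, run()) } else NA_real_
  tibble::tibble(incremental_r2 = est, se = se, n = nrow(data))
}

#' @export
print.trio_result <- function(x, ...) {
  cat("<trio_result> ", x$n_trios, " trios\n", sep = "")
  cat(sprintf("  child  %6.3f (%.3f) -> %6.3f (%.3f) | attenuation %.1f%% (%.1f)\n",
              x$b_child_ind, x$se_child_ind, x$b_child_adj, x$se_child_adj,
              x$attenuation_pct, x$se_attenuation))
  cat(sprintf("  mother %6.3f (%.3f) -> %6.3f (%.3f)\n",
              x$b_mother_ind, x$se_mother_ind, x$b_mother_adj, x$se_mother_adj))
  cat(sprintf("  father %6.3f (%.3f) -> %6.3f (%.3f)\n",
              x$b_father_ind, x$se_father_ind, x$b_father_adj, x$se_father_adj))
  cat(sprintf("  SUR difference p = %.3g\n", x$p_diff))
  invisible(x)
}

#' Assemble the trio analysis table for a simulated cohort
#'
#' Builds child/mother/father polygenic scores from a weight set, joins
#' the child phenotype and (optionally) principal components, and returns
#' the tibble [trio_regression()] consumes.
#'
#' @param cohort A `cohort` with trios and phenotypes.
#' @param weights Weight tibble (default: the cohort's trait-A effects).
#' @param trait Phenotype column for the child outcome.
#' @param pcs Optional tibble from [compute_pcs()] (children's ids).
#' @param p_threshold,clump_kb,clump_r2 Score retention rules.
#' @return Tibble with one row per trio.
#' @export
trio_score_data <- function(cohort, weights = cohort_weights(cohort, "a"),
                            trait = "trait_a", pcs = NULL,
                            p_threshold = 5e-8, clump_kb = 250, clump_r2 = 0.1) {
  trios <- cohort_trios(cohort)
  pg <- build_pgs(cohort$dosages, cohort$variant_table, weights,
                  p_threshold = p_threshold, clump_kb = clump_kb,
                  clump_r2 = clump_r2, standardize = FALSE)
  sc <- stats::setNames(pg$score, pg$id)
  std <- function(v) (v - mean(v)) / stats::sd(v)
  ph <- cohort$phenos
  out <- tibble::tibble(
    child_id = trios$child_id,
    phenotype = ph[[trait]][match(trios$child_id, ph$id)],
    score_child = std(sc[trios$child_id]),
    score_mother = std(sc[trios$mother_id]),
    score_father = std(sc[trios$father_id])
  )
  if (!is.null(pcs)) {
    out <- dplyr::left_join(out, dplyr::rename(pcs, child_id = "id"), by = "child_id")
  }
  out
}
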