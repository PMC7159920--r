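#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a GREML fit
#'
#' One row per estimated quantity (`h2`, variance components, and for
#' bivariate fits `rg`, `cov_g`, `r_p`, per-trait heritabilities) with
#' standard errors where defined.
#'
#' @param x A `greml_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.greml_fit <- function(x, ...) {
  if (x$type == "univariate") {
    tibble::tibble(
      term = c("h2", "sigma2_g", "sigma2_e"),
      estimate = c(x$h2, x$sigma2_g, x$sigma2_e),
      std.error = c(x$se_h2, x$se_sigma2_g, x$se_sigma2_e))
  } else {
    tibble::tibble(
      term = c("rg", "h2_A", "h2_B", "r_p", "cov_g",
               "sigma2_g_A", "sigma2_g_B", "sigma2_e_A", "sigma2_e_B", "cov_e"),
      estimate = c(x$rg, x$h2_A, x$h2_B, x$r_p, x$cov_g,
                   x$sigma2_g_A, x$sigma2_g_B, x$sigma2_e_A, x$sigma2_e_B, x$cov_e),
      std.error = c(x$se_rg, x$se_h2_A, x$se_h2_B, x$se_rp,
                    rep(NA_real_, 6)))
  }
}

#' Fit-level summary of a GREML fit
#' @param x A `greml_fit`.
#' @param ... Unused.
#' @return One-row tibble with log-likelihood, iterations, convergence
#'   and boundary flags, and sample size.
#' @export
glance.greml_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_iter = x$n_iter,
                 converged = x$converged, boundary = x$boundary, nobs = x$n)
}

#' Tidy a trio attenuation result
#'
#' @param x A `trio_result`.
#' @param ... Unused.
#' @return Tibble with one row per score term and model
#'   (independent/adjusted).
#' @export
tidy.trio_result <- function(x, ...) {
  tibble::tibble(
    term = rep(c("child", "mother", "father"), 2),
    model = rep(c("independent", "adjusted"), each = 3),
    estimate = c(x$b_child_ind, x$b_mother_ind, x$b_father_ind,
                 x$b_child_adj, x$b_mother_adj, x$b_father_adj),
    std.error = c(x$se_child_ind, x$se_mother_ind, x$se_father_ind,
                  x$se_child_adj, x$se_mother_adj, x$se_father_adj))
}

#' @param x A `trio_result`.
#' @param ... Unused.
#' @rdname tidy.trio_result
#' @return `glance()`: one-row tibble with attenuation, its bootstrap SE,
#'   the SUR difference p-value and trio count.
#' @export
glance.trio_result <- function(x, ...) {
  tibble::tibble(attenuation_pct = x$attenuation_pct,
                 se_attenuation = x$se_attenuation,
                 p_diff = x$p_diff, n_trios = x$n_trios,
                 n_boot = x$n_boot)
}

#' Tidy a bivariate-heritability estimate
#' @param x A `bivariate_h2`.
#' @param ... Unused.
#' @return Tibble with the ratio, its MC SE, and the input estimates.
#' @export
tidy.bivariate_h2 <- function(x, ...) {
  tibble::tibble(
    term = c("h2_AB", "rg", "h2_A", "h2_B", "r_p"),
    estimate = c(x$h2_ab, x$inputs$rg, x$inputs$h2_A, x$inputs$h2_B, x$inputs$r_p),
    std.error = c(x$se_h2_ab, x$inputs$se_rg, x$inputs$se_h2_A,
                  x$inputs$se_h2_B, x$inputs$se_rp))
}
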