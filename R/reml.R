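#' SNP heritability by restricted maximum likelihood (GREML)
#'
#' Fits the mixed model `y = X b + g + e` with `g ~ N(0, sigma2_g K)` for
#' a genetic relatedness matrix `K` and i.i.d. residuals, maximizing the
#' restricted likelihood over the two variance components. Because the
#' model has a single GRM, the covariance is diagonal in the GRM
#' eigenbasis; the fit rotates once and then runs average-information
#' (AI) REML with two EM warm-up steps, step-halving to keep the
#' restricted log-likelihood non-decreasing. Convergence is declared when
#' the relative log-likelihood change falls below `tol` (default 1e-6);
#' components are floored at `1e-6 * var(y)` and flagged as boundary fits
#' when pinned there.
#'
#' The heritability `h2 = sigma2_g / (sigma2_g + sigma2_e)` and its
#' standard error (delta method on the inverse AI matrix, the usual
#' information-based SE) are returned. Individuals with missing phenotype
#' or covariates are dropped (complete-case analysis).
#'
#' @param y Named numeric vector of phenotypes, or unnamed in GRM order.
#' @param X Covariate matrix/data frame (an intercept is added if absent);
#'   `NULL` for intercept only.
#' @param grm A `grm` (optionally carrying a cached eigendecomposition
#'   from [grm_with_eigen()]).
#' @param max_iter,tol AI iteration cap and relative log-likelihood
#'   tolerance.
#' @return A `greml_fit` with components `sigma2_g`, `sigma2_e`, `h2`,
#'   `se_h2`, covariate coefficients, log-likelihood trace, iteration
#'   count, `converged` and `boundary` flags.
#' @export
reml_univariate <- function(y, X = NULL, grm, max_iter = 100, tol = 1e-6) {
  d <- reml_prepare(list(y), X, grm)
  lam <- d$lam
  ys <- d$ys[[1]]
  Xs <- d$Xs
  n <- length(ys)
  vp <- stats::var(ys)
  floor_v <- 1e-6 * vp

  if (max(lam) - min(lam) < 1e-8) {
    stop(errorCondition(
      "GRM eigenvalues are constant (e.g. identity GRM): genetic and residual variance are not separately identifiable",
      class = c("popconfound_identifiability_error", "error")))
  }

  dk <- list(g = lam, e = rep(1, n))
  theta <- c(g = vp / 2, e = vp / 2)

  eval_fit <- function(theta) {
    v <- theta[1] * lam + theta[2]
    w <- 1 / v
    XtVX <- crossprod(Xs, w * Xs)
    ch <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(ch) || any(v <= 0)) return(NULL)
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xs, w * ys)))
    r <- ys - drop(Xs %*% beta)
    py <- w * r
    ll <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(ch))) + sum(r * py))
    list(v = v, w = w, ch = ch, beta = beta, py = py, ll = ll)
  }
  Pfun <- function(st, v) {
    wv <- st$w * v
    cc <- backsolve(st$ch, forwardsolve(t(st$ch), crossprod(Xs, wv)))
    wv - st$w * drop(Xs %*% cc)
  }
  grad_ai <- function(st) {
    score <- numeric(2); ai <- matrix(0, 2, 2)
    XtVX_inv <- chol2inv(st$ch)
    pv <- lapply(dk, function(d) Pfun(st, d * st$py))
    for (k in 1:2) {
      d <- dk[[k]]
      M <- crossprod(Xs, (st$w^2 * d) * Xs)
      tr_pak <- sum(st$w * d) - sum(XtVX_inv * M)
      ypapy <- sum(d * st$py^2)
      score[k] <- -0.5 * (tr_pak - ypapy)
      # AI_kl = 0.5 y'P A_k P A_l P y = 0.5 (A_k Py)' P (A_l Py)
      for (l in k:2) {
        ai[k, l] <- ai[l, k] <- 0.5 * sum((d * st$py) * pv[[l]])
      }
    }
    list(score = score, ai = ai)
  }

  st <- eval_fit(theta)
  ll_trace <- st$ll
  boundary <- FALSE

  # EM warm-up: sigma_k' = sigma_k + sigma_k^2 (y'P A_k P y - tr(P A_k)) / n
  for (em in 1:2) {
    g <- grad_ai(st)
    theta_new <- pmax(theta + theta^2 * (2 * g$score) / n, floor_v)
    st_new <- eval_fit(theta_new)
    if (!is.null(st_new) && st_new$ll >= st$ll - 1e-10) {
      theta <- theta_new; st <- st_new; ll_trace <- c(ll_trace, st$ll)
    }
  }

  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    g <- grad_ai(st)
    step <- tryCatch(solve(g$ai + diag(1e-10, 2), g$score),
                     error = function(e) g$score / max(abs(g$score), 1))
    ok <- FALSE
    for (h in 0:10) {
      theta_new <- pmax(theta + step / 2^h, floor_v)
      st_new <- eval_fit(theta_new)
      if (!is.null(st_new) && st_new$ll >= st$ll - 1e-10) { ok <- TRUE; break }
    }
    if (!ok) break
    delta <- st_new$ll - st$ll
    theta <- theta_new; st <- st_new
    ll_trace <- c(ll_trace, st$ll)
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  boundary <- any(theta <= floor_v * (1 + 1e-8))

  g <- grad_ai(st)
  vc <- tryCatch(solve(g$ai), error = function(e) matrix(NA_real_, 2, 2))
  s <- sum(theta)
  grad_h2 <- c(theta[2], -theta[1]) / s^2
  se_h2 <- sqrt(max(drop(t(grad_h2) %*% vc %*% grad_h2), 0))
  h2 <- min(max(theta[1] / s, 0), 1)

  beta <- drop(st$beta)
  names(beta) <- colnames(Xs)
  structure(list(
    type = "univariate",
    sigma2_g = unname(theta[1]), sigma2_e = unname(theta[2]),
    h2 = h2, se_h2 = se_h2,
    se_sigma2_g = sqrt(max(vc[1, 1], 0)), se_sigma2_e = sqrt(max(vc[2, 2], 0)),
    vcov_theta = vc, beta = beta,
    loglik = st$ll, ll_trace = ll_trace, n_iter = iter,
    converged = converged, boundary = boundary, n = n
  ), class = "greml_fit")
}

#' Bivariate GREML: genetic covariance and genetic correlation
#'
#' Joint REML fit of two traits sharing one GRM, estimating per-trait
#' genetic and residual variances plus the genetic and residual
#' covariances (six parameters). The covariance structure is 2x2
#' block-diagonal in the GRM eigenbasis, so iterations stay O(n).
#' Starting values come from the two univariate fits; AI updates with
#' step-halving keep the restricted likelihood ascending and the
#' per-block covariance matrices positive definite.
#'
#' The genetic correlation is `rg = cov_g / sqrt(var_gA * var_gB)` (SE by
#' delta method on the inverse AI matrix). The phenotypic correlation
#' `r_p` of the covariate-residualized traits is computed and stored,
#' since the bivariate-heritability ratio needs it. If either genetic
#' variance is pinned at its floor, `rg` is returned as `NA` with the
#' boundary flag set.
#'
#' @param yA,yB Phenotype vectors on the same individuals (complete cases
#'   used).
#' @param X Covariates shared by both traits (intercept added if absent).
#' @param grm A `grm`.
#' @param max_iter,tol As in [reml_univariate()].
#' @return A `greml_fit` with bivariate fields (`sigma2_g_A`, `sigma2_g_B`,
#'   `cov_g`, residual analogues, `rg`, `se_rg`, `r_p`, `se_rp`, per-trait
#'   `h2_A`/`h2_B` with SEs).
#' @export
reml_bivariate <- function(yA, yB, X = NULL, grm, max_iter = 100, tol = 1e-6) {
  d <- reml_prepare(list(yA, yB), X, grm)
  lam <- d$lam
  Y <- cbind(d$ys[[1]], d$ys[[2]])
  Xs <- d$Xs
  n <- nrow(Y)
  p <- ncol(Xs)
  vp <- c(stats::var(Y[, 1]), stats::var(Y[, 2]))
  floor_v <- 1e-6 * vp

  # r_p on covariate-residualized traits (in the rotated basis the GLS
  # residualization differs; use the original-scale OLS residuals)
  resA <- stats::lm.fit(d$X0, d$y0[[1]])$residuals
  resB <- stats::lm.fit(d$X0, d$y0[[2]])$residuals
  r_p <- stats::cor(resA, resB)
  se_rp <- sqrt((1 - r_p^2) / (length(resA) - 2))

  fitA <- reml_univariate(d$y0[[1]], d$X0[, -1, drop = FALSE], grm_keep(grm, d$ids))
  fitB <- reml_univariate(d$y0[[2]], d$X0[, -1, drop = FALSE], grm_keep(grm, d$ids))

  # theta = (gA, cg, gB, eA, ce, eB); start from the univariate fits but
  # keep the start strictly interior (a boundary start breaks the AI step)
  interior <- function(v, vp) min(max(v, 0.05 * vp), 0.95 * vp)
  gA0 <- interior(fitA$sigma2_g, vp[1]); eA0 <- vp[1] - gA0
  gB0 <- interior(fitB$sigma2_g, vp[2]); eB0 <- vp[2] - gB0
  theta <- c(gA = gA0, cg = 0.5 * r_p * sqrt(gA0 * gB0), gB = gB0,
             eA = eA0, ce = 0.5 * r_p * sqrt(eA0 * eB0), eB = eB0)

  # per-parameter rotated derivative blocks (d11, d12, d22) per eigenvalue
  one <- rep(1, n)
  zero <- numeric(n)
  dk <- list(gA = list(lam, zero, zero), cg = list(zero, lam, zero),
             gB = list(zero, zero, lam), eA = list(one, zero, zero),
             ce = list(zero, one, zero), eB = list(zero, zero, one))

  bmul <- function(b, v) {  # 2x2 block matrix (b11,b12,b22) times n x 2
    cbind(b[[1]] * v[, 1] + b[[2]] * v[, 2], b[[2]] * v[, 1] + b[[3]] * v[, 2])
  }
  eval_fit <- function(theta) {
    v11 <- theta["gA"] * lam + theta["eA"]
    v12 <- theta["cg"] * lam + theta["ce"]
    v22 <- theta["gB"] * lam + theta["eB"]
    det <- v11 * v22 - v12^2
    if (any(det <= 0) || any(v11 <= 0) || any(v22 <= 0)) return(NULL)
    W <- list(v22 / det, -v12 / det, v11 / det)
    XtVX <- rbind(cbind(crossprod(Xs, W[[1]] * Xs), crossprod(Xs, W[[2]] * Xs)),
                  cbind(crossprod(Xs, W[[2]] * Xs), crossprod(Xs, W[[3]] * Xs)))
    ch <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    WY <- bmul(W, Y)
    xty <- c(crossprod(Xs, WY[, 1]), crossprod(Xs, WY[, 2]))
    beta <- backsolve(ch, forwardsolve(t(ch), xty))
    R <- Y - cbind(Xs %*% beta[1:p], Xs %*% beta[(p + 1):(2 * p)])
    PY <- bmul(W, R)
    ll <- -0.5 * (sum(log(det)) + 2 * sum(log(diag(ch))) + sum(R * PY))
    list(W = W, ch = ch, beta = beta, PY = PY, ll = ll)
  }
  Pfun <- function(st, v) {
    Wv <- bmul(st$W, v)
    cc <- backsolve(st$ch, forwardsolve(t(st$ch),
                                        c(crossprod(Xs, Wv[, 1]), crossprod(Xs, Wv[, 2]))))
    Xc <- cbind(Xs %*% cc[1:p], Xs %*% cc[(p + 1):(2 * p)])
    Wv - bmul(st$W, Xc)
  }
  grad_ai <- function(st) {
    K <- length(dk)
    score <- numeric(K); ai <- matrix(0, K, K)
    APy <- lapply(dk, function(d) bmul(d, st$PY))
    PAPy <- lapply(APy, function(v) Pfun(st, v))
    XtVX_inv <- chol2inv(st$ch)
    W <- st$W
    for (k in seq_len(K)) {
      d <- dk[[k]]
      # tr(V^-1 A_k) summed over 2x2 blocks
      tr1 <- sum(W[[1]] * d[[1]] + 2 * W[[2]] * d[[2]] + W[[3]] * d[[3]])
      # T = W D W per block (symmetric 2x2)
      t11 <- W[[1]] * (d[[1]] * W[[1]] + d[[2]] * W[[2]]) +
             W[[2]] * (d[[2]] * W[[1]] + d[[3]] * W[[2]])
      t12 <- W[[1]] * (d[[1]] * W[[2]] + d[[2]] * W[[3]]) +
             W[[2]] * (d[[2]] * W[[2]] + d[[3]] * W[[3]])
      t22 <- W[[2]] * (d[[1]] * W[[2]] + d[[2]] * W[[3]]) +
             W[[3]] * (d[[2]] * W[[2]] + d[[3]] * W[[3]])
      M <- rbind(cbind(crossprod(Xs, t11 * Xs), crossprod(Xs, t12 * Xs)),
                 cbind(crossprod(Xs, t12 * Xs), crossprod(Xs, t22 * Xs)))
      tr2 <- sum(XtVX_inv * M)
      ypapy <- sum(st$PY * APy[[k]])
      score[k] <- -0.5 * ((tr1 - tr2) - ypapy)
      for (l in k:K) {
        ai[k, l] <- ai[l, k] <- 0.5 * sum(APy[[k]] * PAPy[[l]])
      }
    }
    list(score = score, ai = ai)
  }

  st <- eval_fit(theta)
  if (is.null(st)) stop("could not initialize bivariate REML (singular start)")
  ll_trace <- st$ll
  converged <- FALSE
  iter <- 0
  clamp <- function(theta) {
    theta["gA"] <- max(theta["gA"], floor_v[1]); theta["gB"] <- max(theta["gB"], floor_v[2])
    theta["eA"] <- max(theta["eA"], floor_v[1]); theta["eB"] <- max(theta["eB"], floor_v[2])
    cap_g <- 0.9999 * sqrt(theta["gA"] * theta["gB"])
    cap_e <- 0.9999 * sqrt(theta["eA"] * theta["eB"])
    theta["cg"] <- min(max(theta["cg"], -cap_g), cap_g)
    theta["ce"] <- min(max(theta["ce"], -cap_e), cap_e)
    theta
  }
  while (iter < max_iter) {
    iter <- iter + 1
    g <- grad_ai(st)
    step <- tryCatch(solve(g$ai + diag(1e-10, 6), g$score),
                     error = function(e) g$score / max(abs(g$score), 1))
    try_step <- function(step) {
      for (h in 0:12) {
        theta_new <- clamp(theta + stats::setNames(step, names(theta)) / 2^h)
        st_new <- eval_fit(theta_new)
        if (!is.null(st_new) && st_new$ll > st$ll + 1e-12) {
          return(list(theta = theta_new, st = st_new))
        }
      }
      NULL
    }
    moved <- try_step(step)
    if (is.null(moved)) {
      # AI direction failed; fall back to a scaled-gradient ascent step
      moved <- try_step(g$score * mean(vp) / max(abs(g$score), 1))
    }
    if (is.null(moved)) break
    theta_new <- moved$theta; st_new <- moved$st
    delta <- st_new$ll - st$ll
    theta <- theta_new; st <- st_new
    ll_trace <- c(ll_trace, st$ll)
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  boundary_g <- theta["gA"] <= floor_v[1] * (1 + 1e-8) ||
    theta["gB"] <= floor_v[2] * (1 + 1e-8)

  g <- grad_ai(st)
  vc <- tryCatch(solve(g$ai), error = function(e) matrix(NA_real_, 6, 6))
  dimnames(vc) <- list(names(theta), names(theta))

  h2A <- theta["gA"] / (theta["gA"] + theta["eA"])
  h2B <- theta["gB"] / (theta["gB"] + theta["eB"])
  se_h2 <- function(gn, en) {
    s <- theta[gn] + theta[en]
    gr <- c(theta[en], -theta[gn]) / s^2
    V <- vc[c(gn, en), c(gn, en)]
    sqrt(max(drop(t(gr) %*% V %*% gr), 0))
  }

  if (boundary_g) {
    rg <- NA_real_; se_rg <- NA_real_
  } else {
    rg <- unname(theta["cg"] / sqrt(theta["gA"] * theta["gB"]))
    gr <- c(gA = -rg / (2 * theta[["gA"]]),
            cg = 1 / sqrt(theta[["gA"]] * theta[["gB"]]),
            gB = -rg / (2 * theta[["gB"]]))
    V <- vc[names(gr), names(gr)]
    se_rg <- sqrt(max(drop(t(gr) %*% V %*% gr), 0))
  }

  beta <- drop(st$beta)
  names(beta) <- c(paste0(colnames(Xs), "_A"), paste0(colnames(Xs), "_B"))
  structure(list(
    type = "bivariate",
    sigma2_g_A = unname(theta["gA"]), sigma2_g_B = unname(theta["gB"]),
    cov_g = unname(theta["cg"]),
    sigma2_e_A = unname(theta["eA"]), sigma2_e_B = unname(theta["eB"]),
    cov_e = unname(theta["ce"]),
    h2_A = unname(h2A), se_h2_A = se_h2("gA", "eA"),
    h2_B = unname(h2B), se_h2_B = se_h2("gB", "eB"),
    rg = rg, se_rg = se_rg, r_p = r_p, se_rp = se_rp,
    vcov_theta = vc, beta = beta,
    loglik = st$ll, ll_trace = ll_trace, n_iter = iter,
    converged = converged, boundary = boundary_g, n = n
  ), class = "greml_fit")
}

#' @export
print.greml_fit <- function(x, ...) {
  if (x$type == "univariate") {
    cat(sprintf("<greml_fit univariate> h2 = %.3f (SE %.3f), n = %d, %s\n",
                x$h2, x$se_h2, x$n,
                if (x$converged) sprintf("converged in %d iter", x$n_iter) else "NOT converged"))
  } else {
    cat(sprintf("<greml_fit bivariate> rg = %.3f (SE %.3f), h2_A = %.3f, h2_B = %.3f, r_p = %.3f, n = %d\n",
                x$rg, x$se_rg, x$h2_A, x$h2_B, x$r_p, x$n))
  }
  if (x$boundary) cat("  note: a variance component is at its lower floor\n")
  invisible(x)
}

#' Haseman-Elston regression (method-of-moments heritability)
#'
#' Regresses pairwise phenotype cross-products of standardized,
#' covariate-residualized traits on the off-diagonal GRM entries. The
#' slope estimates `h2` (same trait) or the standardized genetic
#' covariance (two traits). Serves as an independent moment-based check on
#' the REML fits. The OLS standard error is reported; it ignores the
#' dependence between pairs sharing an individual and is therefore mildly
#' anti-conservative.
#'
#' @param y Phenotype vector.
#' @param grm A `grm`.
#' @param y2 Optional second trait for the cross-trait version.
#' @param X Optional covariates to residualize out first.
#' @return Tibble with `estimate`, `se`, `n_pairs`.
#' @export
he_regression <- function(y, grm, y2 = NULL, X = NULL) {
  n <- length(grm$ids)
  if (n < 50) stop("Haseman-Elston regression needs at least 50 individuals")
  stdz <- function(v) {
    if (!is.null(X)) v <- stats::lm.fit(cbind(1, as.matrix(X)), v)$residuals
    else v <- v - mean(v)
    v / stats::sd(v)
  }
  zA <- stdz(y)
  zB <- if (is.null(y2)) zA else stdz(y2)
  ut <- upper.tri(grm$values)
  k <- grm$values[ut]
  if (stats::var(k) == 0) {
    stop(errorCondition("GRM off-diagonals have zero variance",
                        class = c("popconfound_grm_error", "error")))
  }
  prod <- (tcrossprod(zA, zB) + tcrossprod(zB, zA))[ut] / 2
  slope <- stats::cov(prod, k) / stats::var(k)
  res <- prod - mean(prod) - slope * (k - mean(k))
  se <- sqrt(sum(res^2) / (length(k) - 2) / (stats::var(k) * (length(k) - 1)))
  tibble::tibble(estimate = slope, se = se, n_pairs = length(k))
}

# ---- shared preparation: complete cases, covariate matrix, rotation ----

reml_prepare <- function(ys, X, grm) {
  n0 <- length(grm$ids)
  ys <- lapply(ys, function(y) {
    y <- if (!is.null(names(y))) y[grm$ids] else y
    if (length(y) != n0) stop("phenotype length does not match GRM")
    as.numeric(y)
  })
  X0 <- build_design(X, n0)
  keep <- Reduce("&", lapply(ys, function(y) !is.na(y))) &
    stats::complete.cases(X0)
  if (!all(keep)) {
    grm <- grm_subset(grm, grm$ids[keep])
    ys <- lapply(ys, function(y) y[keep])
    X0 <- X0[keep, , drop = FALSE]
  }
  if (qr(X0)$rank < ncol(X0)) stop("covariate matrix is singular")
  eig <- grm_eigen(grm)
  list(
    lam = eig$values,
    ys = lapply(ys, function(y) drop(crossprod(eig$vectors, y))),
    Xs = crossprod(eig$vectors, X0),
    y0 = ys, X0 = X0, ids = grm$ids
  )
}

build_design <- function(X, n) {
  if (is.null(X)) {
    X0 <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X0 <- as.matrix(X)
    if (nrow(X0) != n) stop("covariates do not match GRM dimension")
    has_const <- any(apply(X0, 2, function(c) stats::sd(c) == 0))
    if (!has_const) X0 <- cbind(`(Intercept)` = 1, X0)
    if (is.null(colnames(X0))) colnames(X0) <- paste0("x", seq_len(ncol(X0)))
  }
  X0
}

# subset keeping eigen cache when ids are unchanged
grm_keep <- function(grm, ids) {
  if (identical(grm$ids, ids)) grm else grm_subset(grm, ids)
}
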