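# Shared fixtures (built once per test run) and independent oracles.

# small one-generation cohort with shared genetics between traits
fix_null <- local({
  cfg <- preset_config("null", n_founder_couples = 250, n_snps = 600,
                       n_causal = 300, seed = 101)
  coh <- simulate_scenario(cfg)
  grm <- grm_with_eigen(compute_grm(coh$dosages))
  list(cfg = cfg, cohort = coh, grm = grm,
       phen = cohort_phenotypes(coh, 0))
})

# two-generation cohort with random mating, 1 child per couple (trios)
fix_trio <- local({
  cfg <- sim_config(n_founder_couples = 400, n_snps = 400, n_causal = 200,
                    h2_target = 0.6, n_generations = 2,
                    offspring_per_couple = 1, seed = 202)
  list(cfg = cfg, cohort = simulate_scenario(cfg))
})

# dense-matrix restricted likelihood, maximized numerically: the
# independent oracle for the rotated AI-REML implementation
oracle_reml_uni <- function(y, X, K) {
  n <- length(y)
  X <- cbind(X)
  nll <- function(par) {
    sg <- exp(par[1]); se <- exp(par[2])
    V <- sg * K + diag(se, n)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Vi <- chol2inv(ch)
    XtViX <- crossprod(X, Vi %*% X)
    b <- solve(XtViX, crossprod(X, Vi %*% y))
    r <- y - drop(X %*% b)
    drop(0.5 * (2 * sum(log(diag(ch))) +
                determinant(XtViX)$modulus +
                crossprod(r, Vi %*% r)))
  }
  v0 <- stats::var(y) / 2
  o <- stats::optim(log(c(v0, v0)), nll, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-14))
  stats::setNames(exp(o$par), c("sigma2_g", "sigma2_e"))
}

oracle_reml_biv <- function(yA, yB, X, K) {
  n <- length(yA)
  X <- cbind(X)
  XX <- rbind(cbind(X, 0 * X), cbind(0 * X, X))
  y <- c(yA, yB)
  nll <- function(par) {
    gA <- exp(par[1]); gB <- exp(par[2]); cg <- tanh(par[3]) * sqrt(gA * gB)
    eA <- exp(par[4]); eB <- exp(par[5]); ce <- tanh(par[6]) * sqrt(eA * eB)
    V <- rbind(cbind(gA * K + diag(eA, n), cg * K + diag(ce, n)),
               cbind(cg * K + diag(ce, n), gB * K + diag(eB, n)))
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Vi <- chol2inv(ch)
    XtViX <- crossprod(XX, Vi %*% XX)
    b <- solve(XtViX, crossprod(XX, Vi %*% y))
    r <- y - drop(XX %*% b)
    drop(0.5 * (2 * sum(log(diag(ch))) + determinant(XtViX)$modulus +
                crossprod(r, Vi %*% r)))
  }
  vA <- stats::var(yA) / 2; vB <- stats::var(yB) / 2
  o <- stats::optim(c(log(vA), log(vB), atanh(0.2), log(vA), log(vB), atanh(0.2)),
                    nll, method = "Nelder-Mead",
                    control = list(maxit = 20000, reltol = 1e-14))
  gA <- exp(o$par[1]); gB <- exp(o$par[2])
  c(gA = gA, gB = gB, cg = tanh(o$par[3]) * sqrt(gA * gB),
    eA = exp(o$par[4]), eB = exp(o$par[5]),
    rg = tanh(o$par[3]), ll = -o$value)
}

# Hudson-style two-population FST, ratio-of-averages over variants
hudson_fst <- function(dos, labels) {
  s1 <- dos[labels == 1, , drop = FALSE]
  s2 <- dos[labels == 2, , drop = FALSE]
  p1 <- colMeans(s1) / 2; p2 <- colMeans(s2) / 2
  n1 <- nrow(s1); n2 <- nrow(s2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# build a cohort object by hand (for transmission-level tests)
manual_couples_cohort <- function(dos_m, dos_f, config) {
  n <- nrow(dos_m)
  m <- ncol(dos_m)
  ids <- c(sprintf("g0_i%05d", seq_len(2 * n)))
  dos <- rbind(dos_f, dos_m)
  rownames(dos) <- ids
  colnames(dos) <- sprintf("snp%05d", seq_len(m))
  vt <- tibble::tibble(
    variant_id = colnames(dos), chrom = 1L, pos = 1e4 * seq_len(m),
    effect_allele = "A", other_allele = "G",
    founder_freq = pmin(pmax(colMeans(dos) / 2, 0.01), 0.99))
  ind <- tibble::tibble(
    id = ids, sex = rep(c("M", "F"), each = n), generation = 0L, subpop = 1L,
    mother_id = NA_character_, father_id = NA_character_)
  pairs <- tibble::tibble(husband_id = ids[seq_len(n)],
                          wife_id = ids[n + seq_len(n)], generation = 0L)
  structure(list(dosages = dos, variant_table = vt, individuals = ind,
                 spouse_pairs = pairs, phenos = NULL, transmission = NULL,
                 config = config, effects = NULL), class = "cohort")
}
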