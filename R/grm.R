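#' Genetic relatedness matrix from dosages
#'
#' Standard standardized-dosage GRM: entry (j, k) is the mean over
#' variants of `(x_j - 2p)(x_k - 2p) / (2p(1 - p))`. Allele frequencies
#' are estimated from the sample unless supplied. Monomorphic variants are
#' dropped. Missing dosages are handled pairwise: products are summed over
#' variants observed in both individuals and divided by the per-pair
#' variant count.
#'
#' @param dosages Individuals x variants matrix of 0/1/2 counts (`NA`
#'   allowed), with row names as individual ids.
#' @param allele_freqs Optional numeric vector of effect-allele
#'   frequencies, one per variant column.
#' @return An object of class `grm`: list with `ids`, `values` (symmetric
#'   relatedness matrix) and `n_snps` (per-pair variant-count matrix).
#' @export
compute_grm <- function(dosages, allele_freqs = NULL) {
  if (nrow(dosages) < 2) stop("need at least two individuals")
  if (is.null(allele_freqs)) {
    allele_freqs <- colMeans(dosages, na.rm = TRUE) / 2
  }
  poly <- allele_freqs > 0 & allele_freqs < 1 &
    apply(dosages, 2, function(x) stats::var(x, na.rm = TRUE) > 0)
  poly[is.na(poly)] <- FALSE
  if (!any(poly)) {
    stop(errorCondition("all variants are monomorphic; GRM undefined",
                        class = c("popconfound_grm_error", "error")))
  }
  X <- dosages[, poly, drop = FALSE]
  p <- allele_freqs[poly]
  W <- sweep(X, 2, 2 * p, "-")
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")

  if (anyNA(W)) {
    obs <- !is.na(W)
    W[!obs] <- 0
    counts <- tcrossprod(obs + 0)
    K <- tcrossprod(W) / counts
  } else {
    counts <- matrix(ncol(W), nrow(W), nrow(W))
    K <- tcrossprod(W) / ncol(W)
  }
  ids <- rownames(dosages)
  if (is.null(ids)) ids <- sprintf("ind%05d", seq_len(nrow(dosages)))
  dimnames(K) <- list(ids, ids)
  structure(list(ids = ids, values = K, n_snps = counts), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("<grm> ", length(x$ids), " individuals, mean diagonal ",
      sprintf("%.3f", mean(diag(x$values))), "\n", sep = "")
  invisible(x)
}

#' Subset a GRM to a set of individuals
#' @param grm A `grm`.
#' @param ids Individual ids to keep, in the order requested.
#' @return A `grm` over `ids`.
#' @export
grm_subset <- function(grm, ids) {
  idx <- match(ids, grm$ids)
  if (anyNA(idx)) stop("ids not present in GRM: ", paste(ids[is.na(idx)][1:3], collapse = ", "))
  structure(list(ids = ids, values = grm$values[idx, idx, drop = FALSE],
                 n_snps = grm$n_snps[idx, idx, drop = FALSE]), class = "grm")
}

#' Greedy relatedness pruning
#'
#' Repeatedly removes the individual involved in the most remaining pairs
#' whose relatedness exceeds `threshold`, until no such pair is left -
#' the usual pre-GREML step of restricting to nominally unrelated
#' individuals.
#'
#' @param grm A `grm`.
#' @param threshold Off-diagonal relatedness cutoff (default 0.1).
#' @return Character vector of retained ids.
#' @export
prune_related <- function(grm, threshold = 0.1) {
  K <- grm$values
  diag(K) <- 0
  keep <- rep(TRUE, length(grm$ids))
  repeat {
    over <- (abs(K) > threshold) & outer(keep, keep, "&")
    counts <- rowSums(over)
    if (all(counts == 0)) break
    drop_i <- which.max(counts)
    keep[drop_i] <- FALSE
    K[drop_i, ] <- 0
    K[, drop_i] <- 0
  }
  grm$ids[keep]
}

#' Leading principal components of genetic structure
#'
#' Eigendecomposition of the GRM (or of the standardized-dosage covariance
#' when a dosage matrix is given). Scores are the eigenvectors scaled by
#' the square root of their eigenvalues, orthogonal by construction, with
#' the sign convention that each component's largest-magnitude entry is
#' positive (so results are deterministic up to machine precision).
#'
#' @param x A `grm` or a dosage matrix.
#' @param k Number of components (must be positive and < n).
#' @return Tibble with `id` and `PC1..PCk`; eigenvalues in
#'   `attr(, "eigenvalues")` (all of them, for spectrum diagnostics).
#' @export
compute_pcs <- function(x, k = 20) {
  if (k <= 0) stop("k must be positive")
  if (!inherits(x, "grm")) x <- compute_grm(x)
  n <- length(x$ids)
  if (k >= n) stop("k must be smaller than the number of individuals")
  eig <- grm_eigen(x)
  scores <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(eig$values[seq_len(k)], 0)), k)
  for (j in seq_len(k)) {
    if (scores[which.max(abs(scores[, j])), j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  out <- tibble::tibble(id = x$ids)
  out <- dplyr::bind_cols(out, tibble::as_tibble(scores))
  attr(out, "eigenvalues") <- eig$values
  out
}

# cache the eigendecomposition on the grm object (REML and PCA share it)
grm_eigen <- function(grm) {
  cached <- attr(grm, "eigen")
  if (!is.null(cached)) return(cached)
  eigen(grm$values, symmetric = TRUE)
}

#' Attach a cached eigendecomposition to a GRM
#'
#' REML fits and principal components both consume the GRM eigenbasis;
#' decomposing once and reusing it saves the dominant O(n^3) cost when a
#' GRM is analysed repeatedly.
#'
#' @param grm A `grm`.
#' @return The same `grm` with the eigendecomposition stored in an
#'   attribute.
#' @export
grm_with_eigen <- function(grm) {
  attr(grm, "eigen") <- grm_eigen(grm)
  grm
}

#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles of `(rank - c) / (n - 2c + 1)` with the
#' Blom offset `c = 3/8`; ties share their mean rank and missing values
#' stay missing.
#'
#' @param values Numeric vector (>= 2 non-missing values required).
#' @return Transformed vector of the same length.
#' @export
#' @examples
#' inverse_normal_transform(c(5, 1, 9))
inverse_normal_transform <- function(values) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(x) < 2) stop("need at least two non-missing values")
  if (stats::sd(x) == 0) stop("all values identical; transform undefined")
  n <- length(x)
  r <- rank(x, ties.method = "average")
  out <- values
  out[ok] <- stats::qnorm((r - 3 / 8) / (n - 2 * 3 / 8 + 1))
  out
}
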