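#' Build a polygenic score with p-value thresholding and clumping
#'
#' Weights are harmonized to the dosage coding (weights flipped in sign
#' when the stated effect allele matches the variant's other allele;
#' strand-ambiguous A/T and C/G variants dropped), filtered at
#' `p_threshold`, and clumped: scanning variants in ascending discovery
#' p-value, the best variant in each window is retained and every other
#' variant within `clump_kb` kilobases on the same chromosome whose
#' dosage r-squared with it exceeds `clump_r2` is removed. The score is
#' `sum(weight * dosage)` over retained variants, standardized to unit SD
#' in the scoring sample unless `standardize = FALSE`.
#'
#' @param dosages Individuals x variants dosage matrix with variant ids as
#'   column names.
#' @param variant_table Tibble with `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele` (positions only needed when clumping).
#' @param weights Tibble with `variant_id`, `effect_allele`, `weight`,
#'   `p_value` (no duplicate variants).
#' @param p_threshold Discovery p-value cutoff (default genome-wide
#'   significance, 5e-8).
#' @param clump_kb,clump_r2 Clumping window half-width in kb and the LD
#'   r-squared above which neighbours of a retained variant are removed;
#'   `clump_kb = 0` disables clumping.
#' @param standardize Standardize the score to unit SD (default TRUE).
#' @return Tibble `id`, `score`; the per-variant retention log is in
#'   `attr(, "retention")`.
#' @export
build_pgs <- function(dosages, variant_table, weights,
                      p_threshold = 5e-8, clump_kb = 250, clump_r2 = 0.1,
                      standardize = TRUE) {
  if (anyDuplicated(weights$variant_id)) {
    stop(errorCondition("duplicate variant ids in weight set",
                        class = c("popconfound_pgs_error", "error")))
  }
  vt <- variant_table[match(weights$variant_id, variant_table$variant_id), ]
  log <- tibble::tibble(variant_id = weights$variant_id,
                        status = "retained", weight = weights$weight)

  log$status[is.na(vt$variant_id)] <- "missing_from_genotypes"
  ambiguous <- function(a, b) paste0(a, b) %in% c("AT", "TA", "CG", "GC")
  flip <- !is.na(vt$variant_id) & weights$effect_allele == vt$other_allele
  match_ok <- !is.na(vt$variant_id) &
    (weights$effect_allele == vt$effect_allele | flip)
  log$status[!is.na(vt$variant_id) & !match_ok] <- "allele_mismatch"
  amb <- !is.na(vt$variant_id) & ambiguous(vt$effect_allele, vt$other_allele)
  log$status[amb] <- "strand_ambiguous"
  log$weight[flip] <- -log$weight[flip]

  log$status[log$status == "retained" & weights$p_value > p_threshold] <- "above_p_threshold"

  cand <- which(log$status == "retained")
  if (clump_kb > 0 && length(cand) > 1) {
    ord <- cand[order(weights$p_value[cand], weights$variant_id[cand])]
    removed <- logical(nrow(weights))
    for (i in ord) {
      if (removed[i]) next
      near <- cand[!removed[cand] & cand != i &
                     vt$chrom[cand] == vt$chrom[i] &
                     abs(vt$pos[cand] - vt$pos[i]) <= clump_kb * 1000]
      if (length(near)) {
        r2 <- suppressWarnings(
          stats::cor(dosages[, vt$variant_id[i]],
                     dosages[, vt$variant_id[near], drop = FALSE])^2
        )
        drop_these <- near[!is.na(r2) & r2 > clump_r2]
        removed[drop_these] <- TRUE
      }
    }
    log$status[removed] <- "clumped"
  }

  keep <- log$status == "retained"
  if (!any(keep)) {
    stop(errorCondition("no variants retained for scoring",
                        class = c("popconfound_pgs_error", "error")))
  }
  score <- unname(drop(dosages[, vt$variant_id[keep], drop = FALSE] %*% log$weight[keep]))
  if (standardize) {
    if (stats::sd(score) == 0) {
      stop(errorCondition("score has zero variance; cannot standardize",
                          class = c("popconfound_pgs_error", "error")))
    }
    score <- (score - mean(score)) / stats::sd(score)
  }
  out <- tibble::tibble(id = rownames(dosages), score = score)
  attr(out, "retention") <- log
  out
}

#' Nontransmitted-allele (genetic nurture) scores
#'
#' For each child, sums `weight * nontransmitted allele count` per parent
#' over the same retained variant set as the corresponding transmitted
#' score, where the nontransmitted count is the parent's dosage minus the
#' allele that parent transmitted. Because nontransmitted alleles can only
#' influence the child through the environment the parents shape,
#' association of these scores with the child phenotype indicates dynastic
#' effects. Requires the simulator's transmission record (for real,
#' unphased data nontransmitted alleles are only resolvable at
#' homozygous-parent variants; that path is not implemented here).
#'
#' @param cohort A `cohort` with at least two generations.
#' @param weights Weight tibble as in [build_pgs()].
#' @param p_threshold,clump_kb,clump_r2 Retention rules, matched to
#'   [build_pgs()].
#' @param standardize Standardize each score to unit SD (default TRUE).
#' @return Tibble `child_id`, `nt_score_mother`, `nt_score_father`,
#'   `nt_score` (their sum, standardized last if requested), plus the
#'   transmitted `t_score_mother`/`t_score_father` for bookkeeping checks.
#' @export
nontransmitted_score <- function(cohort, weights, p_threshold = 5e-8,
                                 clump_kb = 250, clump_r2 = 0.1,
                                 standardize = TRUE) {
  if (is.null(cohort$transmission)) {
    stop(errorCondition("cohort has no transmission record (no trios)",
                        class = c("popconfound_state_error", "error")))
  }
  ref <- build_pgs(cohort$dosages, cohort$variant_table, weights,
                   p_threshold = p_threshold, clump_kb = clump_kb,
                   clump_r2 = clump_r2, standardize = FALSE)
  log <- attr(ref, "retention")
  keep <- log$status == "retained"
  vids <- log$variant_id[keep]
  w <- log$weight[keep]

  kids <- rownames(cohort$transmission$trans_m)
  info <- cohort$individuals[match(kids, cohort$individuals$id), ]
  nt_m <- cohort$dosages[info$mother_id, vids, drop = FALSE] -
    cohort$transmission$trans_m[, vids, drop = FALSE]
  nt_f <- cohort$dosages[info$father_id, vids, drop = FALSE] -
    cohort$transmission$trans_f[, vids, drop = FALSE]

  out <- tibble::tibble(
    child_id = kids,
    nt_score_mother = unname(drop(nt_m %*% w)),
    nt_score_father = unname(drop(nt_f %*% w)),
    t_score_mother = unname(drop(cohort$transmission$trans_m[, vids, drop = FALSE] %*% w)),
    t_score_father = unname(drop(cohort$transmission$trans_f[, vids, drop = FALSE] %*% w))
  )
  out$nt_score <- out$nt_score_mother + out$nt_score_father
  if (standardize) {
    for (col in c("nt_score_mother", "nt_score_father", "nt_score")) {
      s <- stats::sd(out[[col]])
      if (s > 0) out[[col]] <- (out[[col]] - mean(out[[col]])) / s
    }
  }
  attr(out, "retention") <- log
  out
}

#' Effect-set weights in scoring format
#'
#' Converts a simulator effect set into the weight-table dialect consumed
#' by [build_pgs()] (variant, effect allele, weight, p-value), selecting
#' one trait's effects.
#'
#' @param cohort A `cohort` carrying its effect set.
#' @param trait `"a"`, `"b"` or `"control"`.
#' @return A weight tibble.
#' @export
cohort_weights <- function(cohort, trait = c("a", "b", "control")) {
  trait <- match.arg(trait)
  eff <- cohort$effects
  if (is.null(eff)) stop("cohort carries no effect set")
  beta <- eff[[paste0("beta_", if (trait == "control") "control" else trait)]]
  tibble::tibble(
    variant_id = eff$variant_id,
    effect_allele = cohort$variant_table$effect_allele[
      match(eff$variant_id, cohort$variant_table$variant_id)],
    weight = beta,
    p_value = eff$p_value
  )
}
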