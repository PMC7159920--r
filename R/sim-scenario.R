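#' Run a full multi-generation simulation scenario
#'
#' Orchestrates the simulator: founders are drawn (seeding the single
#' random stream from `config$seed`), causal effects are drawn, and then
#' for each mating round the sequence phenotype computation ->
#' spouse pairing -> reproduction runs, finishing with phenotypes for the
#' final generation. With `n_generations = 1` only founders exist and no
#' trio structure is available.
#'
#' The stochastic draw order is fixed and documented: ancestral
#' frequencies, subpopulation frequencies, founder dosages, effect sets
#' (A, B, control), then per generation residuals/controls, pairing noise
#' (including calibration trials), and transmission coin flips. Repeat
#' runs with the same config are byte-identical.
#'
#' @param config A [sim_config()] or preset name accepted by
#'   [preset_config()].
#' @param ... Overrides forwarded to [preset_config()] when `config` is a
#'   preset name.
#' @return A `cohort` with all generations, phenotypes, spouse pairs,
#'   transmission records, and the effect set attached.
#' @export
#' @examples
#' coh <- simulate_scenario(preset_config("null", n_founder_couples = 60,
#'                                        n_snps = 120, n_causal = 60))
#' coh
simulate_scenario <- function(config, ...) {
  if (is.character(config)) config <- preset_config(config, ...)
  validate_sim_config(config)
  cohort <- simulate_founders(config)
  effects <- draw_effects(config)
  cohort <- make_phenotypes(cohort, effects, config)
  if (config$n_generations > 1) {
    for (gen in seq_len(config$n_generations - 1L) - 1L) {
      cohort <- assortative_pairing(cohort, config, generation = gen)
      cohort <- reproduce(cohort, config)
      cohort <- make_phenotypes(cohort, effects, config)
    }
  }
  cohort
}

#' Extract complete mother-father-child trios from a cohort
#'
#' @param cohort A `cohort` with at least two generations.
#' @param generation Child generation; default the latest.
#' @return Tibble with `child_id`, `mother_id`, `father_id`.
#' @export
cohort_trios <- function(cohort, generation = max(cohort$individuals$generation)) {
  if (generation < 1 || max(cohort$individuals$generation) < 1) {
    stop(errorCondition("cohort has a single generation; no trios exist",
                        class = c("popconfound_state_error", "error")))
  }
  kids <- cohort$individuals[cohort$individuals$generation == generation, ]
  kids <- kids[!is.na(kids$mother_id) & !is.na(kids$father_id), ]
  tibble::tibble(child_id = kids$id, mother_id = kids$mother_id,
                 father_id = kids$father_id)
}

#' Per-generation phenotype table
#'
#' Convenience accessor joining individuals and phenotypes.
#'
#' @param cohort A `cohort`.
#' @param generation Generation index, default the latest.
#' @return Tibble of individuals with phenotype and true-component columns.
#' @export
cohort_phenotypes <- function(cohort, generation = max(cohort$individuals$generation)) {
  if (is.null(cohort$phenos)) stop("phenotypes not computed")
  dplyr::inner_join(
    cohort$individuals[cohort$individuals$generation == generation, ],
    cohort$phenos,
    by = c("id", "generation")
  )
}
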