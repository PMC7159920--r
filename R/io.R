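#' Write a cohort's genotypes as PLINK text .ped/.map
#'
#' One line per individual: FID IID father mother sex(1=M,2=F) phenotype
#' (-9), then two allele columns per variant. The .map file carries
#' chromosome, variant id, zero genetic distance, and position.
#'
#' @param cohort A `cohort`.
#' @param prefix Output path prefix (writes `prefix.ped` and `prefix.map`).
#' @return The prefix, invisibly.
#' @export
write_plink <- function(cohort, prefix) {
  vt <- cohort$variant_table
  readr::write_tsv(
    tibble::tibble(chrom = vt$chrom, id = vt$variant_id, cm = 0, pos = vt$pos),
    paste0(prefix, ".map"), col_names = FALSE)

  info <- cohort$individuals
  dos <- cohort$dosages
  a1 <- vt$effect_allele; a2 <- vt$other_allele
  con <- file(paste0(prefix, ".ped"), "w")
  on.exit(close(con))
  for (i in seq_len(nrow(info))) {
    d <- dos[info$id[i], ]
    g1 <- ifelse(d >= 1, a1, a2)
    g2 <- ifelse(d == 2, a1, a2)
    line <- c(info$id[i], info$id[i],
              ifelse(is.na(info$father_id[i]), "0", info$father_id[i]),
              ifelse(is.na(info$mother_id[i]), "0", info$mother_id[i]),
              ifelse(info$sex[i] == "M", "1", "2"), "-9",
              as.vector(rbind(g1, g2)))
    writeLines(paste(line, collapse = " "), con)
  }
  invisible(prefix)
}

#' Write an additive-dosage table (.raw-style)
#'
#' Whitespace table with FID, IID and one 0/1/2 column per variant, named
#' `variantid_effectallele`.
#'
#' @param cohort A `cohort`.
#' @param file Output path.
#' @export
write_dosage_raw <- function(cohort, file) {
  vt <- cohort$variant_table
  d <- tibble::as_tibble(cohort$dosages)
  names(d) <- paste0(vt$variant_id, "_", vt$effect_allele)
  out <- dplyr::bind_cols(
    tibble::tibble(FID = rownames(cohort$dosages), IID = rownames(cohort$dosages)), d)
  readr::write_delim(out, file, delim = " ")
  invisible(file)
}

#' Read an additive-dosage table written by [write_dosage_raw()]
#' @param file Path.
#' @return Dosage matrix with individual ids as row names.
#' @export
read_dosage_raw <- function(file) {
  d <- readr::read_delim(file, delim = " ", show_col_types = FALSE)
  m <- as.matrix(d[, -(1:2)])
  rownames(m) <- d$IID
  colnames(m) <- sub("_[ACGT]+$", "", colnames(m))
  storage.mode(m) <- "integer"
  m
}

#' Write a PLINK-style phenotype table (.phen dialect)
#'
#' Whitespace-delimited FID IID then one column per requested trait.
#'
#' @param cohort A `cohort` with phenotypes.
#' @param file Output path.
#' @param traits Phenotype columns to include.
#' @export
write_phen <- function(cohort, file, traits = c("trait_a", "trait_b", "control")) {
  ph <- cohort$phenos
  out <- dplyr::bind_cols(tibble::tibble(FID = ph$id, IID = ph$id),
                          ph[, traits, drop = FALSE])
  readr::write_delim(out, file, delim = " ")
  invisible(file)
}

#' Read a whitespace FID/IID phenotype or covariate table
#' @param file Path.
#' @return Tibble with `FID`, `IID` and value columns.
#' @export
read_phen <- function(file) {
  readr::read_table(file, show_col_types = FALSE)
}

#' Write pedigree, spouse-pair and weight tables
#'
#' `write_pedigree()`: child, mother, father, sex, generation,
#' subpopulation (TSV). `write_spouses()`: husband, wife, generation
#' (TSV). `write_weights()`: variant, effect allele, per-trait betas and
#' the placeholder discovery p-value (TSV).
#'
#' @param cohort A `cohort`.
#' @param file Output path.
#' @name cohort-writers
NULL

#' @rdname cohort-writers
#' @export
write_pedigree <- function(cohort, file) {
  info <- cohort$individuals
  readr::write_tsv(tibble::tibble(
    child = info$id, mother = info$mother_id, father = info$father_id,
    sex = info$sex, generation = info$generation, subpop = info$subpop), file)
  invisible(file)
}

#' @rdname cohort-writers
#' @export
write_spouses <- function(cohort, file) {
  readr::write_tsv(cohort$spouse_pairs, file)
  invisible(file)
}

#' @rdname cohort-writers
#' @export
write_weights <- function(cohort, file) {
  eff <- cohort$effects
  vt <- cohort$variant_table
  readr::write_tsv(tibble::tibble(
    variant_id = eff$variant_id,
    effect_allele = vt$effect_allele[match(eff$variant_id, vt$variant_id)],
    beta_a = eff$beta_a, beta_b = eff$beta_b, p_value = eff$p_value), file)
  invisible(file)
}

#' Read a polygenic-score weight table
#'
#' TSV with columns variant id, effect allele, weight (beta), p-value;
#' flexible about the exact column names (`beta`/`weight`/`beta_a`,
#' `p`/`p_value`/`pval`).
#'
#' @param file Path.
#' @return Weight tibble for [build_pgs()].
#' @export
read_weights <- function(file) {
  d <- readr::read_tsv(file, show_col_types = FALSE)
  pick <- function(cands) {
    hit <- intersect(cands, names(d))
    if (!length(hit)) stop("weight file lacks a column among: ",
                           paste(cands, collapse = ", "))
    d[[hit[1]]]
  }
  tibble::tibble(
    variant_id = pick(c("variant_id", "variant", "snp", "id")),
    effect_allele = pick(c("effect_allele", "a1", "allele")),
    weight = pick(c("weight", "beta", "beta_a", "effect")),
    p_value = pick(c("p_value", "p", "pval"))
  )
}

#' GCTA-format GRM input/output
#'
#' `write_grm_gcta()` writes the binary triple: `.grm.bin` (float32 lower
#' triangle including the diagonal, row-major by individual), `.grm.N.bin`
#' (float32 per-pair variant counts) and `.grm.id` (family/individual id
#' text table). `read_grm_gcta()` reads it back. `write_grm_text()` writes
#' the gzipped text dialect (i, j, n_snps, relatedness per line).
#'
#' @param grm A `grm`.
#' @param prefix Path prefix for the three files.
#' @return The prefix (writers) or a `grm` (reader).
#' @name grm-io
NULL

#' @rdname grm-io
#' @export
write_grm_gcta <- function(grm, prefix) {
  n <- length(grm$ids)
  lt <- which(lower.tri(grm$values, diag = TRUE), arr.ind = TRUE)
  lt <- lt[order(lt[, 1], lt[, 2]), , drop = FALSE]
  vals <- grm$values[lt]
  counts <- grm$n_snps[lt]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(vals), con, size = 4)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(counts), con, size = 4)
  close(con)
  readr::write_tsv(tibble::tibble(FID = grm$ids, IID = grm$ids),
                   paste0(prefix, ".grm.id"), col_names = FALSE)
  invisible(prefix)
}

#' @rdname grm-io
#' @export
read_grm_gcta <- function(prefix) {
  ids <- readr::read_tsv(paste0(prefix, ".grm.id"), col_names = c("FID", "IID"),
                         show_col_types = FALSE)$IID
  n <- length(ids)
  n_lt <- n * (n + 1) / 2
  con <- file(paste0(prefix, ".grm.bin"), "rb")
  vals <- readBin(con, "numeric", n_lt, size = 4)
  close(con)
  nf <- paste0(prefix, ".grm.N.bin")
  counts <- if (file.exists(nf)) {
    con <- file(nf, "rb"); on.exit(close(con))
    readBin(con, "numeric", n_lt, size = 4)
  } else rep(NA_real_, n_lt)
  K <- matrix(0, n, n); Nm <- matrix(0, n, n)
  lt <- which(lower.tri(K, diag = TRUE), arr.ind = TRUE)
  lt <- lt[order(lt[, 1], lt[, 2]), , drop = FALSE]
  K[lt] <- vals; Nm[lt] <- counts
  K <- K + t(K) - diag(diag(K))
  Nm <- Nm + t(Nm) - diag(diag(Nm))
  dimnames(K) <- list(ids, ids)
  structure(list(ids = ids, values = K, n_snps = Nm), class = "grm")
}

#' @rdname grm-io
#' @export
write_grm_text <- function(grm, prefix) {
  n <- length(grm$ids)
  lt <- which(lower.tri(grm$values, diag = TRUE), arr.ind = TRUE)
  lt <- lt[order(lt[, 1], lt[, 2]), , drop = FALSE]
  out <- tibble::tibble(i = lt[, 1], j = lt[, 2],
                        n_snps = grm$n_snps[lt], value = grm$values[lt])
  readr::write_tsv(out, paste0(prefix, ".grm.gz"), col_names = FALSE)
  readr::write_tsv(tibble::tibble(FID = grm$ids, IID = grm$ids),
                   paste0(prefix, ".grm.id"), col_names = FALSE)
  invisible(prefix)
}

#' Read/write a simulation configuration as YAML
#'
#' The YAML mirrors [sim_config()] field for field.
#'
#' @param config A `sim_config` (writer) / path (reader).
#' @param file Path.
#' @return The path (writer) or a `sim_config` (reader).
#' @name config-io
NULL

#' @rdname config-io
#' @export
write_config_yaml <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname config-io
#' @export
read_config_yaml <- function(file) {
  do.call(sim_config, yaml::read_yaml(file))
}
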