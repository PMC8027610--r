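# File readers/writers for the project's plain-text formats: a PLINK
# .raw-dialect genotype TSV, long-format panel TSV, GWAS-style weight
# TSV, and a JSON truth record.

#' Write / read genotypes as a PLINK `.raw`-dialect TSV
#'
#' The header is `FID IID PAT MAT SEX PHENOTYPE` followed by one
#' `variantid_effectallele` column per variant holding dosage counts of
#' the effect allele in \[0, 2\]. `read_genotypes_raw()` validates the
#' layout and dosage range with row/column locations in error messages.
#' Allele metadata beyond the effect allele is carried in a sidecar
#' attribute on write and reconstructed as `NA` on read unless an `info`
#' table is supplied.
#'
#' @param genotypes A `genotype_matrix`.
#' @param path Output file.
#' @return `write_genotypes_raw()` returns `path` invisibly;
#'   `read_genotypes_raw()` returns a `genotype_matrix` (the other
#'   allele is unknown from the `.raw` format alone and set to `NA`
#'   unless provided).
#' @export
write_genotypes_raw <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  ids <- rownames(genotypes$dosages)
  df <- data.frame(
    FID = ids, IID = ids, PAT = 0L, MAT = 0L, SEX = 0L, PHENOTYPE = -9L,
    check.names = FALSE
  )
  cols <- paste0(genotypes$variant_ids, "_", genotypes$effect_allele)
  for (j in seq_along(cols)) df[[cols[j]]] <- genotypes$dosages[, j]
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_genotypes_raw
#' @param other_allele Optional vector of non-effect alleles, aligned
#'   with the variant columns.
#' @export
read_genotypes_raw <- function(path, other_allele = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!identical(names(df)[1:6], need)) {
    abort("Not a .raw-dialect file: first six columns must be FID IID PAT MAT SEX PHENOTYPE.")
  }
  geno_cols <- names(df)[-(1:6)]
  if (length(geno_cols) == 0) abort("No variant columns found.")
  parts <- regmatches(geno_cols, regexpr("_[^_]+$", geno_cols))
  variant_ids <- sub("_[^_]+$", "", geno_cols)
  effect_allele <- sub("^_", "", parts)
  dosages <- as.matrix(df[, geno_cols])
  bad <- which(!is.finite(dosages) | dosages < 0 | dosages > 2, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("Dosage out of [0, 2] at row %d, column '%s'.",
                  bad[1, 1], geno_cols[bad[1, 2]]))
  }
  rownames(dosages) <- df$IID
  colnames(dosages) <- variant_ids
  new_genotype_matrix(dosages, variant_ids, effect_allele,
                      other_allele %||% rep(NA_character_, length(variant_ids)),
                      maf = colMeans(dosages) / 2)
}

#' Read / write a GWAS-style weight table
#'
#' TSV with columns `ID A1 A2 BETA P CHR BP` (`A2`, `P`, `CHR`, `BP`
#' optional; extra columns tolerated), mapped to the internal
#' `variant_id`, `effect_allele`, `other_allele`, `weight`, `p_value`,
#' `chr`, `pos` naming. Duplicate variant ids are an error.
#'
#' @param path File path.
#' @return A weight-table tibble.
#' @export
read_weight_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("ID", "A1", "BETA") %in% names(df))) {
    abort("Weight table needs at least columns ID, A1, BETA.")
  }
  out <- tibble::tibble(
    variant_id = as.character(df$ID),
    effect_allele = as.character(df$A1),
    weight = as.numeric(df$BETA)
  )
  if ("A2" %in% names(df)) out$other_allele <- as.character(df$A2)
  if ("P" %in% names(df)) out$p_value <- as.numeric(df$P)
  if ("CHR" %in% names(df)) out$chr <- df$CHR
  if ("BP" %in% names(df)) out$pos <- as.numeric(df$BP)
  check_weight_table(out)
  out
}

#' @rdname read_weight_table
#' @param weights A weight-table tibble.
#' @export
write_weight_table <- function(weights, path) {
  check_weight_table(weights)
  df <- data.frame(ID = weights$variant_id, A1 = weights$effect_allele,
                   BETA = weights$weight)
  if ("other_allele" %in% names(weights)) df$A2 <- weights$other_allele
  if ("p_value" %in% names(weights)) df$P <- weights$p_value
  if ("chr" %in% names(weights)) df$CHR <- weights$chr
  if ("pos" %in% names(weights)) df$BP <- weights$pos
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read / write the long-format panel TSV
#'
#' Validates the required columns and that (person, wave) pairs are
#' unique and BMI is positive, reporting offending rows.
#'
#' @param panel A panel tibble.
#' @param path File path.
#' @export
write_panel <- function(panel, path) {
  readr::write_tsv(panel, path)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("person_id", "wave", "bmi")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0("Panel lacks column(s): ", paste(missing, collapse = ", ")))
  }
  dup <- duplicated(df[, c("person_id", "wave")])
  if (any(dup)) {
    abort(sprintf("Duplicate (person, wave) pair at row %d.", which(dup)[1]))
  }
  bad <- which(!is.finite(df$bmi) | df$bmi <= 0)
  if (length(bad)) {
    abort(sprintf("Non-positive BMI at row %d.", bad[1]))
  }
  df$person_id <- as.character(df$person_id)
  df
}

#' Write / read a truth record as JSON
#'
#' Every drawn parameter round-trips bit-exactly (full double precision).
#'
#' @param truth A `truth_record`.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_record"))
  jsonlite::write_json(lapply(unclass(truth), as.list), path,
                       digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      mean_betas = unlist(raw$mean_betas),
      var_alphas = unlist(raw$var_alphas),
      true_att_params = unlist(raw$true_att_params),
      true_alpha1 = unname(unlist(raw$true_alpha1)),
      propensity_coefs = unlist(raw$propensity_coefs),
      drift_coefs = unlist(raw$drift_coefs)
    ),
    class = "truth_record"
  )
}
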