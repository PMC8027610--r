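#' Compute a polygenic score as an allele-aligned weighted dosage sum
#'
#' For each person the raw score is `sum_j beta_j x_ij` over the variants
#' shared between the genotype matrix and the weight table, where `x_ij`
#' counts copies of the weight's effect allele. When the genotype file
#' counts the opposite allele, the dosage is flipped to `2 - x` before
#' summing; variants where neither allele matches are skipped with a
#' warning. Works identically for mean-effect (mPGS) and dispersion-effect
#' (vPGS) weights.
#'
#' @param genotypes A `genotype_matrix`.
#' @param weights A weight table: tibble with `variant_id`,
#'   `effect_allele`, `weight` (optionally `other_allele`, `p_value`,
#'   `chr`, `pos`).
#' @return A tibble with `person_id`, `raw_score`, `standardized_score`
#'   (sample mean 0, SD 1; all-zero when the raw score is constant at 0).
#'   A scoring report (matched / flipped / skipped counts) is attached as
#'   attribute `"scoring_report"`.
#' @export
compute_pgs <- function(genotypes, weights) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  check_weight_table(weights)
  idx <- match(weights$variant_id, genotypes$variant_ids)
  shared <- which(!is.na(idx))
  if (length(shared) == 0) {
    abort("No variants shared between genotypes and the weight table.")
  }
  n <- nrow(genotypes$dosages)
  raw <- numeric(n)
  n_flipped <- 0L
  n_allele_skip <- 0L
  for (k in shared) {
    j <- idx[k]
    w <- weights$weight[k]
    geno_eff <- genotypes$effect_allele[j]
    geno_oth <- genotypes$other_allele[j]
    wt_eff <- weights$effect_allele[k]
    if (identical(wt_eff, geno_eff)) {
      raw <- raw + w * genotypes$dosages[, j]
    } else if (identical(wt_eff, geno_oth)) {
      raw <- raw + w * (2 - genotypes$dosages[, j])
      n_flipped <- n_flipped + 1L
    } else {
      warn(sprintf("Variant %s: allele %s matches neither genotype allele (%s/%s); skipped.",
                   weights$variant_id[k], wt_eff, geno_eff, geno_oth))
      n_allele_skip <- n_allele_skip + 1L
    }
  }
  n_used <- length(shared) - n_allele_skip
  if (n_used == 0) abort("All shared variants had irreconcilable alleles.")
  s <- sd(raw)
  std <- if (!is.na(s) && s > 0) (raw - mean(raw)) / s else raw * 0
  out <- tibble::tibble(
    person_id = rownames(genotypes$dosages) %||% as.character(seq_len(n)),
    raw_score = raw,
    standardized_score = std
  )
  attr(out, "scoring_report") <- tibble::tibble(
    n_weights = nrow(weights),
    n_matched = length(shared),
    n_used = n_used,
    n_flipped = n_flipped,
    n_skipped_unmatched = nrow(weights) - length(shared),
    n_skipped_allele = n_allele_skip
  )
  out
}

check_weight_table <- function(weights) {
  need <- c("variant_id", "effect_allele", "weight")
  missing <- setdiff(need, names(weights))
  if (length(missing)) {
    abort(paste0("Weight table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(weights$variant_id)) {
    dups <- unique(weights$variant_id[duplicated(weights$variant_id)])
    abort(paste0("Duplicate variant id(s) in weight table: ",
                 paste(head(dups, 5), collapse = ", ")))
  }
  if (any(!is.finite(weights$weight))) abort("Weights must be finite.")
  if ("p_value" %in% names(weights)) {
    p <- weights$p_value[!is.na(weights$p_value)]
    if (any(p <= 0 | p > 1)) abort("p-values must lie in (0, 1].")
  }
  invisible(weights)
}

#' Standardize a score to mean zero and unit standard deviation
#'
#' The z-transform uses the sample mean and sample SD (n - 1 denominator),
#' matching the convention that polygenic scores enter all models
#' standardized over the scoring sample. Idempotent up to floating point.
#'
#' @param x A numeric vector, or a score tibble from [compute_pgs()] (its
#'   `raw_score` column is restandardized).
#' @return Same shape as the input with standardized values.
#' @export
standardize_score <- function(x) {
  if (is.data.frame(x)) {
    x$standardized_score <- standardize_score(x$raw_score)
    return(x)
  }
  (x - mean(x)) / sample_sd(x)
}

#' Greedy LD clumping of a weight table
#'
#' Iterates variants by ascending p-value and keeps a variant unless it
#' lies within `window_kb` of an already-kept variant on the same
#' chromosome with pairwise r-squared at or above `r2_threshold` (the
#' PLINK-style clumping rule, here run against a supplied r-squared
#' table). Ties are broken deterministically by
#' (p-value, chromosome, position, variant id), so the output is
#' independent of input row order.
#'
#' @param weights Weight table with `p_value`, `chr`, `pos` columns.
#' @param r2 Pairwise r-squared values: a tibble with columns `id_a`,
#'   `id_b`, `r2` (treated as symmetric; absent pairs count as 0), or a
#'   symmetric matrix with variant ids as dimnames.
#' @param r2_threshold Clumping threshold (default 0.1, the conventional
#'   value for polygenic-score construction).
#' @param window_kb Window in kilobases (default 1000).
#' @return The kept rows of `weights`, sorted by the tie-break order.
#' @export
greedy_clump <- function(weights, r2, r2_threshold = 0.1, window_kb = 1000) {
  check_weight_table(weights)
  need <- c("p_value", "chr", "pos")
  if (!all(need %in% names(weights)) ||
      anyNA(weights$p_value) || anyNA(weights$chr) || anyNA(weights$pos)) {
    abort("Clumping requires complete `p_value`, `chr`, `pos` columns.")
  }
  lookup <- build_r2_lookup(r2)
  ord <- order(weights$p_value, weights$chr, weights$pos, weights$variant_id)
  w <- weights[ord, ]
  kept <- logical(nrow(w))
  for (i in seq_len(nrow(w))) {
    prior <- which(kept)
    conflict <- FALSE
    for (j in prior) {
      if (w$chr[j] != w$chr[i]) next
      if (abs(w$pos[j] - w$pos[i]) > window_kb * 1000) next
      if (lookup(w$variant_id[i], w$variant_id[j]) >= r2_threshold) {
        conflict <- TRUE
        break
      }
    }
    kept[i] <- !conflict
  }
  w[kept, ]
}

build_r2_lookup <- function(r2) {
  if (is.matrix(r2)) {
    function(a, b) {
      if (!a %in% rownames(r2) || !b %in% colnames(r2)) return(0)
      r2[a, b]
    }
  } else {
    stopifnot(all(c("id_a", "id_b", "r2") %in% names(r2)))
    key <- c(paste(r2$id_a, r2$id_b, sep = "\r"),
             paste(r2$id_b, r2$id_a, sep = "\r"))
    val <- c(r2$r2, r2$r2)
    env <- new.env(parent = emptyenv())
    for (i in seq_along(key)) assign(key[i], val[i], envir = env)
    function(a, b) {
      k <- paste(a, b, sep = "\r")
      if (exists(k, envir = env, inherits = FALSE)) get(k, envir = env) else 0
    }
  }
}

#' Validate a mean polygenic score against growth-curve BMI intercepts
#'
#' Two-stage growth-curve validation: stage 1 fits, per person, an
#' ordinary least squares quadratic age model
#' `BMI_it = b0_i + b1_i age + b2_i age^2 + e_it` (age centered at the
#' sample mean, so the intercept is the person's expected BMI at the
#' average age) and extracts the intercepts `b0_i`; stage 2 regresses
#' those intercepts on the mPGS plus sex and ancestry-PC covariates and
#' reports the incremental R-squared of the mPGS over the covariate-only
#' model. Persons with fewer than three waves cannot support a quadratic
#' fit and are excluded (counted in the report).
#'
#' @param panel Long panel tibble with `person_id`, `bmi`, `age`.
#' @param scores Score tibble (`person_id`, `standardized_score`) or a
#'   two-column tibble with `person_id` and a score column named `mpgs`.
#' @param covariates Character vector of person-level covariate columns in
#'   `panel` to adjust for (constant within person).
#' @return A list of class `growth_curve_validation`: `incremental_r2`,
#'   `slope` (stage-2 mPGS coefficient), `r2_full`, `r2_covariates`,
#'   `n_persons`, `n_excluded`, and the stage-1 `intercepts` tibble.
#' @export
validate_mpgs_growth_curve <- function(panel, scores,
                                       covariates = character(0)) {
  score_col <- if ("standardized_score" %in% names(scores)) {
    "standardized_score"
  } else if ("mpgs" %in% names(scores)) "mpgs" else {
    abort("`scores` needs a `standardized_score` or `mpgs` column.")
  }
  counts <- dplyr::count(panel, .data$person_id)
  ok_ids <- counts$person_id[counts$n >= 3]
  n_excluded <- nrow(counts) - length(ok_ids)
  if (length(ok_ids) == 0) abort("No person has >= 3 observations.")
  sub <- panel[panel$person_id %in% ok_ids, ]
  age_c <- sub$age - mean(sub$age)
  sub$.age_c <- age_c

  intercepts <- sub |>
    dplyr::group_by(.data$person_id) |>
    dplyr::group_modify(function(d, key) {
      fit <- lm(bmi ~ .age_c + I(.age_c^2), data = d)
      tibble::tibble(intercept = unname(coef(fit)[1]))
    }) |>
    dplyr::ungroup()

  df <- dplyr::inner_join(intercepts,
                          scores[, c("person_id", score_col)],
                          by = "person_id")
  names(df)[names(df) == score_col] <- ".mpgs"
  if (length(covariates)) {
    covs <- dplyr::distinct(sub[, c("person_id", covariates)])
    df <- dplyr::inner_join(df, covs, by = "person_id")
  }
  rhs_cov <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  fit_cov <- lm(as.formula(paste("intercept ~", rhs_cov)), data = df)
  fit_full <- lm(as.formula(paste("intercept ~ .mpgs +", rhs_cov)), data = df)
  r2 <- function(f) summary(f)$r.squared
  structure(
    list(
      incremental_r2 = r2(fit_full) - r2(fit_cov),
      slope = unname(coef(fit_full)[".mpgs"]),
      r2_full = r2(fit_full),
      r2_covariates = r2(fit_cov),
      n_persons = length(ok_ids),
      n_excluded = n_excluded,
      intercepts = intercepts
    ),
    class = "growth_curve_validation"
  )
}

#' @export
print.growth_curve_validation <- function(x, ...) {
  cat("<growth_curve_validation>\n")
  cat(sprintf("  persons: %d (excluded <3 waves: %d)\n",
              x$n_persons, x$n_excluded))
  cat(sprintf("  incremental R^2 of mPGS: %.4f (slope %.4f)\n",
              x$incremental_r2, x$slope))
  invisible(x)
}
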