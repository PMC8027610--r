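#' Subset a genotype matrix by person ids
#'
#' @param genotypes A `genotype_matrix`.
#' @param ids Person ids (row names) to keep.
#' @return A `genotype_matrix` restricted to `ids`.
#' @export
subset_genotypes <- function(genotypes, ids) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  keep <- rownames(genotypes$dosages) %in% ids
  new_genotype_matrix(genotypes$dosages[keep, , drop = FALSE],
                      genotypes$variant_ids, genotypes$effect_allele,
                      genotypes$other_allele, genotypes$maf)
}

#' Run the full synthetic study end to end
#'
#' Executes the whole analytic workflow on one synthetic cohort:
#' simulate genotypes and truth; split individuals 80-20; run the
#' per-variant dispersion scan on the training split and turn its mean
#' and dispersion effects into mPGS/vPGS weight tables; score the
#' held-out cohort and validate the trained vPGS by DGLM (with and
#' without mPGS adjustment) on the inverse-normal-transformed phenotype;
#' then, on the longitudinal panel, estimate the probit propensity model
#' (including the polygenic scores among the conditioning variables),
#' trim to common support, compute Epanechnikov kernel matching weights
#' within survey-year-by-sex strata, tabulate covariate balance, fit the
#' weighted DiD interaction regression, derive treatment effects by
#' genotype, and fit the event-time study for the full sample and both
#' vPGS-median strata.
#'
#' @param config A [sim_config()].
#' @param seed Optional global seed override (defaults to
#'   `config$seed`).
#' @param output_dir Optional directory: panel, weight tables, truth,
#'   and coefficient JSONs plus a run report are written there.
#' @param att_grid Tibble of (`mpgs`, `vpgs`) values for the
#'   treatment-effect grid; defaults to scores in \{-2, -1, 0, 1, 2\}
#'   varied one at a time.
#' @return A list of class `gxe_run` with elements `config`, `truth`,
#'   `scan`, `test_scores`, `vpgs_validation`, `propensity`,
#'   `match_weights`, `balance`, `did`, `att`, `ets` (list: full,
#'   below_median, above_median), and `report`.
#' @export
run_workflow <- function(config, seed = NULL, output_dir = NULL,
                         att_grid = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
  }

  # --- simulate ------------------------------------------------------
  genotypes <- simulate_genotypes(config)
  truth <- draw_truth(genotypes, config)
  pheno <- simulate_phenotype(genotypes, truth, config)

  split <- split_train_test(pheno$person_id, fraction = 0.8,
                            seed = child_seed(config$seed, "split"))

  # --- train dispersion (and mean) weights on the training split -----
  train_geno <- subset_genotypes(genotypes, split$train)
  train_y <- inverse_normal_transform(
    pheno$phenotype[pheno$person_id %in% split$train]
  )
  scan <- dispersion_scan(train_geno, train_y)

  vpgs_weights <- tibble::tibble(
    variant_id = scan$variant_id,
    effect_allele = genotypes$effect_allele[
      match(scan$variant_id, genotypes$variant_ids)],
    weight = scan$dispersion_effect,
    p_value = scan$dispersion_p
  )
  mpgs_weights <- tibble::tibble(
    variant_id = scan$variant_id,
    effect_allele = vpgs_weights$effect_allele,
    weight = scan$mean_effect
  )

  # --- score and validate on the held-out cohort ---------------------
  test_geno <- subset_genotypes(genotypes, split$test)
  test_y <- inverse_normal_transform(
    pheno$phenotype[pheno$person_id %in% split$test]
  )
  test_scores <- tibble::tibble(
    person_id = rownames(test_geno$dosages),
    phenotype_int = test_y,
    vpgs = compute_pgs(test_geno, vpgs_weights)$standardized_score,
    mpgs = compute_pgs(test_geno, mpgs_weights)$standardized_score
  )
  vpgs_val <- validate_vpgs(test_scores, response = "phenotype_int",
                            vpgs = "vpgs", mpgs = "mpgs")

  # --- causal arm: panel, matching, DiD, ETS -------------------------
  panel <- simulate_panel(genotypes, truth, config)
  scores <- attr(panel, "person_scores")  # oracle-weight scores
  # Under a null architecture the oracle score is degenerate (all zero);
  # fall back to the trained weights so the regression stays full rank.
  if (sd(scores$vpgs) == 0) {
    scores$vpgs <- compute_pgs(genotypes, vpgs_weights)$standardized_score
  }
  if (sd(scores$mpgs) == 0) {
    scores$mpgs <- compute_pgs(genotypes, mpgs_weights)$standardized_score
  }

  frame <- build_did_frame(panel)
  frame <- dplyr::left_join(frame, scores, by = "person_id")
  pcs <- paste0("pc", seq_len(config$n_pcs))
  covars <- c("year_baseline", "age_baseline", "log_income", "tenure",
              "smoker", "sex", "firm_size", "industry_service", pcs)
  prop_covars <- c(covars, "mpgs", "vpgs")

  prop <- fit_propensity(frame, treated = "treated",
                         covariates = prop_covars)
  support <- trim_common_support(prop, frame$treated)
  strata <- paste(frame$year_baseline, frame$sex, sep = "_")
  mw <- kernel_match_weights(prop, frame$treated, strata = strata,
                             bandwidth = 0.06, on_support = support)
  balance <- balance_table(frame, treated = "treated",
                           covariates = c(prop_covars, "bmi_lag"),
                           weights = mw)
  did <- fit_did(frame, covariates = covars, weights = mw)

  att_grid <- att_grid %||% dplyr::bind_rows(
    tibble::tibble(mpgs = seq(-2, 2), vpgs = 0),
    tibble::tibble(mpgs = 0, vpgs = seq(-2, 2))
  ) |> dplyr::distinct()
  att <- att_by_genotype(did, grid = att_grid)

  ets_frame <- build_ets_frame(panel)
  ets_frame <- dplyr::left_join(ets_frame, scores, by = "person_id")
  ctrl_w <- frame |>
    dplyr::mutate(.weight = mw$observations$weight) |>
    dplyr::filter(.data$treated == 0L) |>
    dplyr::select("person_id", "wave", ".weight")
  treated_support <- frame$person_id[frame$treated == 1L &
                                       mw$observations$on_support]
  ets_frame <- dplyr::left_join(ets_frame, ctrl_w,
                                by = c("person_id", "wave"))
  ets_w <- dplyr::case_when(
    ets_frame$treated == 1L & ets_frame$person_id %in% treated_support ~ 1,
    ets_frame$treated == 1L ~ 0,
    TRUE ~ dplyr::coalesce(ets_frame$.weight, 0)
  )
  ets_frame$.weight <- NULL
  ets <- lapply(
    setNames(c("full", "below_median", "above_median"),
             c("full", "below_median", "above_median")),
    function(s) fit_ets(ets_frame, covariates = covars, weights = ets_w,
                        stratum = s)
  )

  report <- tibble::tibble(
    stage = c("simulate", "split_train", "split_test", "scan",
              "did_frame", "treated_before_support",
              "treated_after_support", "controls_matched"),
    n = c(config$n_individuals, length(split$train), length(split$test),
          nrow(scan), nrow(frame), sum(frame$treated == 1),
          mw$n_treated_on_support,
          sum(mw$observations$weight > 0 & mw$observations$treated == 0))
  )

  run <- structure(
    list(config = config, truth = truth, scan = scan,
         test_scores = test_scores, vpgs_validation = vpgs_val,
         propensity = prop, match_weights = mw, balance = balance,
         did = did, att = att, ets = ets, report = report,
         panel = panel, frame = frame),
    class = "gxe_run"
  )
  if (!is.null(output_dir)) write_run(run, output_dir,
                                      vpgs_weights, mpgs_weights)
  run
}

write_run <- function(run, output_dir, vpgs_weights, mpgs_weights) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write_panel(run$panel, file.path(output_dir, "panel.tsv"))
  write_truth(run$truth, file.path(output_dir, "truth.json"))
  write_weight_table(vpgs_weights, file.path(output_dir, "vpgs_weights.tsv"))
  write_weight_table(mpgs_weights, file.path(output_dir, "mpgs_weights.tsv"))
  coef_json <- list(
    did = run$did$coef_table,
    att = as.data.frame(run$att),
    ets = lapply(run$ets, function(e) as.data.frame(e$coef_table)),
    vpgs_validation = lapply(run$vpgs_validation, function(m) {
      list(alpha1 = m$alpha1, se = m$se_alpha1, ci = m$ci_alpha1,
           p = m$p_alpha1)
    })
  )
  jsonlite::write_json(coef_json, file.path(output_dir, "coefficients.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "columns")
  jsonlite::write_json(run$report, file.path(output_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "columns")
  md <- c(
    "# Synthetic G-by-E run report", "",
    sprintf("- individuals: %d", run$config$n_individuals),
    sprintf("- treated on support: %d (of %d)",
            run$match_weights$n_treated_on_support,
            sum(run$frame$treated == 1)),
    sprintf("- vPGS validation alpha1 (model 1): %.4f (p = %.3g)",
            run$vpgs_validation$model1$alpha1,
            run$vpgs_validation$model1$p_alpha1),
    sprintf("- DiD lambda: %.4f; BCxvPGS delta: %.4f",
            unname(run$did$coefs[run$did$terms$treated]),
            unname(run$did$coefs[run$did$terms$int_vpgs]))
  )
  writeLines(md, file.path(output_dir, "report.md"))
  invisible(output_dir)
}

#' @export
print.gxe_run <- function(x, ...) {
  cat("<gxe_run>\n")
  print(as.data.frame(x$report), row.names = FALSE)
  cat("\nvPGS validation:\n")
  print(x$vpgs_validation)
  cat("\nDiD headline terms:\n")
  print(x$did)
  invisible(x)
}
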