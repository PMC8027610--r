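# Shared builders for small in-code fixtures.

# A genotype matrix from an explicit dosage matrix.
make_genotypes <- function(dosages, effect_allele = NULL, other_allele = NULL,
                           ids = NULL) {
  m <- ncol(dosages)
  ids <- ids %||% sprintf("v%03d", seq_len(m))
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("p%03d", seq_len(nrow(dosages)))
  }
  colnames(dosages) <- ids
  varGxE:::new_genotype_matrix(
    dosages, ids,
    effect_allele %||% rep("A", m),
    other_allele %||% rep("G", m),
    maf = colMeans(dosages) / 2
  )
}

# A truth record with explicit per-variant effects.
make_truth <- function(mean_betas, var_alphas,
                       att = c(lambda = 0, vartheta = 0, delta = 0)) {
  structure(
    list(
      mean_betas = mean_betas,
      var_alphas = var_alphas,
      true_att_params = att,
      true_alpha1 = NA_real_,
      propensity_coefs = c(log_income = -0.3, tenure = -0.25,
                           smoker = 0.25, sex = 0.1, age_baseline = 0.15,
                           firm_size = -1.5, industry_service = 1.0),
      drift_coefs = c(log_income = -0.6, tenure = -0.5, smoker = 0.5,
                      sex = 0.2, age_baseline = 0.3)
    ),
    class = "truth_record"
  )
}

# Covariate sets used by the matched-DiD checks.
panel_covariates <- function(n_pcs = 4) {
  c("year_baseline", "age_baseline", "log_income", "tenure", "smoker",
    "sex", "firm_size", "industry_service", paste0("pc", seq_len(n_pcs)))
}

confounder_covariates <- function() {
  c("log_income", "tenure", "smoker", "sex", "age_baseline")
}

# One full matched-DiD pass on a simulated cohort; returns the pieces.
run_matched_did <- function(cfg, keep_pairs = FALSE) {
  g <- simulate_genotypes(cfg)
  tr <- draw_truth(g, cfg)
  panel <- simulate_panel(g, tr, cfg)
  frame <- dplyr::left_join(build_did_frame(panel),
                            attr(panel, "person_scores"), by = "person_id")
  covars <- panel_covariates(cfg$n_pcs)
  prop <- fit_propensity(frame, "treated", c(covars, "mpgs", "vpgs"))
  sup <- trim_common_support(prop, frame$treated)
  strata <- paste(frame$year_baseline, frame$sex, sep = "_")
  mw <- kernel_match_weights(prop, frame$treated, strata = strata,
                             bandwidth = 0.06, on_support = sup,
                             keep_pairs = keep_pairs)
  did <- fit_did(frame, covariates = covars, weights = mw)
  list(panel = panel, frame = frame, prop = prop, mw = mw, did = did,
       covars = covars)
}

# Matched ETS on the same weights, for a given stratum.
run_ets <- function(pieces, stratum = "full") {
  panel <- pieces$panel
  frame <- pieces$frame
  mw <- pieces$mw
  ef <- dplyr::left_join(build_ets_frame(panel),
                         attr(panel, "person_scores"), by = "person_id")
  ctrl_w <- frame |>
    dplyr::mutate(.w = mw$observations$weight) |>
    dplyr::filter(.data$treated == 0L) |>
    dplyr::select("person_id", "wave", ".w")
  tsup <- frame$person_id[frame$treated == 1L & mw$observations$on_support]
  ef <- dplyr::left_join(ef, ctrl_w, by = c("person_id", "wave"))
  ew <- ifelse(ef$treated == 1L, as.numeric(ef$person_id %in% tsup),
               dplyr::coalesce(ef$.w, 0))
  ef$.w <- NULL
  fit_ets(ef, covariates = pieces$covars, weights = ew, stratum = stratum)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
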