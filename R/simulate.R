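#' Configuration for the synthetic cohort generator
#'
#' Bundles every parameter of the synthetic study: genotype panel size and
#' allele-frequency range, the mean/variance genetic architecture, the
#' biennial BMI panel, and the confounded treatment (business-closure)
#' assignment. Defaults encode the study conditions the package is
#' validated under: a cohort of 20,000 workers aged 50-70 followed over
#' six biennial waves, a ~10% person-level business-closure rate assigned
#' by a probit latent index on firm and socioeconomic covariates, and a
#' treatment effect on BMI of
#' `att_mean + att_by_mpgs * mPGS + att_by_vpgs * vPGS` (kg/m²).
#'
#' @param n_individuals Number of individuals.
#' @param n_variants Number of biallelic variants.
#' @param maf_range Length-2 numeric in (0,1): minor allele frequencies are
#'   drawn uniformly from this range.
#' @param n_mean_causal,n_var_causal Number of variants with mean
#'   (respectively log-variance) effects on the phenotype. The two causal
#'   sets are disjoint unless `overlap_causal = TRUE`, which decorrelates
#'   mean and variance effects by construction.
#' @param mean_effect_sd SD of per-allele mean effects (phenotype units).
#' @param var_effect_sd SD of per-allele log-variance effects.
#' @param base_log_var Baseline log residual variance of the cross-sectional
#'   phenotype (the variance-model intercept).
#' @param treatment_fraction Target proportion of individuals experiencing
#'   a business closure.
#' @param confounding_strength Scale of the probit latent index in units of
#'   latent-index SD per covariate SD; 0 means randomized treatment.
#' @param n_waves Number of biennial panel waves (>= 2).
#' @param att_mean,att_by_mpgs,att_by_vpgs True treatment-effect parameters
#'   (lambda, vartheta, delta): main effect and its interactions with the
#'   standardized mean and variance polygenic scores, in kg/m².
#' @param att_stratum `"all"` applies the treatment effect to every treated
#'   person; `"below_median"` applies it only to treated persons at or
#'   below the cohort vPGS median (used for stratified event-study checks).
#' @param bmi_noise_sd SD of within-person BMI measurement noise (kg/m²).
#'   Self-reported BMI is noisy; the default of 1 kg/m² is a realistic
#'   magnitude for self-report error in surveys.
#' @param drift_per_wave Effect of one SD of the confounder index on the
#'   per-wave BMI slope (kg/m² per wave). Nonzero drift makes the naive
#'   unmatched difference-in-differences biased whenever
#'   `confounding_strength > 0`.
#' @param missing_rate Probability that a person's income and tenure are
#'   missing (missing completely at random), exercising the
#'   missing-indicator coding path.
#' @param n_pcs Number of simulated ancestry principal-component
#'   covariates.
#' @param overlap_causal Allow the mean- and variance-causal sets to
#'   overlap.
#' @param seed Global seed; each stochastic stage derives its own child
#'   seed from it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 20000,
                       n_variants = 100,
                       maf_range = c(0.05, 0.5),
                       n_mean_causal = 20,
                       n_var_causal = 20,
                       mean_effect_sd = 0.15,
                       var_effect_sd = 0.1,
                       base_log_var = 0,
                       treatment_fraction = 0.1,
                       confounding_strength = 2,
                       n_waves = 6,
                       att_mean = -0.1,
                       att_by_mpgs = 0,
                       att_by_vpgs = 0.25,
                       att_stratum = c("all", "below_median"),
                       bmi_noise_sd = 1,
                       drift_per_wave = 0.3,
                       missing_rate = 0.1,
                       n_pcs = 4,
                       overlap_causal = FALSE,
                       seed = 1L) {
  att_stratum <- match.arg(att_stratum)
  if (n_individuals < 1 || n_variants < 1) {
    abort("`n_individuals` and `n_variants` must be positive.")
  }
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range >= 1) ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an ordered pair inside (0, 1).")
  }
  if (n_mean_causal > n_variants || n_var_causal > n_variants) {
    abort("Causal variant counts cannot exceed `n_variants`.")
  }
  if (!overlap_causal && n_mean_causal + n_var_causal > n_variants) {
    abort("Disjoint causal sets need `n_mean_causal + n_var_causal <= n_variants`.")
  }
  if (n_waves < 2) abort("`n_waves` must be at least 2.")
  if (treatment_fraction <= 0 || treatment_fraction >= 1) {
    abort("`treatment_fraction` must be inside (0, 1).")
  }
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      n_variants = as.integer(n_variants),
      maf_range = as.numeric(maf_range),
      n_mean_causal = as.integer(n_mean_causal),
      n_var_causal = as.integer(n_var_causal),
      mean_effect_sd = mean_effect_sd,
      var_effect_sd = var_effect_sd,
      base_log_var = base_log_var,
      treatment_fraction = treatment_fraction,
      confounding_strength = confounding_strength,
      n_waves = as.integer(n_waves),
      att_mean = att_mean,
      att_by_mpgs = att_by_mpgs,
      att_by_vpgs = att_by_vpgs,
      att_stratum = att_stratum,
      bmi_noise_sd = bmi_noise_sd,
      drift_per_wave = drift_per_wave,
      missing_rate = missing_rate,
      n_pcs = as.integer(n_pcs),
      overlap_causal = overlap_causal,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a genotype dosage matrix under Hardy-Weinberg equilibrium
#'
#' Each variant's minor allele frequency is drawn uniformly from
#' `config$maf_range` and dosages are drawn independently per individual as
#' Binomial(2, maf) counts of the effect allele. Variants are in linkage
#' equilibrium by construction.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed override; by default a child seed derived
#'   from `config$seed`.
#'
#' @return A list of class `genotype_matrix` with elements `dosages`
#'   (individuals x variants numeric matrix in \[0, 2\]), `variant_ids`,
#'   `effect_allele`, `other_allele`, and `maf`.
#' @export
simulate_genotypes <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% child_seed(config$seed, "genotypes")
  n <- config$n_individuals
  m <- config$n_variants
  with_seed(seed, {
    maf <- runif(m, config$maf_range[1], config$maf_range[2])
    dosages <- vapply(maf, function(p) rbinom(n, 2L, p), numeric(n))
    dosages <- matrix(dosages, nrow = n, ncol = m)
    alleles <- t(vapply(seq_len(m), function(i) {
      sample(c("A", "C", "G", "T"), 2L)
    }, character(2)))
    ids <- sprintf("rs%06d", seq_len(m))
    dimnames(dosages) <- list(sprintf("id%06d", seq_len(n)), ids)
    new_genotype_matrix(dosages, ids, alleles[, 1], alleles[, 2], maf)
  })
}

new_genotype_matrix <- function(dosages, variant_ids, effect_allele,
                                other_allele, maf) {
  stopifnot(
    ncol(dosages) == length(variant_ids),
    !anyDuplicated(variant_ids),
    length(effect_allele) == length(variant_ids),
    length(other_allele) == length(variant_ids),
    all(dosages >= 0 & dosages <= 2)
  )
  structure(
    list(dosages = dosages, variant_ids = variant_ids,
         effect_allele = effect_allele, other_allele = other_allele,
         maf = maf),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Draw the true genetic architecture and treatment parameters
#'
#' Samples disjoint (by default) mean- and variance-causal variant sets
#' with Gaussian per-allele effects, and records the treatment-effect
#' truth and the fixed propensity coefficients. Everything downstream
#' recovery tests compare against lives in this record, stored exactly as
#' drawn.
#'
#' @inheritParams simulate_genotypes
#' @param genotypes A `genotype_matrix`.
#'
#' @return A list of class `truth_record`: `mean_betas`, `var_alphas`
#'   (per-variant, zero off the causal sets), `true_att_params`
#'   (lambda, vartheta, delta), `true_alpha1` (SD of the variance linear
#'   predictor, i.e. the dispersion effect of the standardized true vPGS),
#'   and `propensity_coefs`.
#' @export
draw_truth <- function(genotypes, config, seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "sim_config"))
  seed <- seed %||% child_seed(config$seed, "truth")
  m <- config$n_variants
  with_seed(seed, {
    mean_idx <- sample.int(m, config$n_mean_causal)
    pool <- if (config$overlap_causal) seq_len(m) else setdiff(seq_len(m), mean_idx)
    var_idx <- sample(pool, config$n_var_causal)
    mean_betas <- numeric(m)
    var_alphas <- numeric(m)
    mean_betas[mean_idx] <- rnorm(config$n_mean_causal, 0, config$mean_effect_sd)
    var_alphas[var_idx] <- rnorm(config$n_var_causal, 0, config$var_effect_sd)
    vlp <- as.vector(genotypes$dosages %*% var_alphas)
    structure(
      list(
        mean_betas = setNames(mean_betas, genotypes$variant_ids),
        var_alphas = setNames(var_alphas, genotypes$variant_ids),
        true_att_params = c(lambda = config$att_mean,
                            vartheta = config$att_by_mpgs,
                            delta = config$att_by_vpgs),
        true_alpha1 = if (sd(vlp) > 0) sd(vlp) else 0,
        # Selection into business closure: firm characteristics (size,
        # service industry) dominate — closures are firm events — with
        # more modest selection on the socioeconomic covariates that
        # also drive BMI.
        propensity_coefs = c(log_income = -0.3, tenure = -0.25,
                             smoker = 0.25, sex = 0.1, age_baseline = 0.15,
                             firm_size = -1.5, industry_service = 1.0),
        drift_coefs = c(log_income = -0.6, tenure = -0.5,
                        smoker = 0.5, sex = 0.2, age_baseline = 0.3)
      ),
      class = "truth_record"
    )
  })
}

#' True polygenic scores implied by the simulated architecture
#'
#' Computes the oracle mean and variance polygenic scores, i.e. the
#' weighted dosage sums under the true per-allele effects, standardized
#' over the cohort (zero vectors if the architecture is null).
#'
#' @param genotypes A `genotype_matrix`.
#' @param truth A `truth_record`.
#' @return A tibble with `person_id`, `mpgs`, `vpgs`.
#' @export
true_scores <- function(genotypes, truth) {
  raw_m <- as.vector(genotypes$dosages %*% truth$mean_betas)
  raw_v <- as.vector(genotypes$dosages %*% truth$var_alphas)
  std <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  tibble::tibble(
    person_id = rownames(genotypes$dosages),
    mpgs = std(raw_m),
    vpgs = std(raw_v)
  )
}

#' Simulate a cross-sectional phenotype with mean and variance architecture
#'
#' Generates `Y_i = sum_j beta_j x_ij + e_i` with
#' `e_i ~ N(0, exp(alpha0 + sum_j alpha_j x_ij))`: a phenotype whose
#' residual variance is log-linear in the variance genetic score, the
#' generative counterpart of the double generalized linear model used for
#' validation.
#'
#' @inheritParams draw_truth
#' @param truth A `truth_record`; drawn via [draw_truth()] if `NULL`.
#' @return A tibble with `person_id` and `phenotype`; the truth record is
#'   attached as attribute `"truth"`.
#' @export
simulate_phenotype <- function(genotypes, truth = NULL, config, seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "sim_config"))
  truth <- truth %||% draw_truth(genotypes, config)
  seed <- seed %||% child_seed(config$seed, "phenotype")
  mu <- as.vector(genotypes$dosages %*% truth$mean_betas)
  log_var <- config$base_log_var +
    as.vector(genotypes$dosages %*% truth$var_alphas)
  if (any(log_var > 50)) {
    abort("Variance effects too large: exp() overflow in the log-variance model.")
  }
  y <- with_seed(seed, mu + rnorm(length(mu), 0, sqrt(exp(log_var))))
  out <- tibble::tibble(person_id = rownames(genotypes$dosages), phenotype = y)
  attr(out, "truth") <- truth
  out
}

#' Assign treatment by a probit latent index on observed covariates
#'
#' Treatment (business closure between waves t-2 and t) depends only on
#' socioeconomic covariates — never on genotype — so gene-environment
#' correlation is absent by construction. The latent index is
#' `c0 + s * u_i + e_i` with `u_i` the standardized covariate index under
#' `truth$propensity_coefs`, `s = confounding_strength`, `e ~ N(0,1)`,
#' and `c0` calibrated so the marginal treated fraction matches
#' `config$treatment_fraction`. Each treated person receives one event
#' wave, drawn uniformly among waves with both a lagged wave and (where
#' the panel allows) a post-event wave.
#'
#' @param data A person-level tibble with the covariates named in
#'   `truth$propensity_coefs`, or a panel (with a `wave` column), in which
#'   case assignment uses first-wave rows and the result is joined back.
#' @param truth A `truth_record`.
#' @param config A [sim_config()].
#' @param seed Optional seed override.
#' @return The input tibble with `treated` (0/1) and `event_wave`
#'   (`NA` for controls) columns; panels additionally gain `event_time`
#'   (years relative to the reported loss).
#' @export
assign_treatment <- function(data, truth, config, seed = NULL) {
  stopifnot(inherits(truth, "truth_record"), inherits(config, "sim_config"))
  seed <- seed %||% child_seed(config$seed, "treatment")
  is_panel <- "wave" %in% names(data)
  persons <- if (is_panel) {
    dplyr::slice_min(dplyr::group_by(data, .data$person_id),
                     .data$wave, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  } else {
    data
  }
  coefs <- truth$propensity_coefs
  use <- intersect(names(coefs), names(persons))
  z <- vapply(use, function(v) {
    x <- persons[[v]]
    if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  }, numeric(nrow(persons)))
  u <- as.vector(z %*% coefs[use])
  if (sd(u) > 0) u <- u / sd(u)
  s <- config$confounding_strength
  with_seed(seed, {
    c0 <- qnorm(config$treatment_fraction) * sqrt(1 + s^2)
    for (try in 1:10) {
      treated <- rbinom(nrow(persons), 1L, pnorm(c0 + s * u))
      if (sum(treated) > 0 && sum(treated) < nrow(persons)) break
      warn("Degenerate treatment draw; resampling with adjusted intercept.")
      c0 <- c0 + if (sum(treated) == 0) 0.25 else -0.25
    }
    if (sum(treated) == 0 || sum(treated) == nrow(persons)) {
      abort("Could not draw a non-degenerate treatment assignment.")
    }
    lo <- min(3L, config$n_waves)
    hi <- max(lo, config$n_waves - 1L)
    eligible <- max(2L, lo):max(2L, hi)
    event_wave <- rep(NA_integer_, nrow(persons))
    event_wave[treated == 1L] <-
      sample(eligible, sum(treated), replace = TRUE)
    assign_tbl <- tibble::tibble(
      person_id = persons$person_id,
      treated = treated,
      event_wave = event_wave
    )
    if (is_panel) {
      out <- dplyr::left_join(data, assign_tbl, by = "person_id")
      out$event_time <- ifelse(out$treated == 1L,
                               2L * (out$wave - out$event_wave), NA_integer_)
      out
    } else {
      dplyr::left_join(data, assign_tbl, by = "person_id")
    }
  })
}

#' Simulate a biennial longitudinal BMI panel with confounded job loss
#'
#' Builds the full synthetic cohort: person-level firm and socioeconomic
#' covariates plus simulated ancestry PCs, probit treatment assignment on
#' those covariates via [assign_treatment()], and a biennial BMI
#' trajectory that mean-reverts around a person level `mu_i` loading on
#' the true mean polygenic score:
#' `BMI_iw = (1 - rho) mu_i + kappa u_i + rho BMI_i,w-1 + shock + noise`
#' with AR coefficient `rho = 0.9`. The confounder index `u_i`
#' (`kappa = drift_per_wave`) shifts each person's steady state, so raw
#' pre/post contrasts are confounded while the lagged-BMI outcome
#' regression is correctly specified. The treatment effect
#' `lambda + vartheta mPGS_i + delta vPGS_i` enters the state at the
#' event wave and decays thereafter (a transient shock).
#'
#' @inheritParams draw_truth
#' @param truth A `truth_record`; drawn if `NULL`.
#' @return A long tibble (one row per person-wave): `person_id`, `wave`,
#'   `year`, `treated`, `event_wave`, `event_time`, `bmi`, `age`, `sex`,
#'   `log_income`, `tenure`, `smoker`, `pc1..pcK`. True per-person scores
#'   are attached as attribute `"person_scores"`; the truth record as
#'   `"truth"`.
#' @export
simulate_panel <- function(genotypes, truth = NULL, config, seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "sim_config"))
  if (config$n_waves < 2) abort("`n_waves` must be at least 2.")
  truth <- truth %||% draw_truth(genotypes, config)
  seed <- seed %||% child_seed(config$seed, "panel")
  n <- config$n_individuals
  scores <- true_scores(genotypes, truth)

  with_seed(seed, {
    persons <- tibble::tibble(
      person_id = rownames(genotypes$dosages),
      sex = rbinom(n, 1L, 0.5),
      age_baseline = runif(n, 50, 70),
      log_income = rnorm(n, 11.2, 0.8),
      tenure = pmax(rnorm(n, 12, 6), 0),
      smoker = rbinom(n, 1L, 0.45),
      firm_size = rnorm(n, 4, 1.5),
      industry_service = rbinom(n, 1L, 0.3)
    )
    for (k in seq_len(config$n_pcs)) {
      persons[[paste0("pc", k)]] <- rnorm(n)
    }

    persons <- assign_treatment(persons, truth, config,
                                seed = child_seed(config$seed, "treatment"))

    # Confounder index driving the BMI slope (the socioeconomic subset of
    # the selection covariates; firm characteristics do not affect BMI).
    coefs <- truth$drift_coefs %||% truth$propensity_coefs
    use <- intersect(names(coefs), names(persons))
    z <- vapply(use, function(v) {
      x <- persons[[v]]
      if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
    }, numeric(n))
    u <- as.vector(z %*% coefs[use])
    if (sd(u) > 0) u <- u / sd(u)

    att <- truth$true_att_params
    effect <- att["lambda"] + att["vartheta"] * scores$mpgs +
      att["delta"] * scores$vpgs
    if (config$att_stratum == "below_median") {
      effect <- effect * (scores$vpgs <= stats::median(scores$vpgs))
    }

    # BMI evolves as a mean-reverting (AR) process around a person level
    # mu_i that loads on the true mean polygenic score. The confounder
    # index u shifts the per-wave inflow (kappa = drift_per_wave), so BMI
    # drifts toward a covariate-dependent steady state: a raw
    # pre/post contrast is confounded whenever selection is, while the
    # lagged-BMI outcome regression is correctly specified. The treatment
    # effect enters the state at the event wave and decays with the AR
    # coefficient thereafter (a transient shock).
    # Person levels are determined by the genetic score and the observed
    # covariates (no permanent unobserved heterogeneity): the lagged-BMI
    # outcome model assumes away unobserved permanent confounders, and
    # the generator emulates the structure the analysis assumes.
    # Persistent individual differences beyond mu_i arise from the AR
    # state itself. The 0.8 kg/m2 per SD loading puts the mean score's
    # share of between-person variance near 7%.
    mu_i <- 27.5 + 0.8 * scores$mpgs
    rho <- 0.9
    kappa <- config$drift_per_wave

    miss <- rbinom(n, 1L, config$missing_rate) == 1L
    persons$log_income[miss] <- NA_real_
    persons$tenure[rbinom(n, 1L, config$missing_rate) == 1L] <- NA_real_

    event_wave <- persons$event_wave
    bmi <- matrix(NA_real_, n, config$n_waves)
    bmi[, 1] <- mu_i + rnorm(n, 0, config$bmi_noise_sd)
    for (w in 2:config$n_waves) {
      shock <- ifelse(!is.na(event_wave) & event_wave == w, effect, 0)
      bmi[, w] <- (1 - rho) * mu_i + kappa * u + rho * bmi[, w - 1] +
        shock + rnorm(n, 0, config$bmi_noise_sd)
    }

    panel <- tidyr::expand_grid(
      person_id = persons$person_id,
      wave = seq_len(config$n_waves)
    )
    panel <- dplyr::left_join(panel, persons, by = "person_id")
    idx <- match(panel$person_id, persons$person_id)
    panel$year <- 2000L + 2L * (panel$wave - 1L)
    panel$age <- panel$age_baseline + 2 * (panel$wave - 1L)
    panel$event_time <- ifelse(panel$treated == 1L,
                               2L * (panel$wave - panel$event_wave),
                               NA_integer_)
    panel$bmi <- bmi[cbind(idx, panel$wave)]
    panel <- dplyr::select(panel, -"age_baseline")
    attr(panel, "person_scores") <- scores
    attr(panel, "truth") <- truth
    panel
  })
}

#' Split identifiers into disjoint training and test sets
#'
#' @param ids Vector of identifiers.
#' @param fraction Training fraction (default the conventional 80-20
#'   split).
#' @param seed Seed for the shuffle.
#' @return A list with `train` and `test` (disjoint, exhaustive).
#' @export
split_train_test <- function(ids, fraction = 0.8, seed = 1L) {
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1].")
  n_train <- round(fraction * length(ids))
  if (n_train == length(ids)) {
    warn("Training fraction leaves an empty test set.")
  }
  with_seed(seed, {
    train <- sort(sample(seq_along(ids), n_train))
    list(train = ids[train], test = ids[setdiff(seq_along(ids), train)])
  })
}
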