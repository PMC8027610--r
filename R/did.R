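#' Build the two-wave difference-in-differences analytic frame
#'
#' Converts a long biennial panel into the analytic sample of the matched
#' DiD design: each treated person contributes exactly one observation —
#' the post-treatment wave (event time 0), with the previous wave's BMI
#' and covariates attached as baseline (t-2) values — while control
#' persons contribute one observation per wave with a lagged wave
#' available. Controls can therefore appear in multiple waves.
#'
#' @param panel A long panel tibble as produced by [simulate_panel()]
#'   (columns `person_id`, `wave`, `year`, `treated`, `event_time`,
#'   `bmi`, `age`, plus covariates).
#' @return A tibble with one analytic observation per row: outcome `bmi`,
#'   baseline `bmi_lag`, `age_baseline`, `year_baseline`, the person's
#'   covariates, and `treated`.
#' @export
build_did_frame <- function(panel) {
  lagged <- panel |>
    dplyr::transmute(
      person_id = .data$person_id,
      wave = .data$wave + 1L,
      bmi_lag = .data$bmi,
      age_baseline = .data$age,
      year_baseline = .data$year
    )
  rows <- panel |>
    dplyr::filter(.data$wave >= 2L &
                    (.data$treated == 0L |
                       (!is.na(.data$event_time) & .data$event_time == 0L)))
  dplyr::inner_join(rows, lagged, by = c("person_id", "wave"))
}

#' Fit the weighted difference-in-differences interaction regression
#'
#' Weighted least squares of post-period BMI on the business-closure
#' indicator, the mean and variance polygenic scores, both
#' treatment-by-score interactions, lagged (baseline) BMI, and baseline
#' covariates:
#' `BMI_t = a + lambda BC + phi mPGS + vartheta BC x mPGS + theta vPGS +
#' delta BC x vPGS + tau BMI_{t-2} + X' beta + e`.
#' Treated observations carry weight 1 and controls their aggregated
#' kernel-matching weight; covariates get the same missing-indicator
#' coding as the propensity model. Inference uses an HC1 sandwich
#' covariance (optionally clustered by person), and the coefficient
#' table carries Benjamini-Hochberg adjusted p-values.
#'
#' @param data An analytic frame from [build_did_frame()] with `mpgs` and
#'   `vpgs` columns merged in.
#' @param covariates Character vector of baseline covariate columns.
#' @param weights A `match_weights` object aligned with the rows of
#'   `data`, a numeric weight vector, or `NULL` for equal weights.
#'   Zero-weight rows (off-support treated, unmatched controls) are
#'   excluded.
#' @param outcome,treated,mpgs,vpgs,lag Column names.
#' @param fdr_q FDR level for the rejection flags (default 0.05).
#' @param cluster Optional column name for cluster-robust (by-person)
#'   standard errors; default is heteroskedasticity-robust only.
#' @return An object of class `did_fit`: `coefs`, `robust_vcov`,
#'   `coef_table` (tibble with estimate, robust SE, CI, p, FDR-adjusted
#'   p), `n_treated`, `n_control`, `r_squared`, `terms` (the role-to-term
#'   mapping), `profile` (weighted means of the design columns), `model`.
#' @export
fit_did <- function(data, covariates = character(0), weights = NULL,
                    outcome = "bmi", treated = "treated",
                    mpgs = "mpgs", vpgs = "vpgs", lag = "bmi_lag",
                    fdr_q = 0.05, cluster = NULL) {
  w <- resolve_weights(weights, nrow(data))
  if (all(w == 0)) abort("All regression weights are zero.")
  keep <- w > 0
  dd <- data[keep, , drop = FALSE]
  w <- w[keep]
  aug <- add_missing_indicators(dd, covariates)
  dd <- aug$data
  rhs_cov <- c(covariates, aug$indicator_columns)
  f <- as.formula(paste(
    outcome, "~", treated, "+", mpgs, "+", vpgs, "+", lag,
    if (length(rhs_cov)) paste("+", paste(rhs_cov, collapse = " + ")) else "",
    "+", paste0(treated, ":", mpgs), "+", paste0(treated, ":", vpgs)
  ))
  dd$.w <- w
  fit <- lm(f, data = dd, weights = .w)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("Collinear design column(s): ", paste(bad, collapse = ", ")))
  }
  V <- if (is.null(cluster)) {
    sandwich::vcovHC(fit, type = "HC1")
  } else {
    sandwich::vcovCL(fit, cluster = dd[[cluster]], type = "HC1")
  }
  est <- coef(fit)
  se <- sqrt(diag(V))
  p <- 2 * pnorm(-abs(est / se))
  fdr <- bh_fdr(unname(p), q = fdr_q)
  coef_table <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std_error = unname(se),
    statistic = unname(est / se),
    p_value = unname(p),
    conf_low = unname(est - qnorm(0.975) * se),
    conf_high = unname(est + qnorm(0.975) * se),
    p_fdr = fdr$p_adjusted,
    fdr_significant = fdr$rejected
  )
  X <- model.matrix(fit)
  profile <- colSums(X * w) / sum(w)
  structure(
    list(
      coefs = est,
      robust_vcov = V,
      coef_table = coef_table,
      n_treated = sum(dd[[treated]] == 1),
      n_control = sum(dd[[treated]] == 0),
      r_squared = summary(fit)$r.squared,
      terms = list(treated = treated, mpgs = mpgs, vpgs = vpgs, lag = lag,
                   int_mpgs = paste0(treated, ":", mpgs),
                   int_vpgs = paste0(treated, ":", vpgs)),
      profile = profile,
      score_range = list(mpgs = range(dd[[mpgs]]), vpgs = range(dd[[vpgs]])),
      fdr_q = fdr_q,
      model = fit
    ),
    class = "did_fit"
  )
}

resolve_weights <- function(weights, n) {
  if (is.null(weights)) return(rep(1, n))
  if (inherits(weights, "match_weights")) {
    weights <- weights$observations$weight
  }
  if (length(weights) != n) {
    abort("Weights do not align with the rows of `data`.")
  }
  if (any(weights < 0)) abort("Weights must be non-negative.")
  weights
}

#' Construct a `did_fit` from printed coefficients
#'
#' Builds a minimal fitted object from a named coefficient vector (and
#' optional covariance), so treatment-effect algebra such as
#' [att_by_genotype()] can be applied to published regression tables.
#' Names must include the treatment indicator and the two
#' treatment-by-score interactions (e.g. `treated`, `treated:mpgs`,
#' `treated:vpgs`).
#'
#' @param coefs Named numeric vector.
#' @param vcov Optional covariance matrix (default zero: point algebra
#'   only).
#' @param treated,mpgs,vpgs Term names.
#' @return A `did_fit` without a stored model.
#' @export
did_fit_from_coefs <- function(coefs, vcov = NULL, treated = "treated",
                               mpgs = "mpgs", vpgs = "vpgs") {
  if (is.null(vcov)) {
    vcov <- matrix(0, length(coefs), length(coefs),
                   dimnames = list(names(coefs), names(coefs)))
  }
  structure(
    list(
      coefs = coefs,
      robust_vcov = vcov,
      coef_table = tibble::tibble(term = names(coefs),
                                  estimate = unname(coefs)),
      terms = list(treated = treated, mpgs = mpgs, vpgs = vpgs,
                   int_mpgs = paste0(treated, ":", mpgs),
                   int_vpgs = paste0(treated, ":", vpgs)),
      profile = NULL,
      score_range = NULL
    ),
    class = "did_fit"
  )
}

#' @export
print.did_fit <- function(x, ...) {
  cat("<did_fit>")
  if (!is.null(x$n_treated)) {
    cat(sprintf("  n_treated = %d, n_control = %d, R^2 = %.3f",
                x$n_treated, x$n_control, x$r_squared))
  }
  cat("\n")
  key <- unlist(x$terms[c("treated", "int_mpgs", "int_vpgs")])
  tab <- x$coef_table[x$coef_table$term %in% key, ]
  print(as.data.frame(tab), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Predicted BMI by genotype and treatment status
#'
#' Evaluates the fitted DiD regression at stated values of the mean and
#' variance polygenic scores and treatment status, holding all other
#' covariates at their weighted sample means (or a supplied profile).
#' Confidence intervals use the delta method with the robust covariance.
#'
#' @param fit A `did_fit`.
#' @param mpgs,vpgs,treated Vectors of score values and 0/1 treatment
#'   status (recycled against each other elementwise).
#' @param profile Optional named vector over the design columns; defaults
#'   to the weighted column means stored in the fit.
#' @return A tibble: `mpgs`, `vpgs`, `treated`, `predicted`, `std_error`,
#'   `conf_low`, `conf_high`.
#' @export
predict_bmi_by_genotype <- function(fit, mpgs = 0, vpgs = 0, treated = 1,
                                    profile = NULL) {
  stopifnot(inherits(fit, "did_fit"))
  grid <- tibble::tibble(mpgs = mpgs, vpgs = vpgs, treated = treated)
  profile <- profile %||% fit$profile
  if (is.null(profile)) {
    profile <- setNames(numeric(length(fit$coefs)), names(fit$coefs))
    if ("(Intercept)" %in% names(profile)) profile["(Intercept)"] <- 1
  }
  if (!is.null(fit$score_range)) {
    if (any(grid$mpgs < fit$score_range$mpgs[1] |
            grid$mpgs > fit$score_range$mpgs[2]) ||
        any(grid$vpgs < fit$score_range$vpgs[1] |
            grid$vpgs > fit$score_range$vpgs[2])) {
      warn("Score values outside the fitted range; extrapolating.")
    }
  }
  tm <- fit$terms
  out <- purrr::pmap_dfr(grid, function(mpgs, vpgs, treated) {
    x <- profile[names(fit$coefs)]
    x[tm$treated] <- treated
    x[tm$mpgs] <- mpgs
    x[tm$vpgs] <- vpgs
    x[tm$int_mpgs] <- treated * mpgs
    x[tm$int_vpgs] <- treated * vpgs
    pred <- sum(x * fit$coefs)
    se <- sqrt(as.numeric(t(x) %*% fit$robust_vcov %*% x))
    tibble::tibble(mpgs = mpgs, vpgs = vpgs, treated = treated,
                   predicted = pred, std_error = se,
                   conf_low = pred - qnorm(0.975) * se,
                   conf_high = pred + qnorm(0.975) * se)
  })
  out
}

#' Average treatment effect on the treated, by genotype
#'
#' From the fitted interaction model,
#' `ATT(m, v) = lambda + vartheta m + delta v` — the treated-minus-control
#' difference in predicted BMI at mPGS `m` and vPGS `v` — with
#' delta-method standard errors from the robust covariance of
#' (lambda, vartheta, delta).
#'
#' @param fit A `did_fit` (fitted, or from [did_fit_from_coefs()]).
#' @param mpgs,vpgs Score values; crossed into a grid unless `grid` is
#'   supplied.
#' @param grid Optional tibble with `mpgs` and `vpgs` columns.
#' @return A tibble of class `att_estimate`: `mpgs`, `vpgs`, `att`,
#'   `std_error`, `conf_low`, `conf_high`.
#' @export
att_by_genotype <- function(fit, mpgs = 0, vpgs = 0, grid = NULL) {
  stopifnot(inherits(fit, "did_fit"))
  grid <- grid %||% tidyr::expand_grid(mpgs = mpgs, vpgs = vpgs)
  tm <- fit$terms
  key <- c(tm$treated, tm$int_mpgs, tm$int_vpgs)
  if (!all(key %in% names(fit$coefs))) {
    abort(paste0("Fit lacks coefficient(s): ",
                 paste(setdiff(key, names(fit$coefs)), collapse = ", ")))
  }
  b <- fit$coefs[key]
  V <- fit$robust_vcov[key, key]
  out <- grid |>
    dplyr::mutate(
      att = b[1] + b[2] * .data$mpgs + b[3] * .data$vpgs,
      std_error = purrr::map2_dbl(.data$mpgs, .data$vpgs, function(m, v) {
        cvec <- c(1, m, v)
        sqrt(as.numeric(t(cvec) %*% V %*% cvec))
      }),
      conf_low = .data$att - qnorm(0.975) * .data$std_error,
      conf_high = .data$att + qnorm(0.975) * .data$std_error
    )
  class(out) <- c("att_estimate", class(out))
  out
}

#' Benjamini-Hochberg step-up false discovery rate control
#'
#' Given `m` p-values, the step-up procedure rejects hypotheses
#' `1..k*` (in ascending p order) where `k*` is the largest `k` with
#' `p_(k) <= k q / m`. Adjusted p-values are
#' `min_{j >= k} (m p_(j) / j)`, capped at 1; a hypothesis is rejected
#' iff its adjusted p-value is at most `q`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return A tibble in input order: `p_value`, `p_adjusted`, `rejected`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0) {
    return(tibble::tibble(p_value = numeric(0), p_adjusted = numeric(0),
                          rejected = logical(0)))
  }
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  adj_sorted <- rev(cummin(rev(m * ranked / seq_len(m))))
  adj_sorted <- pmin(adj_sorted, 1)
  adjusted <- numeric(m)
  adjusted[ord] <- adj_sorted
  tibble::tibble(p_value = p, p_adjusted = adjusted,
                 rejected = adjusted <= q)
}

#' Build the event-time-study analytic frame
#'
#' Like [build_did_frame()] but treated persons contribute observations
#' at event times -4, -2, 0 and +2 years (where the panel covers them),
#' each with its own lagged-wave baseline; controls contribute all waves
#' with a lag. Adds treatment-by-event-time indicator columns `ev_m4`,
#' `ev_0`, `ev_p2`; event time -2 is the omitted reference category.
#'
#' @inheritParams build_did_frame
#' @return A tibble of analytic observations with event indicators.
#' @export
build_ets_frame <- function(panel) {
  lagged <- panel |>
    dplyr::transmute(
      person_id = .data$person_id,
      wave = .data$wave + 1L,
      bmi_lag = .data$bmi,
      age_baseline = .data$age,
      year_baseline = .data$year
    )
  rows <- panel |>
    dplyr::filter(.data$wave >= 2L &
                    (.data$treated == 0L |
                       (!is.na(.data$event_time) &
                          .data$event_time %in% c(-4L, -2L, 0L, 2L))))
  out <- dplyr::inner_join(rows, lagged, by = c("person_id", "wave"))
  out$ev_m4 <- as.numeric(out$treated == 1L & !is.na(out$event_time) &
                            out$event_time == -4L)
  out$ev_0 <- as.numeric(out$treated == 1L & !is.na(out$event_time) &
                           out$event_time == 0L)
  out$ev_p2 <- as.numeric(out$treated == 1L & !is.na(out$event_time) &
                            out$event_time == 2L)
  out
}

#' Fit the event-time study regression
#'
#' Weighted regression of BMI on treatment-by-event-time indicators
#' (reference: the wave prior to treatment, event time -2), the mean
#' polygenic score, lagged BMI, and baseline covariates, with HC1 robust
#' standard errors. The full-sample variant additionally controls for
#' the vPGS; stratified variants restrict to persons below (at) or above
#' the vPGS median, computed over the distinct persons of the analytic
#' sample with ties assigned to the lower stratum. Near-zero pre-event
#' coefficients (`ev_m4`) support the parallel-trends assumption.
#'
#' @param data A frame from [build_ets_frame()] with `mpgs`/`vpgs`
#'   merged in and (typically) a weight vector from the baseline match.
#' @param covariates Character vector of baseline covariate columns.
#' @param weights As in [fit_did()].
#' @param stratum `"full"`, `"below_median"` or `"above_median"`.
#' @param outcome,treated,mpgs,vpgs,lag Column names.
#' @return An object of class `ets_fit`: `coef_table` for the event
#'   terms (term, event_time, estimate, robust SE, CI, p), `stratum`,
#'   `n_treated`, `n_control`, full `coefs` and `robust_vcov`, `model`.
#' @export
fit_ets <- function(data, covariates = character(0), weights = NULL,
                    stratum = c("full", "below_median", "above_median"),
                    outcome = "bmi", treated = "treated",
                    mpgs = "mpgs", vpgs = "vpgs", lag = "bmi_lag") {
  stratum <- match.arg(stratum)
  w <- resolve_weights(weights, nrow(data))
  if (stratum != "full") {
    med <- stats::median(unique(data.frame(id = data$person_id,
                                           v = data[[vpgs]]))$v)
    keep_person <- if (stratum == "below_median") {
      data[[vpgs]] <= med
    } else {
      data[[vpgs]] > med
    }
    data <- data[keep_person, , drop = FALSE]
    w <- w[keep_person]
  }
  keep <- w > 0
  dd <- data[keep, , drop = FALSE]
  w <- w[keep]
  if (nrow(dd) == 0) abort("No observations left after weighting/stratifying.")
  ev_terms <- c("ev_m4", "ev_0", "ev_p2")
  present <- ev_terms[vapply(ev_terms, function(v) sum(dd[[v]]) > 0, logical(1))]
  dropped <- setdiff(ev_terms, present)
  if (length(dropped)) {
    warn(paste0("No treated observations for event term(s): ",
                paste(dropped, collapse = ", "), "; omitted."))
  }
  aug <- add_missing_indicators(dd, covariates)
  dd <- aug$data
  rhs_cov <- c(covariates, aug$indicator_columns)
  rhs <- c(present, mpgs, if (stratum == "full") vpgs, lag, rhs_cov)
  f <- as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
  dd$.w <- w
  fit <- lm(f, data = dd, weights = .w)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("Collinear design column(s): ", paste(bad, collapse = ", ")))
  }
  V <- sandwich::vcovHC(fit, type = "HC1")
  est <- coef(fit)[present]
  se <- sqrt(diag(V)[present])
  coef_table <- tibble::tibble(
    term = present,
    event_time = c(ev_m4 = -4, ev_0 = 0, ev_p2 = 2)[present],
    estimate = unname(est),
    std_error = unname(se),
    p_value = 2 * pnorm(-abs(unname(est / se))),
    conf_low = unname(est - qnorm(0.975) * se),
    conf_high = unname(est + qnorm(0.975) * se)
  )
  structure(
    list(
      coef_table = coef_table,
      stratum = stratum,
      n_treated = sum(dd[[treated]] == 1),
      n_control = sum(dd[[treated]] == 0),
      coefs = coef(fit),
      robust_vcov = V,
      model = fit
    ),
    class = "ets_fit"
  )
}

#' @export
print.ets_fit <- function(x, ...) {
  cat(sprintf("<ets_fit> stratum = %s (reference: event time -2)\n",
              x$stratum))
  print(as.data.frame(x$coef_table), row.names = FALSE, digits = 3)
  invisible(x)
}
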