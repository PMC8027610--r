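#' Fit a probit propensity-score model with missing-indicator coding
#'
#' Estimates the probability of treatment (business closure) given
#' baseline covariates by probit regression. Covariates with missing
#' values are handled by the missing-indicator convention: missing
#' entries are set to zero and a dichotomous `<name>_missing` column is
#' appended, so matching is on observed values and on the missingness
#' pattern. Collinear columns are dropped (and reported) before fitting.
#'
#' @param data Data frame of baseline (t-2) observations.
#' @param treated Name of the 0/1 treatment column.
#' @param covariates Character vector of covariate columns.
#' @return An object of class `propensity_model`: `coefs`,
#'   `fitted_probabilities` (strictly inside (0,1)), `converged`,
#'   `dropped_columns`, `indicator_columns`, and the augmented design
#'   `data` used.
#' @export
fit_propensity <- function(data, treated, covariates) {
  tr <- data[[treated]]
  if (is.null(tr)) abort(sprintf("Column `%s` not found.", treated))
  if (length(unique(tr)) < 2) {
    abort("Both treated and control observations are required.")
  }
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov)) {
    abort(paste0("Covariate(s) not found: ", paste(missing_cov, collapse = ", ")))
  }
  aug <- add_missing_indicators(data, covariates)
  design_cols <- c(covariates, aug$indicator_columns)
  X <- dglm_design(aug$data, design_cols)
  da <- drop_aliased(X)
  if (length(da$dropped)) {
    inform(paste0("Dropped collinear column(s): ",
                  paste(da$dropped, collapse = ", ")))
  }
  fit <- suppressWarnings(stats::glm.fit(
    da$X, tr, family = binomial(link = "probit"),
    control = glm.control(epsilon = 1e-12, maxit = 100)
  ))
  p <- fit$fitted.values
  if (all((p > 0.5) == (tr == 1)) && (max(p[tr == 0]) < 1e-6 ||
                                      min(p[tr == 1]) > 1 - 1e-6)) {
    abort("Perfect separation in the propensity model; reduce the covariate set.")
  }
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  structure(
    list(
      coefs = fit$coefficients,
      fitted_probabilities = p,
      converged = fit$converged,
      dropped_columns = da$dropped,
      indicator_columns = aug$indicator_columns,
      data = aug$data
    ),
    class = "propensity_model"
  )
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf("<propensity_model> %d coefficients, converged = %s\n",
              length(x$coefs), x$converged))
  invisible(x)
}

#' Trim treated observations to the region of common support
#'
#' A treated observation is on support iff its propensity score lies
#' inside the closed interval `[min, max]` of the control propensity
#' scores; controls are never dropped.
#'
#' @param propensity Numeric propensity scores (or a `propensity_model`).
#' @param treated 0/1 treatment vector.
#' @return Logical vector: `TRUE` for on-support observations.
#' @export
trim_common_support <- function(propensity, treated) {
  if (inherits(propensity, "propensity_model")) {
    propensity <- propensity$fitted_probabilities
  }
  if (!any(treated == 0)) abort("No control observations.")
  lo <- min(propensity[treated == 0])
  hi <- max(propensity[treated == 0])
  ifelse(treated == 1, propensity >= lo & propensity <= hi, TRUE)
}

epanechnikov <- function(u) ifelse(abs(u) <= 1, 0.75 * (1 - u^2), 0)

#' Epanechnikov kernel matching weights within exact-match strata
#'
#' For each on-support treated observation `i`, every control `j` in the
#' same exact-match stratum receives weight
#' `w(i,j) = K[(P_j - P_i)/b] / sum_m K[(P_m - P_i)/b]` with the
#' Epanechnikov kernel `K(u) = 0.75 (1 - u^2)` on `|u| <= 1` and
#' bandwidth `b`. Matching is with replacement. Treated observations with
#' zero total kernel mass in their stratum (or an empty control stratum)
#' are flagged off support. The per-control aggregate
#' `W_j = sum_i w(i,j)` is emitted for the weighted outcome regression.
#'
#' @param propensity Numeric propensity scores (or a `propensity_model`).
#' @param treated 0/1 treatment vector.
#' @param strata Optional exact-match key per observation (e.g.
#'   interaction of survey year and sex); `NULL` for a single stratum.
#' @param bandwidth Kernel bandwidth (default 0.06).
#' @param on_support Optional logical from [trim_common_support()];
#'   computed internally if `NULL`.
#' @param keep_pairs Store the full treated-control pair weights (memory
#'   grows with n_treated x n_control per stratum; default `FALSE`).
#' @return An object of class `match_weights` with `observations` (a
#'   tibble: `index`, `treated`, `stratum`, `on_support`, `weight` —
#'   1 for on-support treated, `W_j` for controls) and optionally
#'   `pairs` (`treated_index`, `control_index`, `weight`).
#' @export
kernel_match_weights <- function(propensity, treated, strata = NULL,
                                 bandwidth = 0.06, on_support = NULL,
                                 keep_pairs = FALSE) {
  if (inherits(propensity, "propensity_model")) {
    propensity <- propensity$fitted_probabilities
  }
  if (bandwidth <= 0) abort("`bandwidth` must be positive.")
  n <- length(propensity)
  stopifnot(length(treated) == n)
  strata <- if (is.null(strata)) rep("all", n) else as.character(strata)
  on_support <- on_support %||% trim_common_support(propensity, treated)
  if (!any(treated == 1 & on_support)) {
    abort("No on-support treated observations.")
  }

  weight <- numeric(n)
  support <- on_support
  pair_list <- list()
  for (s in unique(strata)) {
    t_idx <- which(strata == s & treated == 1 & on_support)
    c_idx <- which(strata == s & treated == 0)
    if (length(t_idx) == 0) next
    if (length(c_idx) == 0) {
      warn(sprintf("Stratum '%s' has treated observations but no controls; flagged off support.", s))
      support[t_idx] <- FALSE
      next
    }
    u <- outer(propensity[c_idx], propensity[t_idx], "-") / bandwidth
    K <- epanechnikov(u)  # controls x treated
    mass <- colSums(K)
    zero <- mass <= 0
    if (any(zero)) {
      support[t_idx[zero]] <- FALSE
      K <- K[, !zero, drop = FALSE]
      mass <- mass[!zero]
      t_idx <- t_idx[!zero]
    }
    if (length(t_idx) == 0) next
    W <- sweep(K, 2, mass, "/")
    weight[c_idx] <- weight[c_idx] + rowSums(W)
    weight[t_idx] <- 1
    if (keep_pairs) {
      nz <- which(W > 0, arr.ind = TRUE)
      pair_list[[s]] <- tibble::tibble(
        treated_index = t_idx[nz[, 2]],
        control_index = c_idx[nz[, 1]],
        weight = W[nz]
      )
    }
  }
  obs <- tibble::tibble(
    index = seq_len(n),
    treated = as.integer(treated),
    stratum = strata,
    on_support = support,
    weight = weight
  )
  structure(
    list(
      observations = obs,
      pairs = if (keep_pairs) dplyr::bind_rows(pair_list) else NULL,
      bandwidth = bandwidth,
      n_treated_on_support = sum(support & treated == 1),
      n_treated_dropped = sum(treated == 1) - sum(support & treated == 1)
    ),
    class = "match_weights"
  )
}

#' @export
print.match_weights <- function(x, ...) {
  cat(sprintf("<match_weights> bandwidth %.3f: %d treated on support (%d dropped), %d controls with positive weight\n",
              x$bandwidth, x$n_treated_on_support, x$n_treated_dropped,
              sum(x$observations$weight > 0 & x$observations$treated == 0)))
  invisible(x)
}

#' Standardized bias of a covariate between treated and controls
#'
#' `SB = 100 (Xbar_T - Xbar_C) / sqrt((s2_T + s2_C) / 2)`: the mean
#' difference as a percentage of the square root of the average of the
#' two group variances. For the matched version, supply per-control
#' `control_weights`; the control mean is then weighted while the
#' denominator always uses the unmatched group variances, keeping
#' matched and unmatched rows on a common scale.
#'
#' @param x Covariate values.
#' @param treated 0/1 treatment vector.
#' @param weights Optional non-negative matching weights. A vector the
#'   length of `x` weights both groups (on-support treated carry weight
#'   1 and off-support treated 0, so matched-sample statistics cover the
#'   matched treated only); a vector the length of the control group
#'   weights controls only.
#' @return Standardized bias in percent (treated minus control);
#'   `NA` when the pooled variance is zero.
#' @export
standardized_bias <- function(x, treated, weights = NULL) {
  xt <- x[treated == 1]
  xc <- x[treated == 0]
  v <- (var(xt) + var(xc)) / 2
  if (!is.finite(v) || v <= 0) return(NA_real_)
  if (is.null(weights)) {
    mt <- mean(xt)
    mc <- mean(xc)
  } else if (length(weights) == length(x)) {
    wt <- weights[treated == 1]
    wc <- weights[treated == 0]
    stopifnot(all(weights >= 0), sum(wt) > 0, sum(wc) > 0)
    mt <- wtd_mean(xt, wt)
    mc <- wtd_mean(xc, wc)
  } else {
    wc <- weights
    stopifnot(length(wc) == length(xc), all(wc >= 0), sum(wc) > 0)
    mt <- mean(xt)
    mc <- wtd_mean(xc, wc)
  }
  100 * (mt - mc) / sqrt(v)
}

#' Covariate balance table before and after matching
#'
#' For every covariate, reports treated and control means, standardized
#' bias, a Welch two-sample t-test p-value, and (for continuous
#' covariates) the treated/control variance ratio — once on the raw
#' (unmatched) sample and once applying the matching weights to the
#' controls. A covariate is flagged imbalanced when `|SB| > 5` percent or
#' the t-test p-value is below 0.05.
#'
#' @param data Data frame of baseline observations.
#' @param treated Name of the 0/1 treatment column.
#' @param covariates Character vector of covariate columns.
#' @param weights A `match_weights` object, or a numeric weight vector
#'   aligned with the rows of `data`.
#' @return A tibble of class `balance_table`: `covariate`, `sample`
#'   ("unmatched"/"matched"), `mean_treated`, `mean_control`, `std_bias`,
#'   `t_p_value`, `variance_ratio`, `flagged`.
#' @export
balance_table <- function(data, treated, covariates, weights = NULL) {
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov)) {
    abort(paste0("Covariate(s) not found: ", paste(missing_cov, collapse = ", ")))
  }
  tr <- data[[treated]]
  w <- if (inherits(weights, "match_weights")) {
    weights$observations$weight
  } else {
    weights
  }
  rows <- list()
  for (v in covariates) {
    x <- data[[v]]
    ok <- !is.na(x)
    xt <- x[ok & tr == 1]
    xc <- x[ok & tr == 0]
    binary <- length(unique(x[ok])) <= 2
    vr <- if (binary) NA_real_ else var(xt) / var(xc)
    tt <- tryCatch(t.test(xt, xc)$p.value, error = function(e) NA_real_)
    rows[[paste0(v, "_U")]] <- tibble::tibble(
      covariate = v, sample = "unmatched",
      mean_treated = mean(xt), mean_control = mean(xc),
      std_bias = standardized_bias(x[ok], tr[ok]),
      t_p_value = tt, variance_ratio = vr
    )
    if (!is.null(w)) {
      wt <- w[ok & tr == 1]
      wc <- w[ok & tr == 0]
      xt_m <- xt[wt > 0]  # the matched treated sample
      mt <- mean(xt_m)
      mc <- wtd_mean(xc, wc)
      vc <- wtd_var(xc, wc)
      n_t <- length(xt_m)
      n_eff <- sum(wc)^2 / sum(wc^2)
      se <- sqrt(var(xt_m) / n_t + vc / n_eff)
      df <- (var(xt_m) / n_t + vc / n_eff)^2 /
        ((var(xt_m) / n_t)^2 / (n_t - 1) + (vc / n_eff)^2 / (n_eff - 1))
      tt_m <- 2 * stats::pt(-abs((mt - mc) / se), df)
      rows[[paste0(v, "_M")]] <- tibble::tibble(
        covariate = v, sample = "matched",
        mean_treated = mt, mean_control = mc,
        std_bias = standardized_bias(x[ok], tr[ok], weights = w[ok]),
        t_p_value = tt_m,
        variance_ratio = if (binary) NA_real_ else var(xt_m) / vc
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$flagged <- (abs(out$std_bias) > 5 |
                    (!is.na(out$t_p_value) & out$t_p_value < 0.05))
  class(out) <- c("balance_table", class(out))
  out
}
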