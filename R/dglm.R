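#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles of their fractional ranks,
#' `qnorm((r_i - c) / (n - 2c + 1))` with the Blom offset `c = 3/8`.
#' Ties receive average ranks; the transform is strictly monotone on
#' untied input. Phenotypes are transformed this way before variance
#' modelling so that dispersion effects are not artefacts of a skewed
#' scale.
#'
#' @param x Numeric vector (no missing values; length >= 2).
#' @param offset Rank offset `c` (default 3/8).
#' @return Numeric vector of transformed values.
#' @export
inverse_normal_transform <- function(x, offset = 3 / 8) {
  if (anyNA(x)) abort("Missing values are not allowed.")
  n <- length(x)
  if (n < 2) abort("Need at least two values to rank-transform.")
  r <- rank(x, ties.method = "average")
  qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Percent change in phenotype SD per unit score
#'
#' Converts a log-linear variance (dispersion) coefficient into the
#' percent change in the phenotype's standard deviation implied by a
#' one-unit (one SD, for standardized scores) increase in the score:
#' `100 * (sqrt(exp(alpha1)) - 1)`.
#'
#' @param alpha1 Dispersion coefficient(s) on the log-variance scale.
#' @return Percent change in SD (vectorized).
#' @export
interpret_sd_change <- function(alpha1) {
  100 * (sqrt(exp(alpha1)) - 1)
}

#' Fit a double generalized linear model (mean and log-variance submodels)
#'
#' Fits `y_i = Xm_i' gamma + e_i`, `e_i ~ N(0, exp(Zv_i' alpha))` by the
#' standard alternating algorithm for this model class: (a) the mean
#' submodel by weighted least squares with weights `exp(-Zv' alpha)`;
#' (b) the variance submodel by a gamma generalized linear model with log
#' link fitted to leverage-adjusted squared residuals `d_i / (1 - h_i)`
#' with prior weights `(1 - h_i) / 2` (REML-style; set `reml = FALSE` for
#' the maximum-likelihood variant without leverage adjustment).
#' Iteration stops when the Gaussian log-likelihood changes by less than
#' `tol`. Wald inference for the score's dispersion coefficient comes
#' from the variance-submodel information.
#'
#' @param data A data frame.
#' @param response Name of the response column.
#' @param score Name of the score column (its dispersion coefficient is
#'   the parameter of interest); `NULL` for an intercept-only score-free
#'   fit.
#' @param covariates Character vector of covariate columns entering both
#'   submodels.
#' @param var_covariates Covariates for the variance submodel (defaults
#'   to `covariates`).
#' @param score_in_variance Include the score in the variance submodel
#'   (default). With `FALSE` and no `var_covariates` the variance
#'   submodel is intercept-only and the mean submodel coincides with
#'   ordinary least squares.
#' @param reml Use the leverage-adjusted (REML-style) variance step
#'   (default); `FALSE` gives the plain ML alternation, under which the
#'   reported log-likelihood is non-decreasing across iterations.
#' @param max_iter,tol Iteration controls.
#' @return An object of class `dglm_fit`: `mean_coefs`, `var_coefs`,
#'   `mean_vcov`, `var_vcov`, `se_alpha1`, `ci_alpha1`, `p_alpha1`,
#'   `n_iter`, `converged`, `loglik`, `loglik_trace`, `n`, `score`.
#' @export
fit_dglm <- function(data, response, score = NULL, covariates = NULL,
                     var_covariates = covariates, reml = TRUE,
                     score_in_variance = TRUE, max_iter = 50L, tol = 1e-8) {
  y <- data[[response]]
  if (is.null(y)) abort(sprintf("Column `%s` not found.", response))
  if (any(!is.finite(y))) abort("Response must be finite.")
  mean_terms <- c(score, covariates)
  var_terms <- c(if (score_in_variance) score, var_covariates)
  Xm <- dglm_design(data, mean_terms)
  Zv <- dglm_design(data, var_terms)
  n <- length(y)
  if (n <= max(ncol(Xm), ncol(Zv))) {
    abort("Need more observations than parameters in both submodels.")
  }
  check_full_rank(Xm, "mean")
  check_full_rank(Zv, "variance")

  alpha <- numeric(ncol(Zv))
  fit0 <- lm.fit(Xm, y)
  alpha[1] <- log(max(mean(fit0$residuals^2), .Machine$double.eps))
  loglik_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  beta <- NULL
  h <- NULL
  for (iter in seq_len(max_iter)) {
    phi <- exp(as.vector(Zv %*% alpha))
    w <- 1 / phi
    mfit <- lm.wfit(Xm, y, w)
    beta <- mfit$coefficients
    d <- (y - as.vector(Xm %*% beta))^2
    A <- solve(crossprod(Xm * sqrt(w)))
    h <- rowSums((Xm %*% A) * Xm) * w
    h <- pmin(h, 1 - 1e-8)
    if (reml) {
      resp <- d / (1 - h)
      pw <- (1 - h) / 2
    } else {
      resp <- d
      pw <- rep(0.5, n)
    }
    resp <- pmax(resp, .Machine$double.eps * max(mean(d), 1))
    vfit <- suppressWarnings(stats::glm.fit(
      Zv, resp, weights = pw, family = Gamma(link = "log"),
      etastart = as.vector(Zv %*% alpha),
      control = glm.control(epsilon = 1e-10, maxit = 100)
    ))
    alpha <- vfit$coefficients
    phi_new <- exp(as.vector(Zv %*% alpha))
    ll <- -0.5 * sum(log(2 * pi * phi_new) + d / phi_new)
    loglik_trace <- c(loglik_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged) {
    warn(sprintf("DGLM did not converge in %d iterations.", max_iter))
  }

  phi <- exp(as.vector(Zv %*% alpha))
  mean_vcov <- solve(crossprod(Xm / sqrt(phi)))
  wv <- if (reml) (1 - h) else rep(1, n)
  var_vcov <- 2 * solve(crossprod(Zv * sqrt(wv)))
  dimnames(mean_vcov) <- list(colnames(Xm), colnames(Xm))
  dimnames(var_vcov) <- list(colnames(Zv), colnames(Zv))

  a1 <- se1 <- ci1 <- p1 <- NULL
  if (!is.null(score) && score %in% colnames(Zv)) {
    a1 <- unname(alpha[match(score, colnames(Zv))])
    se1 <- sqrt(var_vcov[score, score])
    ci1 <- a1 + c(-1, 1) * qnorm(0.975) * se1
    p1 <- 2 * pnorm(-abs(a1 / se1))
  }
  structure(
    list(
      mean_coefs = setNames(as.vector(beta), colnames(Xm)),
      var_coefs = setNames(as.vector(alpha), colnames(Zv)),
      mean_vcov = mean_vcov,
      var_vcov = var_vcov,
      alpha1 = a1,
      se_alpha1 = se1,
      ci_alpha1 = ci1,
      p_alpha1 = p1,
      n_iter = iter,
      converged = converged,
      loglik = loglik_trace[length(loglik_trace)],
      loglik_trace = loglik_trace,
      n = n,
      score = score,
      reml = reml
    ),
    class = "dglm_fit"
  )
}

dglm_design <- function(data, terms) {
  if (is.null(terms) || length(terms) == 0) {
    X <- matrix(1, nrow(data), 1)
    colnames(X) <- "(Intercept)"
    return(X)
  }
  missing <- setdiff(terms, names(data))
  if (length(missing)) {
    abort(paste0("Column(s) not found: ", paste(missing, collapse = ", ")))
  }
  f <- as.formula(paste("~", paste(sprintf("`%s`", terms), collapse = " + ")))
  X <- model.matrix(f, data = data)
  colnames(X) <- sub("^`|`$", "", gsub("`", "", colnames(X)))
  X
}

check_full_rank <- function(X, which) {
  r <- qr(X)
  if (r$rank < ncol(X)) {
    bad <- colnames(X)[r$pivot[(r$rank + 1):ncol(X)]]
    abort(sprintf("Singular %s-submodel design; collinear column(s): %s",
                  which, paste(bad, collapse = ", ")))
  }
  invisible(X)
}

#' @export
print.dglm_fit <- function(x, ...) {
  cat("<dglm_fit>\n")
  cat(sprintf("  n = %d, iterations = %d, converged = %s\n",
              x$n, x$n_iter, x$converged))
  if (!is.null(x$alpha1)) {
    cat(sprintf("  dispersion effect of %s: %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
                x$score, x$alpha1, x$se_alpha1, x$ci_alpha1[1],
                x$ci_alpha1[2], x$p_alpha1))
    cat(sprintf("  implied SD change per unit score: %.2f%%\n",
                interpret_sd_change(x$alpha1)))
  }
  invisible(x)
}

#' Per-variant dispersion scan
#'
#' A simplified variance-GWAS training step for unrelated samples: each
#' variant's dosage is used as the score in [fit_dglm()], yielding a mean
#' effect and a dispersion (log-variance) effect with Wald SE and
#' p-value. Variants with minor allele frequency below `maf_floor`
#' (including monomorphic variants) are skipped and counted.
#'
#' @param genotypes A `genotype_matrix`.
#' @param phenotype Numeric vector aligned with the genotype rows
#'   (typically already inverse-normal transformed), or a tibble with
#'   `person_id` and `phenotype`.
#' @param covariates Optional data frame of covariates aligned with the
#'   genotype rows.
#' @param maf_floor Minimum minor allele frequency (default 0.01).
#' @param ... Passed to [fit_dglm()].
#' @return A tibble with one row per scanned variant: `variant_id`,
#'   `maf`, `mean_effect`, `mean_se`, `dispersion_effect`,
#'   `dispersion_se`, `dispersion_p`. Skipped-variant counts are in
#'   attribute `"scan_report"`.
#' @export
dispersion_scan <- function(genotypes, phenotype, covariates = NULL,
                            maf_floor = 0.01, ...) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (is.data.frame(phenotype)) {
    idx <- match(rownames(genotypes$dosages), phenotype$person_id)
    if (anyNA(idx)) abort("Phenotype is missing some genotyped persons.")
    phenotype <- phenotype$phenotype[idx]
  }
  n <- nrow(genotypes$dosages)
  stopifnot(length(phenotype) == n)
  base <- tibble::tibble(.y = phenotype)
  cov_names <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
    cov_names <- names(covariates)
    base <- dplyr::bind_cols(base, covariates)
  }
  rows <- vector("list", ncol(genotypes$dosages))
  n_skipped <- 0L
  for (j in seq_len(ncol(genotypes$dosages))) {
    g <- genotypes$dosages[, j]
    p_hat <- mean(g) / 2
    maf <- min(p_hat, 1 - p_hat)
    if (maf < maf_floor) {
      n_skipped <- n_skipped + 1L
      next
    }
    dat <- base
    dat$.g <- g
    fit <- fit_dglm(dat, response = ".y", score = ".g",
                    covariates = cov_names, ...)
    rows[[j]] <- tibble::tibble(
      variant_id = genotypes$variant_ids[j],
      maf = maf,
      mean_effect = unname(fit$mean_coefs[".g"]),
      mean_se = sqrt(fit$mean_vcov[".g", ".g"]),
      dispersion_effect = fit$alpha1,
      dispersion_se = fit$se_alpha1,
      dispersion_p = fit$p_alpha1
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "scan_report") <- tibble::tibble(
    n_variants = ncol(genotypes$dosages),
    n_scanned = nrow(out),
    n_skipped_maf = n_skipped
  )
  out
}

#' Validate a variance polygenic score by DGLM, with and without mPGS
#'
#' Fits the validation DGLM twice on a held-out sample: Model 1 relates
#' the phenotype's log-variance to the vPGS plus covariates; Model 2
#' additionally adjusts the covariate vector for the mean polygenic
#' score. Reporting both side by side shows whether the dispersion
#' association is driven by mean effects.
#'
#' @param data Data frame with the response, scores, and covariates.
#' @param response,vpgs,mpgs Column names.
#' @param covariates Covariate column names (entering both submodels).
#' @param ... Passed to [fit_dglm()].
#' @return A list of class `vpgs_validation` with elements `model1` and
#'   `model2` (both `dglm_fit`).
#' @export
validate_vpgs <- function(data, response, vpgs = "vpgs", mpgs = "mpgs",
                          covariates = NULL, ...) {
  m1 <- fit_dglm(data, response, score = vpgs, covariates = covariates, ...)
  m2 <- fit_dglm(data, response, score = vpgs,
                 covariates = c(covariates, mpgs), ...)
  structure(list(model1 = m1, model2 = m2), class = "vpgs_validation")
}

#' @export
print.vpgs_validation <- function(x, ...) {
  cat("<vpgs_validation>  (Model 2 adjusts for the mean PGS)\n")
  for (nm in c("model1", "model2")) {
    f <- x[[nm]]
    cat(sprintf("  %s: alpha1 = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
                nm, f$alpha1, f$se_alpha1, f$ci_alpha1[1], f$ci_alpha1[2],
                f$p_alpha1))
  }
  invisible(x)
}
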