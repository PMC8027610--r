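# broom-style tidy()/glance() methods for the fitted objects.

#' Tidy a DGLM fit
#'
#' @param x A `dglm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient of both submodels:
#'   `submodel` ("mean"/"variance"), `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`, `conf_low`, `conf_high`.
#' @export
tidy.dglm_fit <- function(x, ...) {
  row <- function(submodel, coefs, vc) {
    se <- sqrt(diag(vc))
    tibble::tibble(
      submodel = submodel, term = names(coefs),
      estimate = unname(coefs), std_error = unname(se),
      statistic = unname(coefs / se),
      p_value = 2 * pnorm(-abs(unname(coefs / se))),
      conf_low = unname(coefs - qnorm(0.975) * se),
      conf_high = unname(coefs + qnorm(0.975) * se)
    )
  }
  dplyr::bind_rows(row("mean", x$mean_coefs, x$mean_vcov),
                   row("variance", x$var_coefs, x$var_vcov))
}

#' @rdname tidy.dglm_fit
#' @export
glance.dglm_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_iter = x$n_iter, converged = x$converged,
                 loglik = x$loglik,
                 alpha1 = x$alpha1 %||% NA_real_,
                 se_alpha1 = x$se_alpha1 %||% NA_real_,
                 p_alpha1 = x$p_alpha1 %||% NA_real_)
}

#' Tidy a matched DiD fit
#'
#' @param x A `did_fit`.
#' @param ... Unused.
#' @return The coefficient table tibble (estimate, robust SE, CI, p,
#'   FDR-adjusted p).
#' @export
tidy.did_fit <- function(x, ...) x$coef_table

#' @rdname tidy.did_fit
#' @export
glance.did_fit <- function(x, ...) {
  tibble::tibble(
    n_treated = x$n_treated %||% NA_integer_,
    n_control = x$n_control %||% NA_integer_,
    r_squared = x$r_squared %||% NA_real_,
    lambda = unname(x$coefs[x$terms$treated]),
    vartheta = unname(x$coefs[x$terms$int_mpgs]),
    delta = unname(x$coefs[x$terms$int_vpgs])
  )
}

#' Tidy an event-time-study fit
#'
#' @param x An `ets_fit`.
#' @param ... Unused.
#' @return The event-term coefficient tibble with a `stratum` column.
#' @export
tidy.ets_fit <- function(x, ...) {
  dplyr::mutate(x$coef_table, stratum = x$stratum)
}

#' @rdname tidy.ets_fit
#' @export
glance.ets_fit <- function(x, ...) {
  tibble::tibble(stratum = x$stratum, n_treated = x$n_treated,
                 n_control = x$n_control)
}
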