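# ggplot2 figures for the main result types.

#' Plot treatment effects by genotype
#'
#' Predicted-BMI-style figure: the ATT with its 95% confidence band
#' along one polygenic score, holding the other fixed.
#'
#' @param object An `att_estimate` tibble from [att_by_genotype()].
#' @param score Which score to put on the x axis (`"vpgs"` or
#'   `"mpgs"`); rows where the other score varies are dropped.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.att_estimate <- function(object, score = c("vpgs", "mpgs"), ...) {
  score <- match.arg(score)
  other <- setdiff(c("vpgs", "mpgs"), score)
  df <- object[object[[other]] == 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[score]], y = .data$att)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = paste("Standardized", toupper(score)),
      y = "ATT on BMI (kg/m²)",
      title = "Treatment effect on the treated by genotype"
    ) +
    ggplot2::theme_minimal()
}

#' Plot event-time-study coefficients
#'
#' Coefficient series by years relative to the reported job loss, with
#' 95% confidence bars; the reference period (-2) is drawn at zero.
#'
#' @param object An `ets_fit`, or a tibble binding several
#'   `tidy(ets_fit)` results (faceted by `stratum`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ets_fit <- function(object, ...) {
  df <- tidy(object)
  ref <- tibble::tibble(term = "ref", event_time = -2, estimate = 0,
                        std_error = 0, p_value = NA_real_,
                        conf_low = 0, conf_high = 0,
                        stratum = df$stratum[1])
  df <- dplyr::bind_rows(df, ref)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$event_time,
                                   y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = -1, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf_low,
                                          ymax = .data$conf_high)) +
    ggplot2::labs(
      x = "Years relative to job loss",
      y = "Difference in BMI, treated vs control (kg/m²)",
      title = paste0("Event-time study (", df$stratum[1], ")")
    ) +
    ggplot2::theme_minimal()
}

#' Love plot of covariate balance
#'
#' Absolute standardized bias per covariate, unmatched versus matched,
#' with the 5% balance threshold marked.
#'
#' @param object A `balance_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.balance_table <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      abs_bias = abs(.data$std_bias))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$abs_bias,
                                   y = stats::reorder(.data$covariate,
                                                      .data$abs_bias),
                                   colour = .data$sample)) +
    ggplot2::geom_vline(xintercept = 5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "|standardized bias| (%)", y = NULL,
                  colour = NULL,
                  title = "Covariate balance before and after matching") +
    ggplot2::theme_minimal()
}
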