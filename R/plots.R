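#' Forest plot of an estimator panel
#'
#' @param object An `mr_panel` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.mr_panel <- function(object, ...) {
  d <- dplyr::filter(object$results, !is.na(.data$estimate))
  null_line <- 0
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$method)) +
    ggplot2::geom_vline(xintercept = null_line, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      title = sprintf("%s on %s", object$exposure, object$outcome),
      subtitle = sprintf("%d instruments, mean F = %.1f",
                         object$n_snp, object$mean_f),
      x = sprintf("causal estimate (%s scale)", object$scale), y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of a full analysis report
#'
#' One panel per analysed pair, methods on the y axis, estimates with 95%
#' CIs on the reporting scale (odds ratios for log-odds outcomes, with the
#' null at 1).
#'
#' @param object An `mr_report` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.mr_report <- function(object, ...) {
  d <- forest_data(object)
  d$null <- ifelse(d$scale == "odds_ratio", 1, 0)
  d$pair <- paste(d$exposure, "→", d$outcome)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$method)) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$null),
                        linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~pair, scales = "free_x") +
    ggplot2::labs(x = "causal estimate (reporting scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Instrument scatter plot
#'
#' Per-variant outcome betas against exposure betas with 1 SE bars, overlaid
#' with the IVW (through the origin) and MR-Egger (free intercept) fits.
#'
#' @param h An `mr_harmonized` tibble.
#' @return A ggplot.
#' @export
plot_instruments <- function(h) {
  d <- tibble::as_tibble(h)
  ivw <- suppressWarnings(mr_ivw(h))
  layers <- list(
    ggplot2::geom_abline(slope = ivw$estimate, intercept = 0,
                         colour = "steelblue")
  )
  if (nrow(h) >= 3) {
    eg <- mr_egger(h)
    layers <- c(layers, list(
      ggplot2::geom_abline(slope = eg$estimate, intercept = eg$intercept,
                           colour = "firebrick", linetype = 2)
    ))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta_exposure, y = .data$beta_outcome)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$beta_outcome - .data$se_outcome,
                   ymax = .data$beta_outcome + .data$se_outcome),
      width = 0, colour = "grey70"
    ) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$beta_exposure - .data$se_exposure,
                   xmax = .data$beta_exposure + .data$se_exposure),
      height = 0, colour = "grey70"
    ) +
    ggplot2::geom_point(size = 1.2) +
    layers +
    ggplot2::labs(
      x = sprintf("SNP effect on %s", attr(h, "exposure")),
      y = sprintf("SNP effect on %s", attr(h, "outcome"))
    ) +
    ggplot2::theme_minimal()
}
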