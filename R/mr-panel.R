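#' Run the full two-sample MR estimator panel
#'
#' Fits the inverse-variance weighted (multiplicative random effects),
#' MR-Egger, weighted-median, simple-mode and weighted-mode estimators on one
#' harmonised instrument set, together with Cochran's Q, the Egger intercept
#' test and the mean instrument F-statistic. Methods whose preconditions fail
#' (e.g. fewer than 3 instruments for the pleiotropy-robust estimators) are
#' reported as absent rows carrying the reason in `note` rather than
#' aborting the panel.
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor Bandwidth multiplier for the mode estimators.
#' @return An object of class `mr_panel`: use [tidy()] for the per-method
#'   rows, [glance()] for a one-row summary and [autoplot()] for a forest
#'   plot.
#' @export
mr_panel <- function(h, n_boot = 1000, seed = 20240401, bandwidth_factor = 1) {
  stopifnot(nrow(h) >= 1)
  scale <- out_scale(h)
  fit_or_absent <- function(method, fun) {
    tryCatch(fun(), error = function(e) {
      mr_row(method, nrow(h), NA_real_, NA_real_, NA_real_, scale,
             note = conditionMessage(e))
    })
  }
  rows <- dplyr::bind_rows(
    fit_or_absent("ivw_mre", function() suppressWarnings(mr_ivw(h))),
    fit_or_absent("egger", function() mr_egger(h)),
    fit_or_absent("weighted_median",
                  function() mr_weighted_median(h, n_boot, seed)),
    fit_or_absent("simple_mode",
                  function() mr_mode(h, FALSE, bandwidth_factor, n_boot, seed)),
    fit_or_absent("weighted_mode",
                  function() mr_mode(h, TRUE, bandwidth_factor, n_boot, seed))
  )
  structure(
    list(
      results = rows,
      exposure = attr(h, "exposure"), outcome = attr(h, "outcome"),
      scale = scale, n_snp = nrow(h), mean_f = mean_f_statistic(h),
      n_boot = n_boot, seed = seed, bandwidth_factor = bandwidth_factor
    ),
    class = "mr_panel"
  )
}

#' @export
print.mr_panel <- function(x, ...) {
  cat(sprintf("Two-sample MR panel: %s -> %s (%d instruments, mean F = %.1f)\n",
              x$exposure, x$outcome, x$n_snp, x$mean_f))
  print(dplyr::select(x$results, "method", "estimate", "se", "ci_low",
                      "ci_high", "pvalue"))
  ivw <- x$results[x$results$method %in% c("ivw_mre", "wald_ratio"), ]
  if (nrow(ivw) == 1 && !is.na(ivw$q)) {
    cat(sprintf("Cochran's Q = %.2f on %d df (p = %.3g)\n",
                ivw$q, ivw$q_df, ivw$q_pvalue))
  }
  eg <- x$results[x$results$method == "egger", ]
  if (nrow(eg) == 1 && !is.na(eg$intercept)) {
    cat(sprintf("Egger intercept = %.4f (p = %.3g)\n",
                eg$intercept, eg$intercept_pvalue))
  }
  invisible(x)
}

#' @rdname mr_panel
#' @param x An `mr_panel` object.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.mr_panel <- function(x, ...) {
  dplyr::mutate(x$results, exposure = x$exposure, outcome = x$outcome,
                .before = 1)
}

#' @rdname mr_panel
#' @export
#' @exportS3Method generics::glance
glance.mr_panel <- function(x, ...) {
  ivw <- x$results[x$results$method %in% c("ivw_mre", "wald_ratio"), ][1, ]
  eg <- x$results[x$results$method == "egger", ]
  tibble::tibble(
    exposure = x$exposure, outcome = x$outcome, scale = x$scale,
    n_snp = x$n_snp, mean_f = x$mean_f,
    estimate_ivw = ivw$estimate, se_ivw = ivw$se, pvalue_ivw = ivw$pvalue,
    q = ivw$q, q_pvalue = ivw$q_pvalue,
    egger_intercept = if (nrow(eg)) eg$intercept[1] else NA_real_,
    egger_intercept_pvalue = if (nrow(eg)) eg$intercept_pvalue[1] else NA_real_
  )
}
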