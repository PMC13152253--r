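#' Mediation gatekeeping rule
#'
#' Two-step MR mediation is only assessed when a putative causal relationship
#' (p < `alpha`, strictly) was detected at every edge of the triangle:
#' exposure on outcome, exposure on mediator, and mediator on outcome.
#'
#' @param step_pvalues Numeric vector of the three step p-values, in the
#'   order total (exposure-outcome), a (exposure-mediator), b
#'   (mediator-outcome).
#' @param alpha Gate threshold; the conventional (and deliberately liberal)
#'   default is 0.05.
#' @return `TRUE` to proceed, `FALSE` to skip; failing steps are attached as
#'   the `"failed"` attribute.
#' @export
mediation_gate <- function(step_pvalues, alpha = 0.05) {
  stopifnot(length(step_pvalues) == 3, alpha > 0, alpha < 1)
  pass <- step_pvalues < alpha
  structure(all(pass),
            failed = c("exposure_outcome", "exposure_mediator",
                       "mediator_outcome")[!pass])
}

#' Indirect effect by the product-of-coefficients method
#'
#' The mediated (indirect) effect is the product `a * b` of the causal effect
#' of the exposure on the mediator (`a`) and of the mediator on the outcome
#' (`b`). Its standard error is the delta-method expression
#' `sqrt(b^2 se_a^2 + a^2 se_b^2 + se_a^2 se_b^2)` and the p-value is the
#' two-tailed normal probability of `estimate / se`.
#'
#' @param a,se_a Exposure-mediator causal estimate and SE.
#' @param b,se_b Mediator-outcome causal estimate and SE.
#' @return A one-row tibble with `estimate`, `se`, `pvalue`.
#' @examples
#' indirect_effect(-0.04, 0.019, -0.03, 0.010)
#' @export
indirect_effect <- function(a, se_a, b, se_b) {
  stopifnot(se_a >= 0, se_b >= 0)
  est <- a * b
  se <- sqrt(b^2 * se_a^2 + a^2 * se_b^2 + se_a^2 * se_b^2)
  p <- if (se > 0) two_sided_z_p(est / se) else clamp_p(as.numeric(est == 0))
  tibble::tibble(estimate = est, se = se, pvalue = p)
}

#' Direct effect by subtraction
#'
#' The direct effect is the total effect minus the indirect effect; its
#' standard error comes from the difference-of-two-estimates method,
#' `sqrt(se_total^2 + se_indirect^2)`, with a two-tailed normal p-value.
#'
#' @param total,se_total Total (univariable) exposure-outcome causal estimate
#'   and SE.
#' @param indirect,se_indirect Indirect effect and SE (see
#'   [indirect_effect()]).
#' @return A one-row tibble with `estimate`, `se`, `pvalue`.
#' @export
direct_effect <- function(total, se_total, indirect, se_indirect) {
  stopifnot(se_total >= 0, se_indirect >= 0)
  est <- total - indirect
  se <- sqrt(se_total^2 + se_indirect^2)
  p <- if (se > 0) two_sided_z_p(est / se) else clamp_p(as.numeric(est == 0))
  tibble::tibble(estimate = est, se = se, pvalue = p)
}

#' Mediation arithmetic from step-wise causal estimates
#'
#' Applies the gate and, when it passes, assembles total, indirect
#' (product-of-coefficients with delta-method SE) and direct
#' (difference-of-estimates) effects from three step-wise causal estimates,
#' however they were obtained. This is the pure-arithmetic core of
#' [run_two_step()]; it is exported so printed step estimates can be entered
#' directly.
#'
#' @param total,se_total,p_total Exposure-outcome estimate, SE, p-value.
#' @param a,se_a,p_a Exposure-mediator estimate, SE, p-value.
#' @param b,se_b,p_b Mediator-outcome estimate, SE, p-value.
#' @param alpha Gate threshold (see [mediation_gate()]).
#' @param proportion Also report the proportion mediated (`indirect/total`)?
#'   Off by default; a warning is attached when the total effect is weak
#'   (|Z| < 1.96) or when indirect and total effects have opposite signs.
#' @return An object of class `mr_mediation` with `steps` (the inputs),
#'   `gate_passed`, `failed_steps` and, when gated through, an `effects`
#'   tibble with one row each for total, indirect and direct effects
#'   (estimate, se, 95% CI, p-value). `tidy()` returns the effects,
#'   `glance()` a one-row summary.
#' @export
mediate_estimates <- function(total, se_total, p_total,
                              a, se_a, p_a, b, se_b, p_b,
                              alpha = 0.05, proportion = FALSE) {
  steps <- tibble::tibble(
    step = c("exposure_outcome", "exposure_mediator", "mediator_outcome"),
    estimate = c(total, a, b), se = c(se_total, se_a, se_b),
    pvalue = c(p_total, p_a, p_b)
  )
  gate <- mediation_gate(steps$pvalue, alpha)
  out <- list(steps = steps, alpha = alpha, gate_passed = as.logical(gate),
              failed_steps = attr(gate, "failed"), effects = NULL,
              proportion_mediated = NULL)
  if (gate) {
    ind <- indirect_effect(a, se_a, b, se_b)
    dir <- direct_effect(total, se_total, ind$estimate, ind$se)
    out$effects <- dplyr::mutate(
      dplyr::bind_rows(
        tibble::tibble(effect = "total", estimate = total, se = se_total,
                       pvalue = p_total),
        dplyr::mutate(ind, effect = "indirect", .before = 1),
        dplyr::mutate(dir, effect = "direct", .before = 1)
      ),
      ci_low = .data$estimate - Z95 * .data$se,
      ci_high = .data$estimate + Z95 * .data$se,
      .after = "se"
    )
    if (proportion) {
      if (total == 0) {
        warn("total effect is zero; proportion mediated undefined")
      } else {
        if (abs(total / se_total) < Z95 || sign(ind$estimate) != sign(total)) {
          warn(paste("proportion mediated is unreliable: weak total effect",
                     "or opposite-signed indirect effect"))
        }
        out$proportion_mediated <- ind$estimate / total
      }
    }
  }
  structure(out, class = "mr_mediation")
}

#' Two-step MR mediation from three summary-statistic sets
#'
#' Runs the three constituent two-sample MR analyses — exposure on outcome
#' (total effect), exposure on mediator (`a`), mediator on outcome (`b`) —
#' each by genome-wide instrument selection, optional LD clumping,
#' harmonisation and the multiplicative random-effects IVW estimator, then
#' applies the mediation gate and the product-of-coefficients /
#' difference-of-estimates arithmetic.
#'
#' @param exposure,mediator,outcome `mr_sumstats` tibbles. Instruments for
#'   the first two steps come from the exposure set, for the third from the
#'   mediator set.
#' @param p_threshold Instrument selection threshold.
#' @param ld Optional `mr_ld_table` used for clumping.
#' @param r2_threshold,window_kb Clumping parameters (see [clump_greedy()]).
#' @inheritParams mediate_estimates
#' @return An `mr_mediation` object; `steps` additionally records each step's
#'   instrument count and mean F-statistic.
#' @export
run_two_step <- function(exposure, mediator, outcome,
                         p_threshold = 5e-8, ld = NULL,
                         r2_threshold = 0.001, window_kb = 10000,
                         alpha = 0.05, proportion = FALSE) {
  step_ivw <- function(from, to) {
    inst <- select_genome_wide(from, p_threshold)
    if (!is.null(ld)) {
      ld_sub <- ld[ld$variant_id_a %in% inst$variant_id &
                     ld$variant_id_b %in% inst$variant_id, ]
      inst <- clump_greedy(inst, ld_sub, r2_threshold, window_kb)
    }
    h <- harmonize_pair(inst, to)
    dplyr::mutate(mr_ivw(h), n_snp = nrow(h), mean_f = mean_f_statistic(h))
  }
  s_total <- step_ivw(exposure, outcome)
  s_a <- step_ivw(exposure, mediator)
  s_b <- step_ivw(mediator, outcome)
  res <- mediate_estimates(
    s_total$estimate, s_total$se, s_total$pvalue,
    s_a$estimate, s_a$se, s_a$pvalue,
    s_b$estimate, s_b$se, s_b$pvalue,
    alpha = alpha, proportion = proportion
  )
  res$steps$n_snp <- c(s_total$n_snp, s_a$n_snp, s_b$n_snp)
  res$steps$mean_f <- c(s_total$mean_f, s_a$mean_f, s_b$mean_f)
  res$labels <- c(exposure = attr(exposure, "trait"),
                  mediator = attr(mediator, "trait"),
                  outcome = attr(outcome, "trait"))
  res
}

#' @export
print.mr_mediation <- function(x, ...) {
  if (!is.null(x$labels)) {
    cat(sprintf("Two-step MR mediation: %s -> %s -> %s\n",
                x$labels["exposure"], x$labels["mediator"], x$labels["outcome"]))
  } else {
    cat("Two-step MR mediation\n")
  }
  print(x$steps)
  if (x$gate_passed) {
    cat(sprintf("Gate passed (all step p < %g)\n", x$alpha))
    print(x$effects)
    if (!is.null(x$proportion_mediated)) {
      cat(sprintf("Proportion mediated: %.3f\n", x$proportion_mediated))
    }
  } else {
    cat(sprintf("Not assessed: gate failed at %s (p >= %g)\n",
                paste(x$failed_steps, collapse = ", "), x$alpha))
  }
  invisible(x)
}

#' @rdname mediate_estimates
#' @param x An `mr_mediation` object.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.mr_mediation <- function(x, ...) {
  if (!x$gate_passed) {
    return(tibble::tibble(effect = character(), estimate = numeric(),
                          se = numeric(), ci_low = numeric(),
                          ci_high = numeric(), pvalue = numeric()))
  }
  x$effects
}

#' @rdname mediate_estimates
#' @export
#' @exportS3Method generics::glance
glance.mr_mediation <- function(x, ...) {
  eff <- function(name, col) {
    if (!x$gate_passed) return(NA_real_)
    x$effects[[col]][x$effects$effect == name]
  }
  tibble::tibble(
    gate_passed = x$gate_passed,
    failed_steps = paste(x$failed_steps, collapse = ","),
    total = eff("total", "estimate"), se_total = eff("total", "se"),
    indirect = eff("indirect", "estimate"), se_indirect = eff("indirect", "se"),
    p_indirect = eff("indirect", "pvalue"),
    direct = eff("direct", "estimate"), se_direct = eff("direct", "se"),
    p_direct = eff("direct", "pvalue")
  )
}
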