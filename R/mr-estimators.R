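#' Per-variant Wald ratio
#'
#' The single-instrument causal estimate: the SNP-outcome association divided
#' by the SNP-exposure association. The standard error is the first-order
#' (no-measurement-error) approximation `se_outcome / |beta_exposure|`, which
#' ignores exposure-side sampling error; it is accurate for strong instruments
#' (F much larger than 10).
#'
#' @param beta_exposure,se_exposure,beta_outcome,se_outcome Numeric vectors of
#'   aligned per-variant estimates; `beta_exposure` must be nonzero.
#' @return A tibble with columns `estimate` and `se`.
#' @examples
#' wald_ratio(0.10, 0.01, 0.02, 0.01) # estimate 0.2, se 0.1
#' @export
wald_ratio <- function(beta_exposure, se_exposure, beta_outcome, se_outcome) {
  if (any(beta_exposure == 0)) abort("Wald ratio undefined for beta_exposure = 0")
  tibble::tibble(
    estimate = beta_outcome / beta_exposure,
    se = se_outcome / abs(beta_exposure)
  )
}

mr_row <- function(method, n_snp, estimate, se, pvalue, scale,
                   q = NA_real_, q_df = NA_integer_, q_pvalue = NA_real_,
                   intercept = NA_real_, intercept_se = NA_real_,
                   intercept_pvalue = NA_real_, note = NA_character_) {
  tibble::tibble(
    method = method, n_snp = as.integer(n_snp),
    estimate = estimate, se = se,
    ci_low = estimate - Z95 * se, ci_high = estimate + Z95 * se,
    pvalue = pvalue, scale = scale,
    q = q, q_df = as.integer(q_df), q_pvalue = q_pvalue,
    intercept = intercept, intercept_se = intercept_se,
    intercept_pvalue = intercept_pvalue, note = note
  )
}

out_scale <- function(h) attr(h, "scale_outcome") %||% "sd"

#' Inverse-variance weighted estimate (multiplicative random effects)
#'
#' Meta-analyses the per-variant Wald ratios with inverse outcome-variance
#' weights, equivalently a weighted zero-intercept regression of the outcome
#' betas on the exposure betas:
#' `estimate = sum(w * bx * by) / sum(w * bx^2)` with `w = 1/se_outcome^2`.
#' The fixed-effects standard error `1/sqrt(sum(w * bx^2))` is inflated
#' multiplicatively by the residual scale `sqrt(Q/(n-1))`, floored at 1, so
#' the random-effects SE is never below the fixed-effects one. Cochran's Q
#' against the fitted slope quantifies heterogeneity. P-values are two-sided
#' normal. With a single instrument the method degrades to the Wald ratio
#' (with a warning).
#'
#' @param h An `mr_harmonized` tibble (see [harmonize_pair()],
#'   [as_harmonized()]).
#' @return A one-row tibble with the estimate, 95% CI (1.96 SE), p-value and
#'   heterogeneity columns `q`, `q_df`, `q_pvalue`.
#' @export
mr_ivw <- function(h) {
  n <- nrow(h)
  stopifnot(n >= 1)
  if (n == 1) {
    warn("single instrument: IVW reduces to the Wald ratio")
    wr <- wald_ratio(h$beta_exposure, h$se_exposure, h$beta_outcome, h$se_outcome)
    return(mr_row("wald_ratio", 1L, wr$estimate, wr$se,
                  two_sided_z_p(wr$estimate / wr$se), out_scale(h)))
  }
  bx <- h$beta_exposure; by <- h$beta_outcome
  w <- 1 / h$se_outcome^2
  est <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- 1 / sqrt(sum(w * bx^2))
  q <- sum(w * (by - est * bx)^2)
  se <- se_fixed * max(1, sqrt(q / (n - 1)))
  mr_row("ivw_mre", n, est, se, two_sided_z_p(est / se), out_scale(h),
         q = q, q_df = n - 1L, q_pvalue = clamp_p(pchisq(q, n - 1, lower.tail = FALSE)))
}

#' MR-Egger regression
#'
#' Weighted regression of the outcome betas on the exposure betas with a free
#' intercept (weights `1/se_outcome^2`). The slope is the causal estimate; a
#' nonzero intercept indicates directional pleiotropy. Because the fit is not
#' invariant to allele coding, instruments are first re-oriented so every
#' `beta_exposure` is positive. The residual scale is floored at 1
#' (multiplicative random effects), and slope and intercept p-values use a t
#' distribution with n - 2 degrees of freedom. Requires at least 3
#' instruments.
#'
#' @inheritParams mr_ivw
#' @return A one-row tibble including `intercept`, `intercept_se`,
#'   `intercept_pvalue` and the Egger heterogeneity statistic (`q` on n - 2
#'   degrees of freedom).
#' @export
mr_egger <- function(h) {
  n <- nrow(h)
  if (n < 3) abort("MR-Egger needs at least 3 instruments")
  flip <- sign(h$beta_exposure)
  bx <- h$beta_exposure * flip
  by <- h$beta_outcome * flip
  w <- 1 / h$se_outcome^2
  # weighted least squares with intercept, solved explicitly
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  sxx <- sum(w * bx^2); sxy <- sum(w * bx * by)
  det <- sw * sxx - swx^2
  if (det <= 0) abort("degenerate design: exposure betas are constant")
  slope <- (sw * sxy - swx * swy) / det
  inter <- (sxx * swy - swx * sxy) / det
  res <- by - inter - slope * bx
  q <- sum(w * res^2)
  sigma <- sqrt(q / (n - 2))
  infl <- max(1, sigma)
  se_slope <- sqrt(sw / det) * infl
  se_inter <- sqrt(sxx / det) * infl
  p_slope <- clamp_p(2 * pt(-abs(slope / se_slope), df = n - 2))
  p_inter <- clamp_p(2 * pt(-abs(inter / se_inter), df = n - 2))
  mr_row("egger", n, slope, se_slope, p_slope, out_scale(h),
         q = q, q_df = n - 2L,
         q_pvalue = clamp_p(pchisq(q, n - 2, lower.tail = FALSE)),
         intercept = inter, intercept_se = se_inter, intercept_pvalue = p_inter)
}

weighted_median_point <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

boot_se <- function(h, point_fun, n_boot, seed) {
  withr::with_seed(seed, {
    est <- vapply(seq_len(n_boot), function(i) {
      bx <- h$beta_exposure + rnorm(nrow(h), 0, h$se_exposure)
      by <- h$beta_outcome + rnorm(nrow(h), 0, h$se_outcome)
      bx[bx == 0] <- .Machine$double.eps
      point_fun(by / bx, bx, by)
    }, numeric(1))
    sd(est)
  })
}

#' Weighted-median estimate
#'
#' Orders the per-variant Wald ratios and takes the weighted median under
#' inverse-variance weights (each ratio's variance from its Wald-ratio SE):
#' with standardised mid-cumulative weights `s_i = (cum_i - w_i/2) / sum(w)`,
#' the estimate interpolates the ratios linearly at `s = 0.5`. Consistent
#' when valid instruments carry more than half of the weight. The SE is the
#' standard deviation of the estimate over `n_boot` parametric bootstrap
#' resamples (perturbing both exposure and outcome betas by their SEs);
#' p-values are two-sided normal. Requires at least 3 instruments.
#'
#' @inheritParams mr_ivw
#' @param n_boot Number of parametric bootstrap resamples.
#' @param seed Seed for the bootstrap (recorded in the result's `note`).
#' @return A one-row tibble.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 20240401) {
  n <- nrow(h)
  if (n < 3) abort("weighted median needs at least 3 instruments")
  wr <- wald_ratio(h$beta_exposure, h$se_exposure, h$beta_outcome, h$se_outcome)
  w <- 1 / wr$se^2
  est <- weighted_median_point(wr$estimate, w)
  point <- function(r, bx, by) {
    weighted_median_point(r, bx^2 / h$se_outcome^2)
  }
  se <- boot_se(h, point, n_boot, seed)
  p <- if (se > 0) two_sided_z_p(est / se) else clamp_p(as.numeric(est == 0))
  mr_row("weighted_median", n, est, se, p, out_scale(h),
         note = sprintf("n_boot=%d seed=%d", n_boot, seed))
}

silverman_bw <- function(r, factor = 1) {
  n <- length(r)
  s <- 0.9 * min(sd(r), mad(r)) * n^(-1 / 5)
  if (!is.finite(s) || s <= 0) s <- 0.9 * sd(r) * n^(-1 / 5)
  factor * s
}

kde_mode <- function(r, w, bw, n_grid = 4096) {
  if (!is.finite(bw) || bw <= 0) return(stats::median(r))
  w <- w / sum(w)
  grid <- seq(min(r) - 3 * bw, max(r) + 3 * bw, length.out = n_grid)
  dens <- colSums(w * outer(r, grid, function(a, g) dnorm(g, a, bw)))
  grid[which.max(dens)]
}

#' Mode-based estimate (simple and weighted)
#'
#' Smooths the empirical distribution of Wald ratios with a normal kernel and
#' takes the density argmax as the causal estimate, on the premise that the
#' largest cluster of instruments is valid (zero modal pleiotropy). The
#' bandwidth is `bandwidth_factor` times the modified Silverman rule
#' `0.9 min(sd, mad) n^(-1/5)` on the ratios; the weighted variant
#' contributes each ratio with its inverse-variance weight. SE by parametric
#' bootstrap as for [mr_weighted_median()]; p-values two-sided normal.
#' Requires at least 3 instruments.
#'
#' @inheritParams mr_weighted_median
#' @param weighted Use inverse-variance weights in the kernel density?
#' @param bandwidth_factor Multiplier on the modified Silverman bandwidth.
#' @return A one-row tibble (method `"simple_mode"` or `"weighted_mode"`).
#' @export
mr_mode <- function(h, weighted = FALSE, bandwidth_factor = 1,
                    n_boot = 1000, seed = 20240401) {
  n <- nrow(h)
  if (n < 3) abort("mode estimator needs at least 3 instruments")
  wr <- wald_ratio(h$beta_exposure, h$se_exposure, h$beta_outcome, h$se_outcome)
  wts <- function(r, se_r) if (weighted) 1 / se_r^2 else rep(1, length(r))
  est <- kde_mode(wr$estimate, wts(wr$estimate, wr$se),
                  silverman_bw(wr$estimate, bandwidth_factor))
  point <- function(r, bx, by) {
    kde_mode(r, wts(r, h$se_outcome / abs(bx)), silverman_bw(r, bandwidth_factor),
             n_grid = 512)
  }
  se <- boot_se(h, point, n_boot, seed)
  p <- if (se > 0) two_sided_z_p(est / se) else clamp_p(as.numeric(est == 0))
  mr_row(if (weighted) "weighted_mode" else "simple_mode", n, est, se, p,
         out_scale(h), note = sprintf("n_boot=%d seed=%d bw_factor=%g",
                                      n_boot, seed, bandwidth_factor))
}

#' Cochran's Q heterogeneity test
#'
#' Weighted sum of squared deviations of the per-variant outcome betas from
#' the line implied by a pooled estimate:
#' `Q = sum(w * (by - beta_hat * bx)^2)` with `w = 1/se_outcome^2`, referred
#' to a chi-square distribution with n - 1 degrees of freedom.
#'
#' @inheritParams mr_ivw
#' @param beta_hat Pooled causal estimate to test against (typically the IVW
#'   estimate).
#' @return A one-row tibble with `q`, `df`, `pvalue`.
#' @export
cochran_q <- function(h, beta_hat) {
  n <- nrow(h)
  stopifnot(n >= 2)
  w <- 1 / h$se_outcome^2
  q <- sum(w * (h$beta_outcome - beta_hat * h$beta_exposure)^2)
  tibble::tibble(q = q, df = n - 1L,
                 pvalue = clamp_p(pchisq(q, n - 1, lower.tail = FALSE)))
}

#' Convert a log-odds estimate to an odds ratio with 95% CI
#'
#' @param beta Estimate on the log-odds scale.
#' @param se Its standard error.
#' @param scale Scale guard; must be `"log_odds"` or the call errors, so
#'   SD-scale estimates are never exponentiated by accident.
#' @return A tibble with `or`, `ci_low`, `ci_high`.
#' @examples
#' beta_to_or(log(1.75), 0.048)
#' @export
beta_to_or <- function(beta, se, scale = "log_odds") {
  if (!identical(scale, "log_odds")) {
    abort("beta_to_or() applies only to log-odds scale estimates")
  }
  tibble::tibble(
    or = exp(beta),
    ci_low = exp(beta - Z95 * se),
    ci_high = exp(beta + Z95 * se)
  )
}
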