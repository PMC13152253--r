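#' Weighted-linear-model partitioning of duo GWAS effects
#'
#' Maternal and fetal genotypes are correlated (each child shares half its
#' alleles with its mother), so an unadjusted GWAS of the maternal genome on a
#' pregnancy trait absorbs half of the fetal effect and vice versa. Writing
#' the unadjusted estimates as `bm_unadj = bm + bf/2` and
#' `bf_unadj = bf + bm/2`, the weighted linear model inverts this mixing; the
#' maternal-specific effect is
#'
#'   `beta_adj = (4/3) * beta_maternal - (2/3) * beta_fetal`
#'
#' (and symmetrically `(4/3) * beta_fetal - (2/3) * beta_maternal` for the
#' fetal-specific effect, provided for completeness). The standard error is
#' propagated through the same linear combination,
#' `sqrt((4/3)^2 se_m^2 + (2/3)^2 se_f^2 - 2 (4/3)(2/3) rho se_m se_f)`,
#' where `rho` is the correlation between the two GWASs' sampling errors
#' (non-zero when the maternal and fetal GWAS samples overlap; default 0).
#'
#' @param duo A data frame with columns `beta_maternal`, `se_maternal`,
#'   `beta_fetal`, `se_fetal` (unadjusted duo GWAS estimates) and optionally
#'   `overlap_correlation`.
#' @param effect Which partitioned effect to compute: `"maternal"` (default)
#'   or `"fetal"`.
#' @param overlap_correlation Sampling-error correlation in \[-1, 1\]; used
#'   when the data frame has no `overlap_correlation` column.
#' @return The input as a tibble with `beta_adj` and `se_adj` columns added.
#' @examples
#' wlm_adjust(data.frame(
#'   beta_maternal = 0.9, se_maternal = 0.01,
#'   beta_fetal = 0.6, se_fetal = 0.01
#' ))
#' @export
wlm_adjust <- function(duo, effect = c("maternal", "fetal"),
                       overlap_correlation = 0) {
  effect <- match.arg(effect)
  duo <- tibble::as_tibble(duo)
  need <- c("beta_maternal", "se_maternal", "beta_fetal", "se_fetal")
  if (!all(need %in% names(duo))) {
    abort(paste("duo data needs columns", paste(need, collapse = ", ")))
  }
  rho <- duo[["overlap_correlation"]] %||% overlap_correlation
  if (any(abs(rho) > 1)) abort("overlap_correlation must lie in [-1, 1]")
  if (any(duo$se_maternal < 0) || any(duo$se_fetal < 0)) {
    abort("standard errors must be non-negative")
  }
  if (effect == "maternal") {
    b1 <- duo$beta_maternal; b2 <- duo$beta_fetal
    s1 <- duo$se_maternal; s2 <- duo$se_fetal
  } else {
    b1 <- duo$beta_fetal; b2 <- duo$beta_maternal
    s1 <- duo$se_fetal; s2 <- duo$se_maternal
  }
  duo$beta_adj <- (4 / 3) * b1 - (2 / 3) * b2
  duo$se_adj <- wlm_se(s1, s2, rho)
  duo
}

#' @rdname wlm_adjust
#' @param se_primary,se_secondary Standard errors of the unadjusted estimate
#'   being adjusted (primary, weight 4/3) and of the other member of the duo
#'   (secondary, weight 2/3).
#' @return For `wlm_se()`: the propagated standard error(s).
#' @export
wlm_se <- function(se_primary, se_secondary, overlap_correlation = 0) {
  v <- (4 / 3)^2 * se_primary^2 + (2 / 3)^2 * se_secondary^2 -
    2 * (4 / 3) * (2 / 3) * overlap_correlation * se_primary * se_secondary
  if (any(v < 0)) {
    abort("propagated variance is negative; check overlap_correlation")
  }
  sqrt(v)
}

#' Absolute blood count from a white-cell percentage
#'
#' Converts a leukocyte subtype reported as a percentage of white blood cells
#' into an absolute count: `count = cell_percent * wbc_total / 100`.
#'
#' @param cell_percent Percentage(s) in \[0, 100\].
#' @param wbc_total Total white blood cell count(s), positive, in the same
#'   volume units as the desired result (conventionally 10^9 cells/L).
#' @return Absolute count(s).
#' @examples
#' derive_absolute_count(25, 8) # 2
#' @export
derive_absolute_count <- function(cell_percent, wbc_total) {
  if (any(!is.finite(cell_percent) | cell_percent < 0 | cell_percent > 100)) {
    abort("cell_percent must lie in [0, 100]")
  }
  if (any(!is.finite(wbc_total) | wbc_total <= 0)) {
    abort("wbc_total must be positive")
  }
  cell_percent * wbc_total / 100
}
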