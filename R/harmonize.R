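#' Harmonise exposure and outcome summary statistics
#'
#' Intersects two summary-statistic sets on `variant_id` and aligns the
#' outcome records to the exposure's effect allele so that each variant
#' contributes a coherent (beta_exposure, beta_outcome) pair:
#'
#' * outcome records whose alleles are swapped relative to the exposure
#'   (directly or after strand complement) have `beta` negated and `eaf`
#'   replaced by `1 - eaf`;
#' * palindromic variants (A/T or G/C) with missing exposure EAF, or with
#'   exposure EAF inside `palindrome_eaf_band`, are ambiguous and dropped;
#'   palindromic variants kept outside the band are aligned by allele labels
#'   and then re-oriented if the exposure and outcome EAFs disagree about
#'   which allele is the minor one;
#' * variants whose alleles cannot be reconciled even after strand
#'   complement are dropped as incompatible;
#' * variants with `beta_exposure` exactly 0 are dropped (their Wald ratio
#'   is undefined).
#'
#' @param exposure,outcome `mr_sumstats` tibbles (see [as_sumstats()]).
#' @param palindrome_eaf_band Ambiguity interval for palindromic variants.
#' @return A tibble of class `mr_harmonized` with columns `variant_id`,
#'   `chromosome`, `position`, `effect_allele`, `other_allele`,
#'   `eaf_exposure`, `beta_exposure`, `se_exposure`, `eaf_outcome`,
#'   `beta_outcome`, `se_outcome`; trait labels, scales and dropped-variant
#'   tallies (`n_dropped_missing`, `n_dropped_palindromic`,
#'   `n_dropped_incompatible`, `n_dropped_zero_exposure`) are attached as
#'   attributes and shown by [harmonization_log()].
#' @export
harmonize_pair <- function(exposure, outcome, palindrome_eaf_band = c(0.42, 0.58)) {
  stopifnot(nrow(exposure) > 0, nrow(outcome) > 0,
            length(palindrome_eaf_band) == 2)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  ex <- tibble::as_tibble(exposure)
  ou <- tibble::as_tibble(outcome)
  m <- dplyr::inner_join(ex, ou, by = "variant_id", suffix = c("_exp", "_out"))
  n_missing <- nrow(ex) - nrow(m)
  if (nrow(m) == 0) abort("exposure and outcome share no variants")

  e1 <- m$effect_allele_exp; e2 <- m$other_allele_exp
  o1 <- m$effect_allele_out; o2 <- m$other_allele_out
  is_pal <- unname(comp[e1]) == e2

  same <- o1 == e1 & o2 == e2
  swap <- o1 == e2 & o2 == e1
  csame <- unname(comp[o1]) == e1 & unname(comp[o2]) == e2
  cswap <- unname(comp[o1]) == e2 & unname(comp[o2]) == e1

  pal_ambiguous <- is_pal &
    (is.na(m$eaf_exp) |
       (m$eaf_exp >= palindrome_eaf_band[1] & m$eaf_exp <= palindrome_eaf_band[2]))

  flip <- dplyr::case_when(
    same ~ FALSE,
    swap ~ TRUE,
    !is_pal & csame ~ FALSE,
    !is_pal & cswap ~ TRUE,
    .default = NA
  )
  incompatible <- is.na(flip) & !pal_ambiguous

  # palindromic variants kept outside the band: allele labels cannot settle
  # the strand, so cross-check allele-frequency sides after label alignment
  eaf_out_aligned <- ifelse(flip %in% TRUE, 1 - m$eaf_out, m$eaf_out)
  pal_mismatch <- is_pal & !pal_ambiguous & !is.na(flip) &
    !is.na(eaf_out_aligned) & !is.na(m$eaf_exp) &
    ((m$eaf_exp < 0.5) != (eaf_out_aligned < 0.5))
  flip <- xor(flip, pal_mismatch)

  keep <- !pal_ambiguous & !incompatible
  zero_exp <- keep & m$beta_exp == 0

  res <- tibble::tibble(
    variant_id = m$variant_id,
    chromosome = m$chromosome_exp,
    position = m$position_exp,
    effect_allele = e1,
    other_allele = e2,
    eaf_exposure = m$eaf_exp,
    beta_exposure = m$beta_exp,
    se_exposure = m$se_exp,
    eaf_outcome = ifelse(flip, 1 - m$eaf_out, m$eaf_out),
    beta_outcome = ifelse(flip, -m$beta_out, m$beta_out),
    se_outcome = m$se_out
  )[keep & !zero_exp, ]

  if (nrow(res) == 0) abort("no variants left after harmonisation")
  new_harmonized(
    res,
    exposure = attr(exposure, "trait"), outcome = attr(outcome, "trait"),
    scale_exposure = attr(exposure, "scale"),
    scale_outcome = attr(outcome, "scale"),
    drops = c(
      n_dropped_missing = n_missing,
      n_dropped_palindromic = sum(pal_ambiguous),
      n_dropped_incompatible = sum(incompatible),
      n_dropped_zero_exposure = sum(zero_exp)
    )
  )
}

new_harmonized <- function(x, exposure, outcome, scale_exposure = "sd",
                           scale_outcome = "sd",
                           drops = c(n_dropped_missing = 0L,
                                     n_dropped_palindromic = 0L,
                                     n_dropped_incompatible = 0L,
                                     n_dropped_zero_exposure = 0L)) {
  structure(
    tibble::as_tibble(x),
    exposure = exposure %||% "exposure", outcome = outcome %||% "outcome",
    scale_exposure = scale_exposure, scale_outcome = scale_outcome,
    drops = drops,
    class = c("mr_harmonized", class(tibble::tibble()))
  )
}

#' Build a harmonised instrument set from aligned columns
#'
#' Convenience constructor for data that is already allele-aligned (for
#' example simulated effect pairs): wraps a data frame holding
#' `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome` (and
#' optionally `variant_id`) as an `mr_harmonized` tibble.
#'
#' @param x A data frame with the four aligned effect columns.
#' @param exposure,outcome Trait labels.
#' @param scale_outcome Scale of the outcome betas (`"sd"`, `"log_odds"`,
#'   `"z_score"`).
#' @return An `mr_harmonized` tibble.
#' @export
as_harmonized <- function(x, exposure = "exposure", outcome = "outcome",
                          scale_outcome = "sd") {
  x <- tibble::as_tibble(x)
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  if (!all(need %in% names(x))) {
    abort(paste("need columns", paste(need, collapse = ", ")))
  }
  if (!"variant_id" %in% names(x)) {
    x$variant_id <- paste0("snp_", seq_len(nrow(x)))
  }
  if (any(x$se_exposure <= 0) || any(x$se_outcome <= 0)) {
    abort("standard errors must be positive")
  }
  if (any(x$beta_exposure == 0)) abort("beta_exposure must be nonzero")
  new_harmonized(x, exposure = exposure, outcome = outcome,
                 scale_outcome = scale_outcome)
}

#' Dropped-variant tallies from harmonisation
#'
#' @param h An `mr_harmonized` tibble.
#' @return A one-row tibble of drop tallies.
#' @export
harmonization_log <- function(h) {
  d <- attr(h, "drops")
  dplyr::bind_cols(
    tibble::tibble(exposure = attr(h, "exposure"), outcome = attr(h, "outcome"),
                   n_variants = nrow(h)),
    tibble::as_tibble(as.list(d))
  )
}

#' Mean instrument F-statistic
#'
#' Mean over instruments of `(beta_exposure / se_exposure)^2`, the usual
#' strength diagnostic; values far above 10 indicate strong instruments.
#'
#' @param h An `mr_harmonized` tibble with at least one instrument.
#' @return A single number.
#' @export
mean_f_statistic <- function(h) {
  stopifnot(nrow(h) >= 1)
  mean((h$beta_exposure / h$se_exposure)^2)
}

#' Write / read a harmonised instrument set as TSV
#'
#' The trait labels and scales are stored as extra constant columns so the
#' file round-trips through [read_harmonized()].
#'
#' @param h An `mr_harmonized` tibble.
#' @param path File path.
#' @return `path` (write) or an `mr_harmonized` tibble (read).
#' @export
write_harmonized <- function(h, path) {
  out <- dplyr::mutate(
    tibble::as_tibble(h),
    exposure = attr(h, "exposure"), outcome = attr(h, "outcome"),
    scale_exposure = attr(h, "scale_exposure"),
    scale_outcome = attr(h, "scale_outcome")
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_harmonized
#' @export
read_harmonized <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta <- lapply(x[c("exposure", "outcome", "scale_exposure", "scale_outcome")],
                 function(col) col[1])
  x <- dplyr::select(x, -dplyr::all_of(c("exposure", "outcome",
                                         "scale_exposure", "scale_outcome")))
  new_harmonized(x, exposure = meta$exposure, outcome = meta$outcome,
                 scale_exposure = meta$scale_exposure,
                 scale_outcome = meta$scale_outcome)
}
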