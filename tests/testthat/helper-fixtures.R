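# programmatic fixtures and independent oracles shared across test files

make_sumstats <- function(n = 5, trait = "trait", scale = "sd",
                          beta = NULL, se = NULL, pvalue = NULL,
                          effect_allele = NULL, other_allele = NULL,
                          eaf = NULL, chromosome = NULL, position = NULL,
                          variant_id = NULL) {
  as_sumstats(
    tibble::tibble(
      variant_id = variant_id %||% paste0("rs", seq_len(n)),
      chromosome = chromosome %||% rep("1", n),
      position = position %||% (seq_len(n) * 1e6),
      effect_allele = effect_allele %||% rep("A", n),
      other_allele = other_allele %||% rep("G", n),
      eaf = eaf %||% rep(0.3, n),
      beta = beta %||% rep(0.1, n),
      se = se %||% rep(0.01, n),
      pvalue = pvalue %||% rep(1e-10, n),
      n = rep(1e5, n)
    ),
    trait = trait, scale = scale
  )
}

make_harmonized <- function(bx, by, sx = rep(0.01, length(bx)),
                            sy = rep(0.01, length(bx)), scale = "sd") {
  as_harmonized(
    tibble::tibble(beta_exposure = bx, se_exposure = sx,
                   beta_outcome = by, se_outcome = sy),
    scale_outcome = scale
  )
}

# independent weighted-least-squares oracle via stats::lm
wls_oracle <- function(bx, by, w, intercept = TRUE) {
  fit <- if (intercept) stats::lm(by ~ bx, weights = w) else
    stats::lm(by ~ 0 + bx, weights = w)
  s <- summary(fit)
  sigma <- s$sigma
  co <- s$coefficients
  list(coef = stats::coef(fit), se_unit = co[, "Std. Error"] / sigma,
       sigma = sigma, rss = sum(w * stats::resid(fit)^2))
}

# independent kernel-mode oracle via stats::density on a fine grid
density_mode_oracle <- function(r, w = rep(1, length(r)), bw) {
  d <- stats::density(r, bw = bw, weights = w / sum(w), kernel = "gaussian",
                      n = 4096, from = min(r) - 3 * bw, to = max(r) + 3 * bw)
  d$x[which.max(d$y)]
}

write_sumstat_file <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# modified Silverman bandwidth, restated independently for mode oracles
silverman_bw_oracle <- function(r) {
  s <- 0.9 * min(sd(r), mad(r)) * length(r)^(-1 / 5)
  if (!is.finite(s) || s <= 0) s <- 0.9 * sd(r) * length(r)^(-1 / 5)
  s
}
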