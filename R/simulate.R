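#' Configuration for the GWAS summary-statistic simulator
#'
#' Bundles and validates the generating parameters for
#' [simulate_mediation_study()] and [simulate_duo_study()]. The defaults
#' emulate the scale of the real studies the pipeline is aimed at: a
#' ~700,000-sample exposure GWAS whose 100 instruments explain 2% of trait
#' variance (mean instrument F around 140), a ~408,000-sample mediator GWAS
#' with large-effect instruments explaining 10% of variance, and a
#' ~270,000-sample outcome GWAS; the causal structure defaults to a direct
#' exposure-outcome effect of 0.2 plus a 0.3 x 0.5 mediated path (total
#' 0.35, all in SD units).
#'
#' @param n_snps Number of exposure-instrument SNPs.
#' @param n_snps_mediator Number of mediator-specific instrument SNPs (SNPs
#'   affecting the mediator directly rather than through the exposure).
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes.
#' @param maf_range Minor-allele-frequency interval in (0, 0.5].
#' @param h2_exposure,h2_mediator Variance in the exposure (mediator)
#'   explained jointly by its instruments; sets the instrument-effect scale.
#' @param theta_direct Direct (non-mediated) causal effect of exposure on
#'   outcome, SD units.
#' @param a_effect Causal effect of exposure on mediator (SD per SD).
#' @param b_effect Causal effect of mediator on outcome (SD per SD).
#' @param pleiotropy_mode `"none"`, `"balanced"` (direct SNP-outcome effects
#'   with mean zero) or `"directional"` (mean `pleiotropy_mean`); directional
#'   effects are defined relative to the allele that increases the
#'   instrumented trait.
#' @param pleiotropy_sd,pleiotropy_mean Scale and mean of the pleiotropic
#'   direct effects (used according to `pleiotropy_mode`).
#' @param binary_outcome Simulate the outcome on the log-odds scale?
#' @param case_fraction Case fraction for a binary outcome (SEs scale as
#'   `1/sqrt(case_fraction * (1 - case_fraction))`).
#' @param palindromic_fraction Fraction of variants given A/T or G/C alleles.
#' @param swapped_fraction Fraction of mediator/outcome records stored with
#'   swapped effect/other alleles (beta negated, EAF complemented), to
#'   exercise harmonisation.
#' @param maternal_effect_sd,fetal_effect_sd True effect scales for duo
#'   simulations.
#' @param duo_se Per-SNP standard error of the unadjusted duo GWAS estimates.
#' @param overlap_correlation Sampling-error correlation between the maternal
#'   and fetal duo GWASs.
#' @param ld_block_size,ld_within_r2 Layout of the block-diagonal LD fixture
#'   written by [write_fixture_bundle()]: variants are grouped into blocks of
#'   this size with the stated within-block r2, blocks far apart.
#' @param seed Integer seed; identical seeds give byte-identical simulations.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 100, n_snps_mediator = n_snps,
                       n_exposure = 700000, n_mediator = 408112,
                       n_outcome = 270002,
                       maf_range = c(0.05, 0.5),
                       h2_exposure = 0.02, h2_mediator = 0.10,
                       theta_direct = 0.2, a_effect = 0.3, b_effect = 0.5,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_sd = 0.02, pleiotropy_mean = 0.01,
                       binary_outcome = FALSE, case_fraction = 0.117,
                       palindromic_fraction = 0.05, swapped_fraction = 0.2,
                       maternal_effect_sd = 0.05, fetal_effect_sd = 0.05,
                       duo_se = 0.01, overlap_correlation = 0,
                       ld_block_size = 5, ld_within_r2 = 0.95,
                       seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(
    n_snps >= 1, n_snps_mediator >= 0,
    n_exposure > 0, n_mediator > 0, n_outcome > 0,
    length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
    maf_range[1] <= maf_range[2],
    h2_exposure > 0, h2_mediator > 0,
    pleiotropy_sd >= 0, case_fraction > 0, case_fraction < 1,
    palindromic_fraction >= 0, palindromic_fraction <= 1,
    swapped_fraction >= 0, swapped_fraction <= 1,
    fetal_effect_sd >= 0, maternal_effect_sd >= 0, duo_se >= 0,
    abs(overlap_correlation) <= 1,
    ld_block_size >= 1, ld_within_r2 >= 0, ld_within_r2 <= 1
  )
  structure(
    list(
      n_snps = as.integer(n_snps), n_snps_mediator = as.integer(n_snps_mediator),
      n_exposure = n_exposure, n_mediator = n_mediator, n_outcome = n_outcome,
      maf_range = maf_range, h2_exposure = h2_exposure,
      h2_mediator = h2_mediator, theta_direct = theta_direct,
      a_effect = a_effect, b_effect = b_effect,
      pleiotropy_mode = pleiotropy_mode, pleiotropy_sd = pleiotropy_sd,
      pleiotropy_mean = pleiotropy_mean,
      binary_outcome = binary_outcome, case_fraction = case_fraction,
      palindromic_fraction = palindromic_fraction,
      swapped_fraction = swapped_fraction,
      maternal_effect_sd = maternal_effect_sd,
      fetal_effect_sd = fetal_effect_sd, duo_se = duo_se,
      overlap_correlation = overlap_correlation,
      ld_block_size = as.integer(ld_block_size), ld_within_r2 = ld_within_r2,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# block-diagonal genomic layout: variants grouped into LD blocks (~1 kb
# spacing within a block) with blocks 50 Mb apart, so the 10,000 kb clumping
# window spans a block but never two
sim_layout <- function(m, block_size) {
  block <- ((seq_len(m) - 1) %/% block_size) + 1
  within <- (seq_len(m) - 1) %% block_size
  chrom <- ((block - 1) %% 22) + 1
  block_on_chrom <- (block - 1) %/% 22
  tibble::tibble(
    block = block,
    chromosome = as.character(chrom),
    position = as.integer(1e6 + block_on_chrom * 5e7 + within * 1000)
  )
}

pal_pairs <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                    ncol = 2, byrow = TRUE)
nonpal_pairs <- matrix(c("A", "C", "C", "A", "A", "G", "G", "A",
                         "T", "C", "C", "T", "T", "G", "G", "T"),
                       ncol = 2, byrow = TRUE)

sim_alleles <- function(m, palindromic_fraction) {
  n_pal <- round(palindromic_fraction * m)
  pal_idx <- if (n_pal > 0) sample.int(m, n_pal) else integer(0)
  ea <- oa <- character(m)
  pick <- function(pairs, k) pairs[sample.int(nrow(pairs), k, replace = TRUE), ,
                                   drop = FALSE]
  if (n_pal > 0) {
    pp <- pick(pal_pairs, n_pal)
    ea[pal_idx] <- pp[, 1]; oa[pal_idx] <- pp[, 2]
  }
  rest <- setdiff(seq_len(m), pal_idx)
  np <- pick(nonpal_pairs, length(rest))
  ea[rest] <- np[, 1]; oa[rest] <- np[, 2]
  list(ea = ea, oa = oa, palindromic = seq_len(m) %in% pal_idx)
}

# represent a fraction of records on the opposite allele orientation
swap_orientation <- function(x, fraction) {
  n_swap <- round(fraction * nrow(x))
  if (n_swap == 0) return(list(x = x, swapped = rep(FALSE, nrow(x))))
  idx <- sample.int(nrow(x), n_swap)
  ea <- x$effect_allele[idx]
  x$effect_allele[idx] <- x$other_allele[idx]
  x$other_allele[idx] <- ea
  x$beta[idx] <- -x$beta[idx]
  x$eaf[idx] <- 1 - x$eaf[idx]
  list(x = x, swapped = seq_len(nrow(x)) %in% idx)
}

#' Simulate a mediation-structured trio of GWAS summary-statistic sets
#'
#' Draws per-SNP instrument effects and sampling noise for three GWASs —
#' exposure, mediator and outcome — under a known causal structure, so every
#' pipeline stage can be checked against ground truth. Two instrument blocks
#' are generated: exposure instruments with effects `gamma` (the mediator
#' inherits `a * gamma`, the outcome `(theta_direct + a*b) * gamma` plus any
#' pleiotropic direct effect), and mediator-specific instruments with effects
#' `delta` (the outcome inherits `b * delta`); every SNP is reported in all
#' three tables, as in real GWAS. Mediator-specific instruments are required
#' for the mediator-outcome step of two-step MR to be identified — an
#' instrument acting on the mediator only through the exposure carries the
#' exposure's direct path as pleiotropy. Sampling SEs follow
#' `1/sqrt(2 p (1-p) N)` per allele-frequency `p` and sample size `N` (times
#' `1/sqrt(cf (1-cf))` for a binary outcome on the log-odds scale); p-values
#' are two-sided normal. A configured fraction of records is palindromic and
#' a configured fraction of mediator/outcome records is stored on the
#' opposite allele orientation so harmonisation is exercised.
#'
#' @param config A [sim_config()] object.
#' @return A list with `mr_sumstats` elements `exposure`, `mediator`,
#'   `outcome`, and `truth` (a list holding the per-SNP tibble of generating
#'   effects and the config).
#' @export
simulate_mediation_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    ne <- config$n_snps; nm <- config$n_snps_mediator
    m <- ne + nm
    lay <- sim_layout(m, config$ld_block_size)
    maf <- runif(m, config$maf_range[1], config$maf_range[2])
    v <- 2 * maf * (1 - maf)
    id <- sprintf("snp_%04d", seq_len(m))
    is_exp_block <- seq_len(m) <= ne

    gamma <- ifelse(is_exp_block,
                    rnorm(m, 0, sqrt(config$h2_exposure / (ne * v))), 0)
    delta <- if (nm > 0) {
      ifelse(!is_exp_block,
             rnorm(m, 0, sqrt(config$h2_mediator / (nm * v))), 0)
    } else rep(0, m)
    # pleiotropic direct effects are defined relative to the allele that
    # increases the instrumented trait, so "directional" means directional
    # regardless of the (arbitrary) allele coding
    orient <- sign(gamma + delta)
    alpha <- switch(config$pleiotropy_mode,
      none = rep(0, m),
      balanced = orient * rnorm(m, 0, config$pleiotropy_sd),
      directional = orient * rnorm(m, config$pleiotropy_mean, config$pleiotropy_sd)
    )

    se_exp <- 1 / sqrt(v * config$n_exposure)
    se_med <- 1 / sqrt(v * config$n_mediator)
    cf <- config$case_fraction
    se_out <- 1 / sqrt(v * config$n_outcome *
                         (if (config$binary_outcome) cf * (1 - cf) else 1))

    a <- config$a_effect; b <- config$b_effect; th <- config$theta_direct
    beta_exp <- gamma + rnorm(m, 0, se_exp)
    beta_med <- a * gamma + delta + rnorm(m, 0, se_med)
    beta_out <- (th + a * b) * gamma + b * delta + alpha + rnorm(m, 0, se_out)

    al <- sim_alleles(m, config$palindromic_fraction)
    base <- tibble::tibble(
      variant_id = id, chromosome = lay$chromosome, position = lay$position,
      effect_allele = al$ea, other_allele = al$oa, eaf = maf
    )
    mk <- function(beta, se, n) {
      dplyr::mutate(base, beta = beta, se = se,
                    pvalue = two_sided_z_p(beta / se), n = n)
    }
    sw_med <- swap_orientation(mk(beta_med, se_med, config$n_mediator),
                               config$swapped_fraction)
    sw_out <- swap_orientation(mk(beta_out, se_out, config$n_outcome),
                               config$swapped_fraction)

    truth <- tibble::tibble(
      variant_id = id, block = lay$block,
      instrument_for = ifelse(is_exp_block, "exposure", "mediator"),
      maf = maf, gamma = gamma, delta = delta, alpha = alpha,
      palindromic = al$palindromic,
      swapped_mediator = sw_med$swapped, swapped_outcome = sw_out$swapped
    )
    list(
      exposure = new_sumstats(mk(beta_exp, se_exp, config$n_exposure),
                              trait = "exposure", scale = "sd"),
      mediator = new_sumstats(sw_med$x, trait = "mediator", scale = "sd"),
      outcome = new_sumstats(
        sw_out$x, trait = "outcome",
        scale = if (config$binary_outcome) "log_odds" else "sd"
      ),
      truth = list(snps = truth, config = config)
    )
  })
}

#' Simulate duo (maternal/fetal) GWAS effect pairs
#'
#' True maternal and fetal per-SNP effects are drawn independently; the
#' unadjusted GWAS estimates are the allele-sharing mixtures
#' `beta_maternal = bm + bf/2 + noise` and `beta_fetal = bf + bm/2 + noise`,
#' the factor 1/2 reflecting mother-child allele sharing, with noise SD
#' `duo_se` and between-GWAS sampling correlation `overlap_correlation`.
#'
#' @param config A [sim_config()] object.
#' @return A list with `duo` (a tibble ready for [wlm_adjust()]) and `truth`
#'   (per-SNP true effects plus the config).
#' @export
simulate_duo_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_snps
    bm <- rnorm(n, 0, config$maternal_effect_sd)
    bf <- rnorm(n, 0, config$fetal_effect_sd)
    rho <- config$overlap_correlation
    z1 <- rnorm(n); z2 <- rnorm(n)
    em <- config$duo_se * z1
    ef <- config$duo_se * (rho * z1 + sqrt(1 - rho^2) * z2)
    duo <- tibble::tibble(
      variant_id = sprintf("snp_%04d", seq_len(n)),
      beta_maternal = bm + bf / 2 + em, se_maternal = config$duo_se,
      beta_fetal = bf + bm / 2 + ef, se_fetal = config$duo_se,
      overlap_correlation = rho
    )
    truth <- tibble::tibble(
      variant_id = duo$variant_id,
      beta_maternal_true = bm, beta_fetal_true = bf
    )
    list(duo = duo, truth = list(snps = truth, config = config))
  })
}

#' Write a simulated fixture bundle to disk
#'
#' Emits five tab-separated files readable by the package's IO functions:
#' `exposure.tsv`, `mediator.tsv`, `outcome.tsv` (summary statistics),
#' `ld.tsv` (long-format block-diagonal LD: every within-block pair at the
#' configured r2, so greedy clumping has a known correct answer of one index
#' variant per block) and `truth_synthetic.tsv` (the per-SNP generating
#' effects; synthetic ground truth, not real data).
#'
#' @param outdir Output directory (created if needed).
#' @param config A [sim_config()] object.
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_fixture_bundle <- function(outdir, config) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_mediation_study(config)
  paths <- c(
    exposure = file.path(outdir, "exposure.tsv"),
    mediator = file.path(outdir, "mediator.tsv"),
    outcome = file.path(outdir, "outcome.tsv"),
    ld = file.path(outdir, "ld.tsv"),
    truth = file.path(outdir, "truth_synthetic.tsv")
  )
  write_sumstats(sim$exposure, paths["exposure"])
  write_sumstats(sim$mediator, paths["mediator"])
  write_sumstats(sim$outcome, paths["outcome"])

  snps <- sim$truth$snps
  ld <- dplyr::bind_rows(lapply(split(snps$variant_id, snps$block), function(ids) {
    if (length(ids) < 2) return(NULL)
    pairs <- utils::combn(ids, 2)
    tibble::tibble(variant_id_a = pairs[1, ], variant_id_b = pairs[2, ],
                   r2 = config$ld_within_r2)
  }))
  if (is.null(ld) || nrow(ld) == 0) {
    ld <- tibble::tibble(variant_id_a = character(), variant_id_b = character(),
                         r2 = numeric())
  }
  readr::write_tsv(ld, paths["ld"])
  readr::write_tsv(snps, paths["truth"])
  invisible(paths)
}
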