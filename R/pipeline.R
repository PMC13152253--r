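#' Bonferroni significance flags
#'
#' Flags p-values significant at `alpha / m`. With the default `m = 7`
#' (seven exposures: one adiposity trait and six blood counts) the threshold
#' is 0.05/7 = 0.00714..., conventionally reported as p < 0.007.
#'
#' @param pvalues Numeric vector.
#' @param m Number of tests corrected for.
#' @param alpha Family-wise error rate.
#' @return Logical vector, `TRUE` where `pvalue < alpha / m`.
#' @export
apply_bonferroni <- function(pvalues, m = 7, alpha = 0.05) {
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  pvalues < alpha / m
}

norm_dataset <- function(x, label) {
  if (is.character(x)) x <- list(path = x)
  stopifnot(is.list(x), !is.null(x$path))
  list(
    path = x$path, scale = x$scale %||% "sd", label = x$label %||% label,
    fetal_path = x$fetal_path, fetal_scale = x$fetal_scale %||% "sd",
    overlap_correlation = x$overlap_correlation %||% 0
  )
}

#' Declarative configuration for a full analysis run
#'
#' Describes the datasets (one exposure, one or more mediators and outcomes)
#' and every analysis threshold for [run_full_analysis()]. Thresholds default
#' to the conventional values used throughout the package: instrument
#' p < 5e-8, clumping r2 0.001 within 10,000 kb, mediation gate alpha 0.05,
#' Bonferroni correction over m = 7 exposures applied to the
#' exposure-outcome analyses. A dataset entry is a list with `path`, `scale`
#' (`"sd"`, `"log_odds"`, `"z_score"`) and optional `label`; an outcome
#' observed as an unadjusted maternal duo GWAS may carry `fetal_path` (and
#' optionally `fetal_scale`, `overlap_correlation`), in which case the
#' maternal-specific effect is derived with the weighted linear model before
#' analysis — already-partitioned inputs simply omit `fetal_path` and are
#' never re-partitioned.
#'
#' @param exposure,mediators,outcomes Dataset entries; `mediators` and
#'   `outcomes` are (optionally named) lists of entries.
#' @param ld_path Optional path to a long-format LD table used for clumping.
#' @param p_threshold,clump_r2,clump_window_kb Instrument selection and
#'   clumping parameters.
#' @param gate_alpha Mediation gate threshold.
#' @param bonferroni_m Number of exposures corrected for.
#' @param bonferroni_scope `"outcomes"` to flag only exposure-outcome rows
#'   (the convention followed here), `"all"` to flag every analysis.
#' @param palindrome_eaf_band Ambiguity band for palindromic variants.
#' @param n_boot,seed,bandwidth_factor Bootstrap and mode-estimator settings
#'   passed to [mr_panel()].
#' @param out_dir If non-`NULL`, [run_full_analysis()] writes the report
#'   there (see [write_report()]).
#' @return A validated list of class `mr_run_config`.
#' @export
run_config <- function(exposure, mediators, outcomes, ld_path = NULL,
                       p_threshold = 5e-8, clump_r2 = 0.001,
                       clump_window_kb = 10000, gate_alpha = 0.05,
                       bonferroni_m = 7, bonferroni_scope = c("outcomes", "all"),
                       palindrome_eaf_band = c(0.42, 0.58),
                       n_boot = 1000, seed = 20240401, bandwidth_factor = 1,
                       out_dir = NULL) {
  bonferroni_scope <- match.arg(bonferroni_scope)
  stopifnot(p_threshold > 0, p_threshold < 1, gate_alpha > 0, gate_alpha < 1,
            clump_r2 >= 0, clump_window_kb > 0, bonferroni_m >= 1)
  if (!is.list(mediators) || length(mediators) == 0) {
    abort("at least one mediator dataset is required")
  }
  if (!is.list(outcomes) || length(outcomes) == 0) {
    abort("at least one outcome dataset is required")
  }
  name_or <- function(x, prefix) {
    nms <- names(x) %||% rep("", length(x))
    nms[nms == ""] <- paste0(prefix, which(nms == ""))
    setNames(x, nms)
  }
  mediators <- name_or(mediators, "mediator")
  outcomes <- name_or(outcomes, "outcome")
  structure(
    list(
      exposure = norm_dataset(exposure, "exposure"),
      mediators = purrr::imap(mediators, norm_dataset),
      outcomes = purrr::imap(outcomes, norm_dataset),
      ld_path = ld_path,
      p_threshold = p_threshold, clump_r2 = clump_r2,
      clump_window_kb = clump_window_kb, gate_alpha = gate_alpha,
      bonferroni_m = bonferroni_m, bonferroni_scope = bonferroni_scope,
      palindrome_eaf_band = palindrome_eaf_band,
      n_boot = n_boot, seed = as.integer(seed),
      bandwidth_factor = bandwidth_factor, out_dir = out_dir
    ),
    class = "mr_run_config"
  )
}

#' @rdname run_config
#' @param path Path to a YAML document with the same fields.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

load_dataset <- function(ds, palindrome_eaf_band = c(0.42, 0.58)) {
  x <- read_summary_stats(ds$path, trait = ds$label, scale = ds$scale)
  if (is.null(ds$fetal_path)) return(x)
  # unadjusted duo GWAS: align the fetal set to the maternal orientation,
  # then derive the maternal-specific effect with the weighted linear model
  fetal <- read_summary_stats(ds$fetal_path, trait = paste0(ds$label, "_fetal"),
                              scale = ds$fetal_scale)
  hz <- harmonize_pair(x, fetal, palindrome_eaf_band)
  adj <- wlm_adjust(
    tibble::tibble(
      beta_maternal = hz$beta_exposure, se_maternal = hz$se_exposure,
      beta_fetal = hz$beta_outcome, se_fetal = hz$se_outcome
    ),
    overlap_correlation = ds$overlap_correlation
  )
  new_sumstats(
    tibble::tibble(
      variant_id = hz$variant_id, chromosome = hz$chromosome,
      position = hz$position, effect_allele = hz$effect_allele,
      other_allele = hz$other_allele, eaf = hz$eaf_exposure,
      beta = adj$beta_adj, se = adj$se_adj,
      pvalue = two_sided_z_p(adj$beta_adj / adj$se_adj), n = NA_real_
    ),
    trait = ds$label, scale = ds$scale
  )
}

#' Run the full analysis graph
#'
#' Executes, for every exposure-outcome, exposure-mediator and
#' mediator-outcome pair: genome-wide instrument selection, LD clumping (when
#' an LD table is configured), harmonisation and the full estimator panel;
#' flags Bonferroni-significant rows; then, for every mediator-outcome triple
#' whose three IVW step p-values pass the mediation gate, computes the
#' total/indirect/direct mediation decomposition. Instrument attrition
#' (selected, clumped, harmonised, dropped-variant tallies) is logged per
#' analysis. Identical configuration and seed give byte-identical reports.
#'
#' @param config An [run_config()] object (or a path to its YAML form).
#' @return An object of class `mr_report` with tibble components `pairs`
#'   (one row per analysis and method), `mediation` (one row per triple),
#'   and `attrition`; written to `config$out_dir` when set.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "mr_run_config"))
  ld <- if (!is.null(config$ld_path)) read_ld_table(config$ld_path) else NULL

  exposure <- load_dataset(config$exposure, config$palindrome_eaf_band)
  mediators <- purrr::map(config$mediators, load_dataset,
                          palindrome_eaf_band = config$palindrome_eaf_band)
  outcomes <- purrr::map(config$outcomes, load_dataset,
                         palindrome_eaf_band = config$palindrome_eaf_band)

  instrument <- function(x) {
    sel <- select_genome_wide(x, config$p_threshold)
    cl <- if (!is.null(ld)) {
      # restrict the LD table to the selected variants: pairs involving
      # unselected variants are irrelevant to clumping this set
      ld_sub <- ld[ld$variant_id_a %in% sel$variant_id &
                     ld$variant_id_b %in% sel$variant_id, ]
      clump_greedy(sel, ld_sub, config$clump_r2, config$clump_window_kb)
    } else sel
    list(set = cl, n_total = nrow(x), n_selected = nrow(sel), n_clumped = nrow(cl))
  }
  inst_exposure <- instrument(exposure)
  inst_mediators <- purrr::map(mediators, instrument)

  attrition <- list()
  panel_rows <- list()
  analyse <- function(inst, target, role) {
    h <- harmonize_pair(inst$set, target, config$palindrome_eaf_band)
    panel <- mr_panel(h, n_boot = config$n_boot, seed = config$seed,
                      bandwidth_factor = config$bandwidth_factor)
    attrition[[length(attrition) + 1]] <<- dplyr::mutate(
      harmonization_log(h), role = role,
      n_total = inst$n_total, n_selected = inst$n_selected,
      n_clumped = inst$n_clumped, .after = "outcome"
    )
    panel_rows[[length(panel_rows) + 1]] <<- dplyr::mutate(
      tidy(panel), role = role, mean_f = panel$mean_f, .after = "outcome"
    )
    invisible(NULL)
  }

  for (ok in names(outcomes)) analyse(inst_exposure, outcomes[[ok]], "exposure_outcome")
  for (mk in names(mediators)) analyse(inst_exposure, mediators[[mk]], "exposure_mediator")
  for (mk in names(mediators)) {
    for (ok in names(outcomes)) {
      analyse(inst_mediators[[mk]], outcomes[[ok]], "mediator_outcome")
    }
  }
  pairs <- dplyr::bind_rows(panel_rows)
  in_scope <- if (config$bonferroni_scope == "outcomes") {
    pairs$role == "exposure_outcome"
  } else rep(TRUE, nrow(pairs))
  pairs$bonferroni_significant <- in_scope &
    pairs$method %in% c("ivw_mre", "wald_ratio") &
    apply_bonferroni(pairs$pvalue, config$bonferroni_m)

  ivw_of <- function(exp_label, out_label) {
    dplyr::filter(pairs, .data$exposure == exp_label, .data$outcome == out_label,
                  .data$method %in% c("ivw_mre", "wald_ratio"))[1, ]
  }
  mediation <- purrr::map_dfr(names(mediators), function(mk) {
    purrr::map_dfr(names(outcomes), function(ok) {
      s_tot <- ivw_of(attr(exposure, "trait"), attr(outcomes[[ok]], "trait"))
      s_a <- ivw_of(attr(exposure, "trait"), attr(mediators[[mk]], "trait"))
      s_b <- ivw_of(attr(mediators[[mk]], "trait"), attr(outcomes[[ok]], "trait"))
      med <- mediate_estimates(
        s_tot$estimate, s_tot$se, s_tot$pvalue,
        s_a$estimate, s_a$se, s_a$pvalue,
        s_b$estimate, s_b$se, s_b$pvalue,
        alpha = config$gate_alpha
      )
      dplyr::mutate(glance(med),
                    exposure = attr(exposure, "trait"),
                    mediator = attr(mediators[[mk]], "trait"),
                    outcome = attr(outcomes[[ok]], "trait"), .before = 1)
    })
  })

  report <- structure(
    list(pairs = pairs, mediation = mediation,
         attrition = dplyr::bind_rows(attrition), config = config),
    class = "mr_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("MR analysis report: %d analyses x methods, %d mediation triple(s)\n",
              length(unique(paste(x$pairs$exposure, x$pairs$outcome))),
              nrow(x$mediation)))
  print(forest_data(x))
  invisible(x)
}

#' Plot-ready estimate table
#'
#' One row per analysis and method with the estimate and 95% CI on the
#' reporting scale: log-odds analyses are exponentiated to odds ratios,
#' everything else is left on its native scale.
#'
#' @param report An `mr_report` object.
#' @return A tibble with `exposure`, `outcome`, `role`, `method`, `estimate`,
#'   `ci_low`, `ci_high`, `scale`.
#' @export
forest_data <- function(report) {
  stopifnot(inherits(report, "mr_report"), nrow(report$pairs) > 0)
  x <- dplyr::filter(report$pairs, !is.na(.data$estimate))
  lo <- x$scale == "log_odds"
  tibble::tibble(
    exposure = x$exposure, outcome = x$outcome, role = x$role,
    method = x$method,
    estimate = ifelse(lo, exp(x$estimate), x$estimate),
    ci_low = ifelse(lo, exp(x$ci_low), x$ci_low),
    ci_high = ifelse(lo, exp(x$ci_high), x$ci_high),
    scale = ifelse(lo, "odds_ratio", x$scale)
  )
}

#' Write an analysis report to disk
#'
#' Writes `pairs.tsv`, `mediation.tsv`, `attrition.tsv`, `forest.tsv` and a
#' machine-readable `summary.json` into `dir`. All tables are plain TSV.
#'
#' @param report An `mr_report` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mr_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$pairs, file.path(dir, "pairs.tsv"))
  readr::write_tsv(report$mediation, file.path(dir, "mediation.tsv"))
  readr::write_tsv(report$attrition, file.path(dir, "attrition.tsv"))
  readr::write_tsv(forest_data(report), file.path(dir, "forest.tsv"))
  jsonlite::write_json(
    list(
      n_analyses = length(unique(paste(report$pairs$exposure,
                                       report$pairs$outcome))),
      n_mediation_triples = nrow(report$mediation),
      n_gated_mediations = sum(report$mediation$gate_passed),
      seed = report$config$seed
    ),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
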