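#' GWAS summary-statistic tables
#'
#' A summary-statistic set is a tibble with one row per variant and columns
#' `variant_id`, `chromosome`, `position`, `effect_allele`, `other_allele`,
#' `eaf`, `beta`, `se`, `pvalue`, `n`, carrying the trait label and the
#' measurement scale of `beta` (`"sd"` for standardised continuous traits,
#' `"log_odds"` for binary traits, `"z_score"` for standardised Z-scores) as
#' attributes. `as_sumstats()` validates a data frame and drops rows that
#' violate the per-variant invariants (alleles must be distinct single bases,
#' `se > 0`, `pvalue` in (0, 1], `eaf` in \[0, 1\] or missing); the number of
#' dropped rows is recorded in the `n_dropped` attribute.
#'
#' @param x A data frame with at least `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se` and `pvalue` columns (common column aliases
#'   such as `SNP`, `rsid`, `pval`, `a1`/`a2` are recognised).
#' @param trait Trait label for the set.
#' @param scale Scale of `beta`: `"sd"`, `"log_odds"` or `"z_score"`.
#' @return A tibble of class `mr_sumstats` with attributes `trait`, `scale`
#'   and `n_dropped`.
#' @examples
#' as_sumstats(
#'   data.frame(
#'     variant_id = c("rs1", "rs2"), chromosome = "1",
#'     position = c(1e5, 2e5), effect_allele = c("A", "C"),
#'     other_allele = c("G", "T"), eaf = c(0.3, 0.4),
#'     beta = c(0.02, -0.01), se = 0.005, pvalue = c(1e-9, 0.04), n = 1e5
#'   ),
#'   trait = "bmi", scale = "sd"
#' )
#' @export
as_sumstats <- function(x, trait = "trait", scale = c("sd", "log_odds", "z_score")) {
  scale <- match.arg(scale)
  x <- resolve_aliases(tibble::as_tibble(x))
  mandatory <- c("variant_id", "effect_allele", "other_allele", "beta", "se", "pvalue")
  missing_cols <- setdiff(mandatory, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")))
  }
  for (col in c("chromosome", "position", "eaf", "n")) {
    if (!col %in% names(x)) x[[col]] <- NA
  }
  x <- dplyr::mutate(
    x,
    variant_id = as.character(.data$variant_id),
    chromosome = as.character(.data$chromosome),
    position = as.integer(round(as.numeric(.data$position))),
    effect_allele = toupper(as.character(.data$effect_allele)),
    other_allele = toupper(as.character(.data$other_allele)),
    eaf = as.numeric(.data$eaf),
    beta = as.numeric(.data$beta),
    se = as.numeric(.data$se),
    pvalue = as.numeric(.data$pvalue),
    n = as.numeric(.data$n)
  )
  bases <- c("A", "C", "G", "T")
  ok <- !is.na(x$variant_id) &
    x$effect_allele %in% bases & x$other_allele %in% bases &
    x$effect_allele != x$other_allele &
    is.finite(x$beta) &
    is.finite(x$se) & x$se > 0 &
    is.finite(x$pvalue) & x$pvalue > 0 & x$pvalue <= 1 &
    (is.na(x$eaf) | (x$eaf >= 0 & x$eaf <= 1))
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    warn(sprintf("dropped %d row(s) failing summary-statistic invariants", n_dropped))
  }
  x <- x[ok, c("variant_id", "chromosome", "position", "effect_allele",
               "other_allele", "eaf", "beta", "se", "pvalue", "n")]
  if (nrow(x) == 0) abort("no valid summary-statistic rows")
  if (anyDuplicated(x$variant_id)) {
    dup <- sum(duplicated(x$variant_id))
    warn(sprintf("dropped %d duplicated variant id(s), keeping first occurrence", dup))
    x <- x[!duplicated(x$variant_id), ]
    n_dropped <- n_dropped + dup
  }
  new_sumstats(x, trait = trait, scale = scale, n_dropped = n_dropped)
}

new_sumstats <- function(x, trait, scale, n_dropped = 0L) {
  structure(
    tibble::as_tibble(x),
    trait = trait, scale = scale, n_dropped = as.integer(n_dropped),
    class = c("mr_sumstats", class(tibble::tibble()))
  )
}

# documented alias map for common GWAS column dialects
sumstat_aliases <- list(
  variant_id = c("variant_id", "snp", "rsid", "rs_id", "id", "marker", "markername"),
  chromosome = c("chromosome", "chr", "chrom", "chr_name"),
  position = c("position", "pos", "bp", "base_pair_location", "bpos"),
  effect_allele = c("effect_allele", "ea", "a1", "allele1", "alt"),
  other_allele = c("other_allele", "oa", "a2", "allele2", "non_effect_allele", "ref"),
  eaf = c("eaf", "effect_allele_frequency", "freq", "af", "frq", "maf"),
  beta = c("beta", "b", "effect", "beta_hat", "effect_size"),
  se = c("se", "standard_error", "stderr", "sebeta"),
  pvalue = c("pvalue", "p", "pval", "p_value", "p.value"),
  n = c("n", "sample_size", "samplesize", "n_total")
)

resolve_aliases <- function(x) {
  nms <- tolower(names(x))
  for (canon in names(sumstat_aliases)) {
    if (canon %in% nms) next
    hit <- which(nms %in% sumstat_aliases[[canon]])
    if (length(hit) > 0) nms[hit[1]] <- canon
  }
  names(x) <- nms
  x
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' Reads a header-bearing TSV of per-variant association records, resolves
#' common column aliases, upper-cases alleles and drops rows failing the
#' invariants (see [as_sumstats()]).
#'
#' @param path Path to a tab-separated file.
#' @inheritParams as_sumstats
#' @return An `mr_sumstats` tibble.
#' @export
read_summary_stats <- function(path, trait = NULL,
                               scale = c("sd", "log_odds", "z_score")) {
  scale <- match.arg(scale)
  trait <- trait %||% sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_sumstats(x, trait = trait, scale = scale)
}

#' Write a summary-statistic set to TSV
#'
#' @param x An `mr_sumstats` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}

#' Select genome-wide significant variants
#'
#' Keeps records with `pvalue < p_threshold` (strict), preserving the input
#' order. The conventional genome-wide threshold 5e-8 is the default.
#'
#' @param x An `mr_sumstats` tibble.
#' @param p_threshold Significance threshold in (0, 1).
#' @return The filtered `mr_sumstats` tibble.
#' @export
select_genome_wide <- function(x, p_threshold = 5e-8) {
  stopifnot(is.numeric(p_threshold), p_threshold > 0, p_threshold < 1)
  keep <- x$pvalue < p_threshold
  if (!any(keep)) warn("no variants pass the significance threshold")
  new_sumstats(x[keep, ], trait = attr(x, "trait"), scale = attr(x, "scale"))
}

#' Pairwise LD tables
#'
#' Long-format linkage-disequilibrium table with columns `variant_id_a`,
#' `variant_id_b` and `r2` in \[0, 1\]. Pairs are treated as unordered:
#' `r2(a, b)` equals `r2(b, a)`, and absent pairs are taken as r2 = 0, which
#' matches sparse LD exports where sub-threshold pairs are omitted.
#'
#' @param x A data frame with `variant_id_a`, `variant_id_b`, `r2`.
#' @return A tibble of class `mr_ld_table`.
#' @export
as_ld_table <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("variant_id_a", "variant_id_b", "r2")
  if (!all(need %in% names(x))) {
    abort("LD table needs columns variant_id_a, variant_id_b, r2")
  }
  x <- dplyr::mutate(
    x,
    variant_id_a = as.character(.data$variant_id_a),
    variant_id_b = as.character(.data$variant_id_b),
    r2 = as.numeric(.data$r2)
  )
  if (any(!is.finite(x$r2) | x$r2 < 0 | x$r2 > 1)) {
    abort("r2 values must lie in [0, 1]")
  }
  structure(x[need], class = c("mr_ld_table", class(tibble::tibble())))
}

#' @rdname as_ld_table
#' @param path Path to a long-format LD TSV.
#' @export
read_ld_table <- function(path) {
  as_ld_table(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

ld_lookup <- function(ld) {
  if (is.null(ld) || nrow(ld) == 0) {
    return(function(a, b) 0)
  }
  key <- paste(pmin(ld$variant_id_a, ld$variant_id_b),
               pmax(ld$variant_id_a, ld$variant_id_b), sep = "\r")
  r2 <- setNames(ld$r2, key)
  function(a, b) {
    v <- r2[paste(pmin(a, b), pmax(a, b), sep = "\r")]
    ifelse(is.na(v), 0, v)
  }
}

#' Greedy LD clumping
#'
#' Selects approximately independent index variants by ascending p-value: a
#' candidate is discarded when it lies within `window_kb` of an already kept
#' variant on the same chromosome *and* its r2 with that variant exceeds
#' `r2_threshold`. Pairs missing from the LD table count as r2 = 0, so with no
#' LD information only the p-value ordering matters and nothing is removed.
#' Defaults follow the standard stringent setting (r2 = 0.001, 10,000 kb).
#'
#' @param x An `mr_sumstats` tibble with `chromosome` and `position` filled in.
#' @param ld An `mr_ld_table`, or `NULL` for no LD information.
#' @param r2_threshold LD pruning threshold.
#' @param window_kb Physical window in kilobases; the window test is
#'   `|pos_a - pos_b| <= window_kb * 1000` on the same chromosome (1-based
#'   coordinates).
#' @return The clumped `mr_sumstats` tibble of index variants, in the original
#'   row order.
#' @export
clump_greedy <- function(x, ld = NULL, r2_threshold = 0.001, window_kb = 10000) {
  stopifnot(r2_threshold >= 0, window_kb > 0)
  if (nrow(x) == 0) return(x)
  if (any(is.na(x$chromosome)) || any(is.na(x$position))) {
    abort("clumping needs chromosome and position for every variant")
  }
  if (!is.null(ld)) {
    unknown <- setdiff(unique(c(ld$variant_id_a, ld$variant_id_b)), x$variant_id)
    if (length(unknown) > 0) {
      warn(sprintf("LD table references %d unknown variant id(s); ignored",
                   length(unknown)))
    }
  }
  r2_of <- ld_lookup(ld)
  ord <- order(x$pvalue)
  kept <- integer(0)
  for (i in ord) {
    drop <- FALSE
    for (k in kept) {
      if (x$chromosome[k] == x$chromosome[i] &&
          abs(x$position[k] - x$position[i]) <= window_kb * 1000 &&
          r2_of(x$variant_id[k], x$variant_id[i]) > r2_threshold) {
        drop <- TRUE
        break
      }
    }
    if (!drop) kept <- c(kept, i)
  }
  new_sumstats(x[sort(kept), ], trait = attr(x, "trait"), scale = attr(x, "scale"))
}
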