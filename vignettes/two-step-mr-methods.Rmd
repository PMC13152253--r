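---
title: "Methods: two-sample MR with maternal effect partitioning and two-step mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR with maternal effect partitioning and two-step mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

# The problem

Maternal adiposity is associated with pregnancy outcomes — offspring birth
weight, placental weight, gestational duration, pre-eclampsia — but
observational associations are confounded. Two-sample Mendelian
randomisation (MR) uses genetic variants as instrumental variables: a SNP
that raises the exposure is, under the instrumental assumptions, a natural
randomised nudge whose downstream association with the outcome measures the
causal effect. `mrmediate` implements the full analysis chain on GWAS
summary statistics: instrument selection and LD clumping, allele
harmonisation, maternal-specific effect partitioning for pregnancy traits,
a panel of pleiotropy-robust causal estimators, and two-step MR mediation
through intermediate traits such as immune blood-cell counts.

Everything operates on tabular per-variant records, so every function takes
a data frame and returns a tibble; fitted objects support `tidy()`,
`glance()` and `autoplot()`.

# The estimators

For each harmonised instrument the Wald ratio is
$\hat\theta_j = \hat\beta_{Y,j}/\hat\beta_{X,j}$ with the first-order SE
$se(\hat\beta_{Y,j})/|\hat\beta_{X,j}|$, which ignores exposure-side
sampling error. This is accurate when instruments are strong; the panel
reports the mean F-statistic $\overline{(\hat\beta_X/se_X)^2}$ so users can
check that F is far above 10.

**IVW (multiplicative random effects).** The headline estimator is the
inverse-variance weighted meta-analysis of Wald ratios, equivalently the
weighted zero-intercept regression of $\hat\beta_Y$ on $\hat\beta_X$ with
weights $1/se_Y^2$. Heterogeneity is summarised by Cochran's
$Q = \sum_j w_j(\hat\beta_{Y,j} - \hat\theta\,\hat\beta_{X,j})^2$ on
$n-1$ df; the multiplicative random-effects SE inflates the fixed-effects SE
by $\max(1, \sqrt{Q/(n-1)})$. The floor at 1 means the random-effects SE is
never smaller than the fixed-effects one; when instrument-strength noise or
pleiotropy adds genuine dispersion, the inflation tracks it.

**MR-Egger.** The same regression with a free intercept. Under the InSIDE
assumption (instrument strength independent of direct effects) the slope is
consistent despite directional pleiotropy, and the intercept estimates the
mean pleiotropic effect. Egger regression is not invariant to allele
coding, so instruments are first re-oriented so that every
$\hat\beta_X > 0$; this canonical orientation makes results reproducible.
Slope and intercept p-values use a t distribution on $n-2$ df, the
conventional pairing for an estimated-variance regression; IVW, median and
mode p-values are two-sided normal.

**Weighted median.** Wald ratios are ordered and the weighted median is the
linear interpolation of the mid-cumulative standardised weights
$s_j = (\sum_{k\le j} w_k - w_j/2)/\sum_k w_k$ at $s = 0.5$. It is
consistent while valid instruments hold more than half the weight.

**Mode estimators.** The simple and weighted modes take the argmax of a
normal-kernel density of the Wald ratios (inverse-variance weights in the
weighted variant), on the premise that the largest cluster of instruments
is valid. The bandwidth is the modified Silverman rule
$0.9\,\min(sd, mad)\,n^{-1/5}$ times a user `bandwidth_factor` (default 1).
The argmax is evaluated exactly (kernel sums on a 4096-point grid spanning
the ratio range extended by three bandwidths); when the median absolute
deviation is zero the rule falls back to the standard deviation, and fully
degenerate ratio sets return their common value.

**Uncertainty for median and mode.** Parametric bootstrap: both
$\hat\beta_X$ and $\hat\beta_Y$ are perturbed by their SEs and the
estimator is recomputed; the SE is the SD over `n_boot` resamples
(default 1000, default seed 20240401, both recorded in the result). The
bootstrap grid for the mode uses 512 points, which is ample because only
the SD of the argmax is needed.

All 95% intervals use $\pm 1.96\,se$, matching conventional reporting.
Log-odds outcomes are guarded by a `scale` flag; `beta_to_or()` refuses to
exponentiate an SD-scale estimate.

# Harmonisation and clumping choices

Records are intersected by variant id and the outcome is aligned to the
exposure's effect allele, flipping the outcome beta and complementing its
EAF when alleles are swapped directly or after strand complement.
Palindromic variants (A/T, G/C) cannot be strand-resolved from alleles
alone: those with missing exposure EAF or EAF inside [0.42, 0.58] are
dropped (a conservative band; there is no universally agreed rule), and the
kept ones are aligned by allele labels and then re-oriented if the exposure
and outcome EAFs disagree about which allele is minor. Variants with
`beta_exposure == 0` are excluded because their Wald ratio is undefined.
Every drop is tallied and surfaced by `harmonization_log()`.

Clumping is the standard greedy p-value-ordered procedure (defaults
p < 5e-8, r2 > 0.001 within 10,000 kb, 1-based coordinates). A pair absent
from the LD table counts as r2 = 0, matching sparse long-format LD exports
where sub-threshold pairs are omitted — so with no LD information clumping
is deliberately a no-op rather than an error.

# Maternal-specific effects

Mother and child share half their alleles, so an unadjusted maternal GWAS
of a pregnancy trait absorbs half the fetal effect and vice versa:
$\hat\beta_M = \beta_m + \beta_f/2$, $\hat\beta_F = \beta_f + \beta_m/2$.
The weighted linear model inverts the mixing:
$\hat\beta_{M,adj} = \tfrac43\hat\beta_M - \tfrac23\hat\beta_F$ (and
symmetrically for the fetal effect, provided for completeness). The source
material prints only the point transform, so the SE is propagated through
the same linear combination with a user-supplied sampling-error correlation
between the two GWASs (default 0, i.e. non-overlapping samples); supplying
the true overlap correlation makes the propagated SE match the Monte-Carlo
SD of the transform, which the test suite verifies. Datasets that arrive
already partitioned are used as-is — the pipeline partitions only when a
`fetal_path` is configured, and never re-partitions.

# Two-step mediation

Each step — exposure on outcome (total effect), exposure on mediator (a),
mediator on outcome (b) — is estimated by the multiplicative random-effects
IVW, using the exposure's instruments for the first two steps and the
mediator's own instruments for the third. The decomposition is only
computed when all three step p-values are strictly below the gate threshold
(default 0.05; deliberately liberal, and configurable). Then

* indirect $= a \times b$, with the delta-method SE
  $\sqrt{b^2 se_a^2 + a^2 se_b^2 + se_a^2 se_b^2}$;
* direct $=$ total $-$ indirect, with SE
  $\sqrt{se_{total}^2 + se_{indirect}^2}$;
* p-values are two-tailed normal.

`direct + indirect = total` holds exactly by construction. The proportion
mediated (indirect/total) is off by default and warns when the total effect
is weak or opposite-signed, since the ratio is then unstable. One numerical
caveat worth recording: re-doing the arithmetic from *rounded* printed step
estimates cannot exactly reproduce a p-value computed from unrounded ones
(e.g. a printed indirect-effect p of 0.11 re-derives as roughly 0.10 from
the rounded inputs); the package always reports unrounded values.

```{r mediation-example}
med <- mediate_estimates(
  total = 0.04, se_total = 0.0153, p_total = 0.01,
  a = -0.04, se_a = 0.0194, p_a = 0.03,
  b = -0.03, se_b = 0.0102, p_b = 0.01
)
tidy(med)
```

# What the simulator emulates — and what it does not

`simulate_mediation_study()` draws GWAS summary statistics directly (no
individual-level genotypes): per-SNP minor allele frequencies uniform on
[0.05, 0.5], instrument effects centred normal and scaled so the instrument
set explains a stated fraction of trait variance, and sampling noise with
SE $1/\sqrt{2p(1-p)N}$ (times $1/\sqrt{cf(1-cf)}$ for a binary outcome
simulated directly on the log-odds scale, with no liability-threshold
conversion). Two instrument blocks are generated. Exposure instruments
$\gamma_j$ propagate as $a\gamma_j$ to the mediator and
$(\theta_{direct} + ab)\gamma_j$ to the outcome. Mediator-specific
instruments $\delta_j$ affect the mediator directly and the outcome as
$b\delta_j$. The second block is not optional decoration: an instrument
that reaches the mediator only through the exposure carries the exposure's
direct path as pleiotropy, so the mediator-to-outcome step would converge
to $\theta/a + b$ rather than $b$ — identification of the third step
requires instruments of the mediator itself, exactly why real analyses
instrument blood counts with their own GWAS hits.

Horizontal pleiotropy adds direct SNP-outcome effects that are balanced
(mean zero) or directional; directional effects are defined relative to
the allele that increases the instrumented trait, since "directional" is
meaningless under arbitrary allele coding. Pleiotropic effects are drawn
independently of instrument strength, so the InSIDE assumption holds and
MR-Egger's slope should be approximately unbiased where IVW is biased —
a property the test suite checks. A configured fraction of records is
palindromic and a configured fraction of mediator/outcome records is
stored on the swapped allele orientation, so harmonisation is exercised on
every simulated run; these fractions are exact counts. Duo simulations mix
true maternal and fetal effects with the fixed allele-sharing coefficient
1/2 and add correlated sampling noise.

Default conditions were chosen once, to be realistic for the motivating
setting, and are not tuned per analysis: exposure GWAS of 700,000 with 100
instruments explaining 2% of variance (mean F around 140, typical of
adiposity GWAS hits), mediator GWAS of 408,112 with instruments explaining
10% (blood-count loci are large-effect), outcome GWAS of 270,002, causal
structure $\theta_{direct} = 0.2$, $a = 0.3$, $b = 0.5$ (total 0.35), case
fraction 0.117 for binary outcomes. At these settings a 10,000-replicate
design pilot gave a two-step indirect-effect bias of about $-0.0004$ on a
true 0.15 — the residual $\sim 1/F$ regression dilution partly offset by
occasional exposure SNPs entering the mediator's instrument set — and a
delta-SE to empirical-SD ratio of about 1.02, so the simulator's defaults
support calibration testing without hiding genuine small-sample artefacts.

What the simulator does **not** model: realistic LD (the LD fixture is
block-diagonal with a known answer, so clumping is testable, not
realistic), winner's curse in instrument selection, sample overlap between
exposure and outcome GWASs, INDELs or multi-allelic sites, and
liability-scale binary traits. Passing simulation tests therefore shows
the estimators and plumbing are correct under clean assumptions — not that
real-data results are unbiased, which depends on pleiotropy and instrument
validity that no simulation can certify.

# Test problem sizes

The suite runs estimator-oracle checks on 15–30 instrument fixtures to
1e-10; null calibration with 500 replicates of 100 instruments (type-I
error and 95% CI coverage); mediation recovery with 300 replicates of the
default two-block design; and duo-partition calibration on 1,000 SNPs.
These sizes give Monte-Carlo error comfortably below the tested bands
while keeping a full run around half a minute on one core.

# Numerical details and edge cases

* p-values are clamped to $(0, 1]$; extreme Z-scores never produce 0.
* A single-instrument IVW degrades to the Wald ratio with a warning;
  Egger, median and modes require three instruments and report absent
  rows with reasons inside the panel rather than failing it.
* Egger aborts on a constant-exposure design (the fit is degenerate).
* Duplicated variant ids keep the first occurrence (warned); rows failing
  record invariants are dropped and tallied on read.
* The greedy clump resolves p-value ties by input order, making results
  deterministic.
* All randomness (simulation, bootstrap) is seed-controlled; identical
  configuration and seed give byte-identical reports.

# Reproducing published-scale analyses

The package's external interface is deliberately minimal — GWAS-SSF-like
TSV columns — so published summary statistics for adiposity, blood counts
and pregnancy outcomes can be dropped in directly: configure the exposure
and outcome files, a reference-panel LD export, and `run_full_analysis()`
reproduces the analysis graph (IVW odds ratio near 1.75 for pre-eclampsia
and around 0.16 SD for placental weight in the motivating analyses, with
differences dominated by the LD panel and clumping software used). Those
datasets are hundreds of megabytes and are not bundled; this workflow is a
tutorial, not part of the test suite.
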