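---
title: "Gene-pair risk scores for survival prognosis: model, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-pair risk scores for survival prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairRisk)
```

## The problem

Diffuse large B-cell lymphoma (DLBCL) outcomes under standard CHOP/R-CHOP
chemotherapy vary widely, and expression-based prognostic signatures try to
capture that variation. Most published signatures score a patient as a
coefficient-weighted sum of absolute expression values, which makes them
sensitive to platform, normalization, and cohort composition. The
alternative implemented here scores a patient only by *within-sample
relative ordering* of gene pairs: for an unfavorable prognostic gene $u$
and a favorable prognostic gene $f$, the indicator

$$ s_{(u,f)} = \mathbf{1}\left[ q_u \ge q_f \right] $$

is 1 when the (within-cohort quantile-transformed) expression of $u$ is at
or above that of $f$. The risk score of a sample is the plain integer sum
over the $k$ pairs of a signature, $R = \sum_p s_p \in \{0, \dots, k\}$ —
deliberately unweighted, so that a $k = 4$ signature has exactly five
interpretable risk levels and the high/low cut (score $\ge 3$) needs no
per-cohort recalibration.

## The discovery pipeline

1. **Integration.** Same-platform cohorts are merged on their common genes
   and batch-corrected by parametric empirical-Bayes location/scale
   adjustment (below). Two independent training cohorts are kept separate
   end-to-end; they meet only at the intersection steps.
2. **Regimen filter.** Patients not treated with CHOP/R-CHOP are split off
   as internal test data; screening sees only the standard-therapy
   population.
3. **Gene screen.** Each gene is dichotomized at its cohort median
   (ties-at-median go to the low group, a deterministic strict-majority
   rule). A univariable Cox model with Efron tie handling supplies the
   hazard ratio of high vs low; a log-rank test and a Gehan-Breslow
   Wilcoxon test supply p-values. A gene is a favorable prognostic gene
   (FPG) if HR < 1 with both p-values < 0.01, an unfavorable one (UPG) if
   HR > 1 with the same gates. The Cox Wald p is recorded but not gated
   on, and no multiple-testing correction is applied at this stage: the
   cross-cohort intersection is the false-positive control, and we keep
   that design.
4. **Pair screen.** Expression restricted to the screened genes is
   quantile-transformed per gene to $[0, 1]$ (`(rank - 1) / (n - 1)`, mean
   ranks for ties), all UPG × FPG pairs are enumerated, and each pair's
   binary indicator is screened by univariable Cox; pairs with HR > 1.8
   are selected. Binarization happens *after* the quantile transform, so
   the comparison is between the two genes' within-cohort percentile
   ranks, not raw intensities — this matters and is the documented
   convention throughout.
5. **Signature.** Pairs selected in both training cohorts form the final
   signature; scoring an external cohort refits the quantile transform on
   that cohort alone, so the score never imports training-cohort scale
   information.

### Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `p_threshold` | 0.01 | two-sided gate for BOTH survival tests in the gene screen |
| `pair_hr_threshold` | 1.8 | Cox HR gate for pair indicators |
| `high_risk_min_score` | 3 | score at which a sample (or cell line) is called high risk |
| `eval_horizons` | 1, 2, 3 years | time-dependent ROC horizons |
| `keep_regimens` | CHOP, R-CHOP | training population filter |

When only $k' < k$ signature pairs are measurable in a dataset, scores are
confined to $0..k'$ and the high-risk cut is rescaled to
$\lceil 3 k' / 4 \rceil$ (so 3 of 3, 2 of 2 for the two reduced forms of a
4-pair signature). The rescaling keeps the proportion of the score range
needed for a high-risk call roughly constant; it is configurable because
no principled universal choice exists.

## Statistical components

* **Kaplan-Meier / log-rank / Gehan-Wilcoxon.** The weighted log-rank
  family is implemented on a shared observed-minus-expected tabulation
  over distinct event times with hypergeometric variance; the log-rank
  uses unit weights (and generalizes to $k$ groups with a $k-1$ df
  chi-square for the five risk levels), the generalized Wilcoxon uses
  number-at-risk weights (Gehan-Breslow), which emphasizes early
  differences. "Wilcoxon" is ambiguous in the literature; the
  Gehan-Breslow variant is fixed here and stated. Subjects censored
  exactly at an event time count as at risk at that time.
* **Cox fits.** Single binary covariate, Efron handling of ties (the
  default of the survival tooling this field uses; fixed and documented).
  Complete separation is flagged non-converged with $|\beta|$ capped at
  20. Wald 95% intervals are emitted but nothing is gated on them.
* **Time-dependent ROC.** Cumulative-case / dynamic-control estimation at
  a fixed horizon with Kaplan-Meier estimates inside marker strata — the
  smoothing-free variant, chosen because the risk score is discrete (five
  levels) and kernel smoothing over five support points is not
  meaningful. Each distinct marker value is one threshold; operating
  points are clipped to $[0,1]$ and monotonized before the trapezoidal
  AUC, so the emitted curve is always a valid ROC. With no censoring
  before the horizon this estimator reduces exactly to the Mann-Whitney
  AUC (tested against a rank-sum oracle).
* **Group comparisons.** Welch's unequal-variance t (Satterthwaite df) for
  unpaired groups — used for the drug panels — and the paired t for paired
  designs. Zero-variance degeneracies return p = 1 for equal means and a
  capped statistic otherwise, rather than failing.

## Batch adjustment

`combat_adjust()` implements the parametric empirical-Bayes location/scale
model: per gene, data are standardized by the batch-corrected pooled mean
and variance; per-batch gene means get a normal shrinkage prior and
per-batch gene variances an inverse-gamma prior, hyperparameters estimated
across genes by the method of moments, posteriors solved by iterating the
two conditional modes (tolerance 1e-6, max 200 iterations). Three
deliberate numerical choices:

* all variances use divide-by-$n$ (MLE) denominators, which makes the
  adjustment *exactly* null for identical batches;
* a gene with zero variance inside some batch gets a location-only
  adjustment there (no scale estimate exists), reported in a message;
* a single batch bypasses adjustment entirely.

One property worth stating because it is easy to assume otherwise:
empirical-Bayes variance shrinkage makes the adjustment a *contraction*
rather than an idempotent map. A second pass leaves batch means in place
(sub-1e-3 movement) and perturbs entries by a few percent of the first
pass, but every pass keeps shrinking the sampling spread of within-batch
variances slightly; the reference implementation in the sva package
behaves the same way. None of this affects the rank-based downstream: a
single-cohort adjustment never changes any risk score (location/scale maps
are monotone per gene), which is tested bit-for-bit.

## The synthetic cohort generator

`simulate_cohort()` emulates the *structure* of merged DLBCL microarray
cohorts: several batches with per-gene additive shifts
($\gamma \sim N(0, \sigma_{shift})$) and multiplicative scale effects
($\delta = e^{N(0, \sigma_{scale})}$) on top of a shared gene baseline
($\mu_g \sim N(6, 2)$, log-intensity-like units) and residual noise. The
hazard model is proportional hazards on an exponential baseline: planted
unfavorable/favorable genes contribute $\pm \beta$ per above-median
indicator of the *batch-free* expression, planted pairs contribute their
log-HR per order indicator, and censoring is uniform on $(0, c)$ with $c$
solved numerically so the expected censored fraction hits the target
(administrative-censoring analogue). Defaults: 30% censoring, baseline
hazard 0.15/year — the cohorts this emulates report neither, so these are
configurable choices of realistic magnitude, not inferred values. Regimen
labels are drawn independently of survival so the regimen filter can be
exercised without confounding.

What the generator does **not** emulate: probe-level artifacts,
platform-specific dynamic ranges, gene-gene correlation beyond what the
planted effects induce, informative censoring, or the effect sizes of any
real cohort. Passing tests therefore demonstrate that the pipeline's
machinery recovers what its model class plants under realistic noise — not
that any particular real-data signature is correct.

### Why the planted signature shares a hub gene

The recovery experiments plant a 4-pair signature over 5 genes: one
unfavorable hub paired with four favorable genes, mirroring the
shared-gene structure typical of published pair signatures (4 pairs / 7
genes). The deeper reason is identifiability of the false-positive count:
if several planted UPGs and FPGs carried independent hazard effects, every
*cross* pair (a planted UPG with a planted FPG from another pair) would
itself be genuinely hazard-associated — its indicator correlates with each
member gene's median split and with any planted pair sharing a gene — so
its true HR exceeds the 1.8 gate and calling it a "false" discovery would
be wrong. With a single hub UPG the planted pairs exhaust the UPG × FPG
product of planted genes, and any extra discovery necessarily involves a
non-planted gene: an unambiguous false positive. Under this design the
full pipeline (two cohorts of 400 samples, 300 genes, two batches each)
recovers ~99% of planted pairs with ~0 false pairs over 20 seeds.

### Validation problem sizes

The shipped tests and the acceptance script use: two cohorts × 400
samples × 300 genes × 20 seeds for end-to-end recovery; 2000-gene
single-batch cohorts (n = 250, 5–20 replicates) for null-screen
calibration; 1000 replicates at n = 200 for test-level type-I error; 500
genes × two 300-sample batches for batch-adjustment metrics. These sizes
give Monte-Carlo standard errors comfortably inside the asserted bands
(e.g. ±0.7% on a 5% rejection rate at 1000 replicates) while keeping the
default suite to a few minutes; they are the package's chosen validation
conditions, not estimates of any real cohort.

## Numerical conventions and edge cases

* Ties: at the gene median → low group; in a pair comparison → indicator
  1 ("at or above"); in AUC ranking across signatures → shared minimum
  rank (so two signatures can both rank 2).
* p-values are floored at the smallest positive double, never 0.
* A constant gene maps to quantile 0.5 everywhere (reported); a constant
  pair indicator is skipped by the pair screen with a reason, never
  selected.
* All screening statistics depend on expression only through per-gene
  ranks; the whole risk score is bit-for-bit invariant under strictly
  monotone per-gene transforms (tested with random transform batteries).
* Fixed seeds make every simulation and the whole pipeline byte-identical
  across runs.

## Known limitations

* Only univariable screening is implemented — no multivariable Cox,
  time-varying covariates, or proportional-hazards diagnostics; the
  method's own design never uses them.
* The shipped seven-gene signature file reconstructs the published
  gene-to-pair assignment only approximately (the assignment is not
  machine-readable in the original figures); it is labelled synthetic and
  should be replaced before scientific use.
* Cross-platform probe mapping is out of scope: cohorts are merged only
  within a platform, matching the two-training-cohort design.
* The drug-panel generator plants additive log-IC50 shifts with exact
  tied-block expression; for signatures whose genes appear in several
  pairs the intended per-line scores are only approximate.
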