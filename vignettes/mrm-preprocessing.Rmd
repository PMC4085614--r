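---
title: "Quality assessment and normalization of label-free MRM data"
author: "mrmprep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality assessment and normalization of label-free MRM data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmprep)
```

## The data model

A label-free MRM experiment quantifies each peptide through several
fragment-ion transitions, measured across LC-MS runs that are grouped into
biological samples (technical replicates are distinct runs sharing a
`sample_id`) and, optionally, treatment groups. `mrmprep` ingests
long-format transition reports (one row per peptide, transition and run —
the shape exported by Skyline- or MultiQuant-style tools, mapped through a
configurable column map) and assembles an `MRMExperiment`: a
`SummarizedExperiment` with a `log2area` assay (peak areas are
log2-transformed at ingest and every downstream intensity operation works
on that scale) and an `rt` assay (retention times, raw minutes — they are
never log-transformed). Undetected peaks are explicit missing cells;
zero-area rows are converted to missing under the default policy because
source tables encode non-detection inconsistently (a config switch errors
instead). Rows stay contiguous by peptide so per-peptide models can
recover the grouping; the usual "detected in at least two runs" screen is
`filterMinDetected()`.

## Retention-time QC

Chromatographic drift moves whole runs earlier or later, which inflates the
per-transition retention-time CV without indicating a real problem. The
adjustment is deliberately minimal: the reference for each transition is
its median RT across runs (a median, not a mean, so a few mis-picked peaks
cannot drag it), the per-run offset is the median deviation of that run's
transitions from their references, and adjusted RT is the per-cell
difference. One pass suffices — for run-constant shifts re-running the
offset computation on adjusted data returns zeros to machine precision,
which the tests assert as a fixed-point property. Nonlinear warping and
iRT calibration are deliberately out of scope.

CVs (100·sd/mean, sample sd, at least two observations) are computed on
raw minutes before and after adjustment. A transition whose ordering
follows the global drift gets a *smaller* adjusted CV; one whose ordering
contradicts the drift gets a *larger* one. Two flag rules are reported
side by side:

* **two-sided** (default): original CV < 4% *and* adjusted CV > 7% — small
  apparent variation that the adjustment reveals to be discordant;
* **single-threshold**: adjusted CV > 5%.

Both thresholds are configurable and the rules are reported separately
because large fractions of perfectly usable transitions can sit above the
single 5% line in real assays; we surface both readings rather than assert
a direction.

## The robust two-way model

For one peptide, log2 areas are additive in a transition effect and a run
effect:

$$y_{ij} = \mu + \alpha_i + \beta_j + \epsilon_{ij}, \qquad
  \textstyle\sum_i \alpha_i = 0.$$

Only the transition effects need a constraint for the science (the
between-transition ratios $2^{\alpha_1-\alpha_2}$ are the collision
pattern); we additionally centre $\beta$ to zero so the unbalanced fit is
well-posed, and report $\mu + \beta_j$ as the run level — the split is
immaterial downstream because fitted values are unchanged.

Fitting is IRLS on the observed cells (weighted normal equations through a
sum-to-zero design; no imputation). Each iteration re-estimates the
residual scale as $\hat\sigma = \mathrm{MAD}/0.6745$, floored at $10^{-8}$
so exact fits do not divide by zero, and updates Huber weights

$$w_{ij} = \begin{cases} 1 & |r_{ij}| \le k\hat\sigma \\
  k\hat\sigma / |r_{ij}| & \text{otherwise} \end{cases}$$

with $k = 1.345$ (95% Gaussian efficiency; weights stay in $(0,1]$,
matching how peak weights behave in the probe-level-model lineage this
method descends from). Tukey bisquare is available as an alternative; its
exact zeros are floored at $10^{-8}$ inside the solve so a fully rejected
cell cannot make the layout singular. Convergence is a maximum coefficient
change below $10^{-6}$ (cap 100 iterations; non-convergence is reported,
not fatal), and the reported weights are recomputed from the final
residuals. Identifiability requires at least two transitions, two occupied
runs and a connected transition-run incidence graph; peptides failing this
are skipped with a warning and listed, never aborting a batch fit.

One property of this weighting deserves a note: because weights depend on
the *ratio* of residual to MAD, they are scale-free. Even in clean
Gaussian data roughly 15–20% of cells sit beyond $1.345\hat\sigma$ and
receive weights below 1. Individual weights are therefore read
comparatively (the interfered peak is the minimum, far below 0.5), and the
QC summaries use medians: a transition passes when its median weight
across runs exceeds 0.9 (strictly), and the weight IQR separates
consistently-good from erratic transitions.

Run quality uses NUSE: for peptide $p$ in run $j$,
$SE_{pj} = 1/\sqrt{\sum_i w_{ij}}$, divided by its median across runs so
every peptide is centred at exactly 1 by construction. A run is flagged
when its median NUSE over peptides exceeds 1.05, i.e. a 5% standard-error
inflation. Runs with zero total weight for a peptide yield a missing NUSE
with a warning.

## Normalization

All five methods preserve shape, annotations, missingness and the log2
scale (a grand-level term is added back where applicable so CV
denominators stay comparable). Rows are opaque — transition-level and
peptide-level matrices are both valid inputs.

* **Global median** — run medians matched to the grand median of run
  medians. Idempotent.
* **Quantile** — each run's order statistics replaced by the cross-run
  mean quantile function. With complete equal-count data all run
  distributions become exactly identical (the tests check this against a
  brute-force order-statistic oracle and against `limma`'s
  implementation). With missing cells, ranks are taken on observed values
  and the reference is read at probabilities $(r-1/2)/n$ by linear
  interpolation of the pooled mean quantile function — a documented
  dialect that reduces exactly to the classical algorithm when nothing is
  missing. Tied values share the mean of the reference values at their
  occupied ranks.
* **Cyclic loess** — for every unordered run pair, a degree-1 loess of
  M on A (span 0.7, pairwise-complete cells, at least 20 per pair) is
  subtracted symmetrically, half from each run. Cycles stop at a maximum
  adjustment below `tol` ($10^{-3}$) or after 3 cycles. The 3-cycle cap is
  not cosmetic: once the systematic trend is removed, further cycles chase
  noise through hundreds of pairwise fits and the adjustments start
  *growing* again; a guard rolls back any cycle whose largest adjustment
  exceeds the previous cycle's and stops. One to three cycles removes
  run-constant artifacts to well under 1% of their size.
* **Subset median** — per-run median (mean available) over a declared
  control set (spiked internal-standard peptides or housekeeping
  proteins), applied as a constant shift to the whole run; it never alters
  within-run contrasts. Unknown control ids are configuration errors.
* **Invariant set** — reference is the per-feature median across runs.
  Features whose rank in a run differs from their rank in the reference by
  less than 5% of the current set size are kept, ranks recomputed,
  iterated to a fixed point. A loess trend of run versus reference fitted
  on the invariant set is inverted by interpolation (the fitted curve is
  forced nondecreasing; outside its range a slope-1 extension applies) and
  applied to every feature. The rank tolerance is proportional rather than
  absolute because MRM panels are small — hundreds, not tens of thousands,
  of features. If the invariant set falls below 10 features the run is
  returned unnormalized and flagged.

## Evaluation

Within-group spread is the yardstick. Per feature, residuals about the
group means of observed cells give $MSE = SSR/(n-K)$ — with a single group
this is just the within-replicate variance — and
$CV = 100\sqrt{MSE}/\overline{y}$ where $\overline{y}$ is the mean *log2*
area. A CV with a log-scale denominator is unconventional, but it is the
quantity this evaluation framework is defined on and it is comparable
across methods precisely because every method preserves the overall log2
level. For single-condition designs the biological samples play the role
of groups, so the CV reflects technical variation. Methods are compared by
median CV (with MAD), per-feature MSE ratios and log2 CV ratios against
the unnormalized data.

The differential screen is a per-feature Welch t-test (unequal variances,
Welch–Satterthwaite df, two groups with at least two observations each),
flagged at raw p < 0.05 by default; Benjamini–Hochberg is available behind
a flag rather than as the default because the two conventions (raw cutoff
vs 5% FDR) coexist in practice and we surface the choice instead of
resolving it silently.

## The synthetic generator

`simulateMRM()` emulates the structure the pipeline is built for: proteins
represented by ~3 peptides of ~5 transitions; runs organised as technical
triplicates of biological samples (defaults: 6 samples, single condition,
18 runs — the technical-variability layout; two-group designs use 9 + 9
where that layout is called for); peptide log2 levels uniform on 14–24;
transition effects with sd 1.5 (realistic fragment-ratio spreads of
several-fold); run effects sd 0.25 and residual noise sd 0.25 (log2);
cell-level interference outliers of ±3 log2 units; retention times per
peptide uniform on 20–60 minutes with run-constant drift (sd 0.2 min) and
small jitter; missing-at-random cells on request. One seed drives
everything and fixes the output exactly. Group effects act at the peptide
level (all transitions shift together, as fragments of one analyte must)
and are direction-balanced.

What it does *not* emulate — intensity-dependent variance, censored
(intensity-dependent) missingness, correlated interference across
transitions, chromatographic peak shapes — bounds what passing tests mean:
they validate the algorithms' behaviour under the stated model, not
instrument physics.

The named fixtures (`makeFixture()`) use noiseless intensities over the
18-run layout so that their QC verdicts are properties of the construction
rather than of a noise realization: `tiny_clean` flags nothing,
`one_bad_transition` plants one alternating ±1.5 interference pattern that
is flagged exactly, `run_artifact` shifts one run by +1 log2,
`rt_shifted` plants a known run-constant RT drift, and `two_group_de`
(with noise, since a t-test needs within-group variance) shifts 20% of
peptides in one group.

## Numerical choices and problem sizes

Degenerate inputs: exact fits hit the $10^{-8}$ scale floor and return
unit weights; constant matrices fit as $\mu$ alone; loess fits with fewer
than four distinct reference values fall back to a constant shift;
inverse interpolation collapses duplicated fitted values. Ties in quantile
normalization follow the mean-of-reference rule above. All error
conditions are typed (`mrm_config_error`, `mrm_data_error`,
`mrm_fit_error`) so callers and the CLI can distinguish configuration
mistakes (exit 1) from data problems (exit 2).

The test-suite simulations are sized to make their assertions sharp but
cheap: 50 random 5×6 peptides for the OLS-equivalence check, 200 seeded
5×18 peptides for outlier weighting and for the robust-vs-OLS comparison,
100 replicates for invariant-set membership tallies, and pooled
3×1000-feature null panels for the type-I error of the Welch screen. The
acceptance script simulates 90 peptides × 18 runs for the QC chain and a
300-feature 9 + 9 panel for the power comparison.

## Known limitations

The RT adjustment is a single global shift per run; gradient
nonlinearities need alignment methods outside this scope. The robust model
assumes at least two transitions per peptide — single-transition peptides
are reported, not fitted. NUSE medians over very few peptides are noisy;
run verdicts are most meaningful for panels of dozens of peptides or more.
Cyclic loess on many-run panels should be left at few cycles (see above).
Subset-median normalization inherits the control set's limitations:
spiked standards capture instrumental but not preparation variation, and
housekeeping controls must genuinely be stable under the treatments.
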