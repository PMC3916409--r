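---
title: "Methods: directional gene-set testing in small case-control expression studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: directional gene-set testing in small case-control expression studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliashift)
```

## The statistical model

`ciliashift` tests whether a predefined gene set is *coordinately*
down-regulated in a small two-group comparison of expression
intensities — the motivating design being bronchial biopsies from six
PCD patients against nine non-PCD controls, where modules of axonemal
genes (outer and inner dynein arms, radial spokes, intraflagellar
transport) are expected to move together.

The inference chain makes only two substantive assumptions:

1. **Per gene**: under the null, the case and control values are
   exchangeable. The one-tailed Wilcoxon–Mann–Whitney test uses only
   ranks, so no distributional form is assumed for bead-array
   intensities.
2. **Across genes**: the per-gene tests are independent. Stouffer's
   unweighted Z-method converts each one-tailed p-value to a standard
   normal deviate `Z_i = Φ⁻¹(1 − p_i)` and refers
   `Z = Σ Z_i / √k` to the standard normal upper tail.

The second assumption is knowingly optimistic for co-regulated gene
modules, and the package's simulation harness is built to *demonstrate*
rather than hide the consequence: with a within-set correlation of 0.6
and no true shift, the combined test's rejection rate at α = 0.05
exceeds 0.10 in the packaged acceptance checks. Combined p-values for
correlated sets should therefore be read as evidence summaries, not
literal error rates.

## Preprocessing

Raw linear intensities are floored at a threshold (default **5
intensity units**) and scaled by log2 (`floor_log2()`). The floor tames
the noisy low-intensity tail before ratios are formed; values at or
below it become exactly log2(5) ≈ 2.32, which creates ties that the
exact rank test handles without approximation. Flooring is monotone and
idempotent on the linear scale, and the function refuses already-logged
input rather than silently double-logging.

Quantile normalization (`quantile_normalize()`, delegated to
`limma::normalizeQuantiles` with tie averaging) is offered as optional
plumbing for matrices that arrive unnormalized; in the motivating
pipeline it ran upstream in the array vendor's software, on the linear
scale, before flooring — which is the order this package recommends
when it is used at all.

Probes are aggregated to genes by the per-sample **arithmetic mean of
log2 values** (`aggregate_probes()`), never of linear intensities: the
reference tables' group means for multi-probe genes live on the log2
scale, and averaging there is what reproduces them. Unmapped probes are
dropped with a message, because every downstream statistic is
gene-level.

## The screen

`de_table()` computes per-gene group means, the log2 fold change on the
control-over-case convention (positive = lower in cases = "down"), the
fold change `2^log2FC` — a ratio of *geometric* means, which is what
exactly reproduces every printed fold change in the reference tables
(arithmetic-mean ratios do not) — and a two-sided t-test. The t-test
defaults to **Welch** (unequal variances); the pooled Student flavor is
available via `var_equal = TRUE`. The motivating analysis said only
"t-test", so the choice is surfaced rather than hidden; no claim is
asserted against the reference t-test p-values, whose flavor is
unknowable without the raw per-sample data.

`de_screen()` applies the published rule — at least 2-fold change in
either direction with raw `p < 0.05`. No multiple-testing correction is
applied in the screen: the fold-change floor plays the
false-positive-control role (a deliberate property of the
fold-change-plus-raw-p design), and a BH-adjusted column (`padj_bh`) is
carried for information only. Degenerate variance is handled
explicitly: two constant equal groups give p = 1, constant unequal
groups give p = 0.

## Exact one-tailed rank-sum p-values

For total sample sizes up to `exact_threshold` (default **25**, so the
6v9 study scale and all leave-one-out re-analyses are always exact) the
null distribution of the case rank sum is built by dynamic programming
over doubled midranks — doubling makes midranks integers, so subset
rank-sums live on an integer lattice and ties need no special-casing.
The distribution is cached by midrank multiset, which makes large
Monte-Carlo runs over untied data essentially free. Beyond the
threshold a normal approximation with tie correction and a 0.5
continuity correction takes over; the threshold is a speed/precision
trade, not a statistical necessity.

### Discreteness and the mid-p option

A 6v9 comparison has only 55 attainable rank sums, so the exact
p-value is heavily discrete. Two conventions exist:

- **Inclusive tail** (default, `mid_p = FALSE`): `p = P(W ≤ w_obs)`.
  This is the textbook exact test and what the package's closed-form
  anchors pin (complete separation gives exactly `1/choose(15, 6)`).
  But `p` is then stochastically *larger* than uniform between lattice
  points, `Φ⁻¹(1 − p)` has negative null mean, and the Z-combination
  across a set inherits a conservative bias — the packaged simulation
  tests verify that the combined test rejects *less* often than α under
  an independent null.
- **Mid-p** (`mid_p = TRUE`): `p = P(W < w_obs) + ½·P(W = w_obs)`. The
  deviate then has exactly zero null mean by symmetry, and the combined
  test holds its nominal size: the acceptance checks verify a type-I
  error inside [0.04, 0.06] at α = 0.05 and a Kolmogorov–Smirnov
  distance below 0.02 between the null combined p-values and U(0,1).

Per-gene p-values are reported with the inclusive convention by
default, matching how such tables are conventionally printed; the
simulation harness (`run_simulation_study()`) defaults to mid-p because
its purpose is to characterize the calibrated combination. Both are one
argument away everywhere. (The reference tables themselves contain
several per-gene p-values that are not multiples of 1/5005, so the
original analysis software's tie and mid-p conventions cannot be
reverse-engineered; the module-level combined p-values are reproduced
here directly from the *printed* per-gene values, which sidesteps the
ambiguity.)

Before the inverse-normal transform, p-values are clipped into
`[1e-16, 1 − 1e-16]`. The bound keeps deviates finite while leaving
every value on the printed scale untouched; it only engages for inputs
that are exactly 0 or 1 (e.g. the inclusive-tail p = 1 of an all-tied
gene).

## The synthetic-data generator

`sim_config()`/`simulate_expression()` emulate the statistical skeleton
of the motivating study:

| parameter | default | meaning |
|---|---|---|
| `n_case`, `n_control` | 6, 9 | the study's group sizes |
| `n_genes` | 1000 | matrix size |
| `mu_range` | (2.4, 11.5) | per-gene baseline log2 means, uniform; spans the empirical range of the reference table's log2 means, so data straddle the intensity floor the way real bead-array data do |
| `baseline_sigma` | 0.5 | per-gene SD of log2 values — a typical within-group spread for bead-array log2 intensities |
| `affected_sets` | none | (name, size, delta): delta is the coordinated log2 down-shift in cases; 1 log2 unit = 2-fold |
| `correlation_rho` | 0 | within-set correlation of log2 values, induced by a single shared latent factor per set and sample |
| `floor_threshold` | 5 | the floor downstream preprocessing will apply |

A single latent factor per set is the simplest mechanism that makes set
members genuinely co-vary, which is exactly the violation of the
Z-method's independence assumption worth stress-testing. Values are
exported on the linear scale (`2^value`) so the preprocessing floor is
genuinely exercised.

What the generator does **not** model: probe-level noise, array spatial
artifacts, batch effects, heavy-tailed or sample-specific technical
variation, and any dependence *between* sets. Passing simulation checks
therefore validates the inference machinery under the stated model, not
the biology of any particular dataset.

## Monte-Carlo design choices

The harness (`run_simulation_study()`) reports, per (delta, rho, k)
cell, the rejection rate of the combined test and the mean estimated
log2 fold change of the affected genes after full preprocessing.
Problem sizes in the packaged checks: 2000 replicates for null
calibration, 1000 for effect recovery, 300–400 for power and
correlation sensitivity, 10,000 for the uniformity check — sizes at
which the binomial Monte-Carlo error is several times smaller than the
acceptance margins being tested.

Calibration, power and recovery cells place baselines **above the
floor region** (`mu_range` 6–11, recovery 6–10). The reason is
separation of concerns: genes whose case values are pushed below
log2(5) are *censored* by the floor, which attenuates both the
estimated shift and the rank signal. That attenuation is a property of
the flooring design, demonstrated on its own (the generator's default
range deliberately includes the floor zone), and should not be
conflated with the calibration or unbiasedness of the test and
estimator themselves. With signal away from the floor, the estimated
log2FC is unbiased to within ±0.05 at 1000 replicates in the packaged
checks.

Per-replicate seeds are derived from the master seed by fixed integer
offsets, so every cell is reproducible in isolation.

## Leave-one-out robustness

`leave_one_out()` re-runs the set tests and the screen once per dropped
case sample (controls behind a flag), and `stability_summary()` reduces
the drops to per-set order statistics plus an `all_significant`
flag at a configurable α (default 0.01). The motivating study's claim
that removing any single patient "does not change the result" is
operationalized exactly as that flag: every leave-one-out combined
p-value stays below α for sets significant in the full design. That is
the package's own definition — the original claim was unquantified.

## Known limitations

- The combined p-value's independence assumption is violated by
  construction for co-regulated modules; the harness quantifies the
  inflation but the package does not correct for it (no competitive or
  rotation-based null is implemented).
- The screen's t-test flavor for the reference tables is unknowable;
  both flavors are provided but neither is asserted against the printed
  t-test p-values.
- Gene identifiers are kept as printed in the reference era (legacy
  symbols with current aliases stored alongside); no identifier-mapping
  service is consulted.
- The genome-wide screen counts of the motivating study (which require
  its raw probe data) are out of scope; the packaged disease-gene table
  reproduces the published down-regulated count (10 of 24 rows) from
  printed values alone.
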