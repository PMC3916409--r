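# ciliashift

Coordinated down-regulation testing for ciliary gene sets in small
case-control expression studies.

## The problem

Primary ciliary dyskinesia (PCD) is a recessive disorder of motile
cilia; its pulmonary phenotype stems from ultrastructural defects of
the axoneme — missing outer or inner dynein arms (ODA/IDA), radial-spoke
defects, failures of intraflagellar transport (IFT). Bronchial-biopsy
expression profiling of PCD patients against non-PCD controls suggests
that whole modules of ciliary genes are transcriptionally down-regulated
together. Detecting such a *coordinated* shift in a tiny cohort (six
cases, nine controls) is a statistical problem of its own: per-gene
tests are underpowered, so evidence must be pooled across a predefined
gene set without assuming normality of bead-array intensities.

`ciliashift` implements that analysis end to end for anyone who has a
probe-level expression matrix, a case/control design and gene sets in
GMT format:

1. **Preprocessing** — intensities below a floor (default 5) are raised
   to it and the matrix is scaled by log2; optional quantile
   normalization; probes averaged to genes on the log2 scale.
2. **Screening** — per-gene fold change `FC = 2^(mean log2 control −
   mean log2 case)` (a ratio of geometric means, control over case) with
   a two-sample t-test; genes pass at `FC ≥ 2` in either direction and
   raw `p < 0.05`.
3. **Set testing (the core)** — for each gene *i* of a set of size *k*,
   a one-tailed Wilcoxon–Mann–Whitney test of the down-shift in cases
   yields `p_i`; the exact null distribution of the rank sum is built by
   dynamic programming over midranks (ties handled without
   approximation). The set-level statistic is Stouffer's unweighted
   Z-method,

   `Z = (Σ_i Φ⁻¹(1 − p_i)) / √k`,

   standard normal under the joint null of k independent tests; the
   combined p-value is its upper tail. A `mid_p` option replaces each
   exact tail by its mid-p, which keeps the combination calibrated
   despite the discreteness of the rank sum (see the vignette).
4. **Enrichment** — exact upper-tail binomial test of set membership in
   a selected gene list against a background proportion.
5. **Robustness** — leave-one-out re-analysis over case samples.
6. **Simulation** — a generator of 6v9 log-normal intensity studies with
   coordinated set shifts, and a Monte-Carlo harness for type-I error,
   power and effect-size recovery of the whole pipeline.

The package ships the published reference tables it is built to
reproduce: 37 axonemal genes in four modules (8 ODA, 10 IDA, 8 radial
spokes, 11 IFT) with per-gene one-tailed p-values and module-level
combined p-values, and 24 PCD disease genes with fold changes and
t-test p-values.

## Worked example

Combining the packaged per-gene p-values reproduces the four published
module-level combined p-values:

```r
library(ciliashift)
library(dplyr)

ciliary_de_table() |>
  group_by(category) |>
  summarise(combine_pvalues_z(wilcoxon_p), .groups = "drop")
#> # A tibble: 4 × 4
#>   category         k z_combined p_combined
#>   <chr>        <int>      <dbl>      <dbl>
#> 1 IDA             10       6.87   3.19e-12
#> 2 IFT             11       5.15   1.28e- 7
#> 3 ODA              8       5.39   3.52e- 8
#> 4 radial_spoke     8       3.70   1.06e- 4
```

`p_combined` is the upper-tail probability of the set's combined Z: the
ten inner-dynein-arm genes, for instance, are jointly shifted downward
in cases with p ≈ 3.2e-12 — overwhelming evidence of coordinated
down-regulation that no single gene's p-value (the smallest is 0.0014)
could provide alone.

The same machinery on a synthetic study with a known injected shift:

```r
cfg <- sim_config(n_genes = 200,
                  affected_sets = list(list(name = "ODA_like",
                                            size = 8, delta = 1.5)))
sim <- simulate_expression(cfg, seed = 2026)
fit <- set_shift_test(floor_log2(sim$expr), sim$design, sim$sets)
glance(fit)
#> # A tibble: 1 × 5
#>   set_name category     k z_combined p_combined
#> 1 ODA_like other        8       9.66   2.26e-22

stability_summary(leave_one_out(floor_log2(sim$expr), sim$design, sim$sets))
#> # A tibble: 1 × 6
#>   set_name n_drops    min_p median_p    max_p all_significant
#> 1 ODA_like       6 1.62e-19 1.62e-19 1.62e-19 TRUE
```

The 1.5-log2-unit (≈2.8-fold) coordinated shift is detected at p ≈
2e-22 and survives removal of every individual case (here each drop
gives complete case/control separation for all eight genes, so the six
re-analyses coincide). Screening the packaged disease-gene table
recovers the published count of down-regulated PCD genes:

```r
screened <- de_screen(pcd_de_table())
sum(screened$passes_screen & screened$direction == "down")
#> [1] 10
```

`tidy()` on a fit gives per-gene p-values and deviates, `autoplot()`
plots them, and `reproduce_reference_analysis()` re-derives every
derivable number in the reference tables and reports pass/fail.

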