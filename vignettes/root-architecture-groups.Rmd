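---
title: "Classifying root architecture groups from augmented seedling-tube designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying root architecture groups from augmented seedling-tube designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootgroups)
library(dplyr)
```

## The problem

Seedling root phenotyping campaigns that screen large germplasm panels for
drought-relevant root architecture face a practical obstacle: there is not
enough space (or seed) to replicate every genotype. The augmented block
design solves this by replicating a small set of *check* genotypes in every
block while each *test* genotype appears once; block effects are estimated
from the checks and subtracted from the tests. `rootgroups` implements this
workflow for a tube-grown wild barley panel: 114 genotypes (9 checks, 105
tests) in 5 blocks of 30 tubes, grown under two soil-moisture regimes
(90–95% and 50–55% of field capacity), 300 tubes in all.

After adjustment, each genotype is placed into one of **nine root
architecture groups** per condition: three *depth* classes from root length
(superficial, semi-deep, deep) crossed with three *density* classes from
root tissue density (non-dense, semi-dense, dense). Group 9 — deep and
dense — is the architecture of interest for water uptake under drought.

## The classification rule

For each condition, the thresholds are the bounds of the 95% confidence
interval of the mean of the genotype-level values,

$$\bar{x} \pm t_{1-\alpha/2,\,n-1}\; s/\sqrt{n},$$

with the sample standard deviation $s$ and $n$ the number of genotypes
(114 at full scale). Values strictly below the lower bound are
superficial/non-dense, strictly above the upper bound deep/dense, and
values inside the **closed** interval semi-deep/semi-dense. Two choices
here were genuinely open and are fixed as follows:

* **t versus normal quantiles.** The interval uses Student's t with
  $n-1$ degrees of freedom; at $n = 114$, $t \approx z$ and the choice is
  near-immaterial, but it must be fixed for reproducibility.
* **Boundary convention.** "Below the interval" is read as strict
  inequality, so boundary values stay in the middle class; with zero
  spread every genotype is semi-deep semi-dense (group 5).

Note that this is an interval for the *mean*, so it is narrow
($\approx 0.19\,s$ at $n = 114$): the middle class is a tight modal core,
not the central 95% of genotypes. Classification is affine-equivariant:
rescaling a trait rescales the interval identically, so class assignments
are invariant under positive affine maps — a property the test suite
exercises directly.

Whether classification should run on raw or check-adjusted values is not
determined by the procedure itself; the pipeline defaults to adjusted
values (`adjust = TRUE` in `pipeline_config()`), since removing block
effects is the point of the design, and a flag bypasses it.

## Derived traits and pigments

`derive_traits()` computes, per tube: root area $2\sqrt{V \pi L}$, root
diameter $\sqrt{4\,FW/(L\pi)}$, specific root length $L/DW$, root length
density $L/S$, root specific mass $DW/S$, root mass density $FW/S$, root
fineness $L/V$, root surface area density $L D \pi$, and root tissue
density. Units are fixed (cm, g, cm³); $S$ is the tube soil volume.

Two numerical choices deserve a note:

* **$\pi = 3.14$ by default.** The area and diameter formulas are
  conventionally printed with the truncated constant; the default
  reproduces that arithmetic bit-for-bit, and `pi_value = base::pi` gives
  full precision.
* **Root tissue density mode.** The reference analysis computes root
  tissue density as the *product* $DW \times V$, while the root-ecology
  literature defines it as the quotient $DW/V$. Both are implemented
  (`rtd_mode = "product"` is the default, `"quotient"` the standard
  form); switching modes changes only that one column. The product form
  is kept as default because the nine-group classification downstream is
  defined on it.
* **Soil volume has no default.** It is an unreported physical property
  of the tubes; examples and fixtures use 1000 cm³, but the user must
  supply it. Since root length density, specific mass and mass density
  are divisions by the same constant within a study, the choice does not
  affect classification or any scale-invariant statistic.

`compute_pigments()` applies the 96%-ethanol spectrophotometric equations
(chlorophyll a/b from A663 and A646, carotenoids from A470) in raw
equation units; the extraction dilution factor is unstated and therefore
not applied. The equations are linear and can return negative values for
extreme absorbance ratios; these are flagged with a warning, never
clamped, because no clamping rule is part of the equations.

## Check-based adjustment

`estimate_block_effects()` uses the classical augmented-design estimator:
the effect of block $j$ is the mean of its checks minus the grand check
mean, per condition and trait. `adjust_augmented()` subtracts the block
effect from every observation; tests keep their single corrected value,
checks are averaged over blocks. On noise-free additive data
($y = g_i + b_j + c$) genotype contrasts are recovered exactly (to
1e-10), and adding a constant to one block changes no contrast — both are
tested properties. The factorial check ANOVA (`factorial_check_anova()`)
is a balanced fixed-effects two-way analysis (genotype × stress) on the
tube-level check data, matching the 9 × 2 × 5 replicated core of the
design; no mixed models are attempted.

## Group statistics

* `oneway_group_anova()` decomposes genotype-level values across the nine
  groups; at full scale the degrees of freedom are 8 and 105. A constant
  trait is reported as SS = 0, F = 0, p = 1 rather than NaN.
* `lsd_compare()` flags pairs whose mean difference *strictly* exceeds
  $t_{1-\alpha/2,\,df_w}\sqrt{MS_w (1/n_i + 1/n_j)}$.
* `canonical_lda()` is canonical discriminant analysis in the pooled
  within-group scatter convention: eigenvalues of $W^{-1}B$, canonical
  correlations $r_i = \sqrt{\lambda_i/(1+\lambda_i)}$, standardized
  coefficients, a structure matrix of pooled within-group correlations and
  grand-centered group centroids. This convention is pinned down by the
  published eigenvalue/canonical-correlation pairs, which satisfy exactly
  that identity. A singular within-group scatter triggers a small ridge
  ($\varepsilon\,\mathrm{tr}(W)/p$, $\varepsilon = 10^{-8}$) with a
  warning. `stepwise_select()` offers greedy Wilks'-lambda selection
  (defaults $F_{enter} = 3.84$, $F_{remove} = 2.71$, the conventional
  thresholds); the default analysis path uses the full variable set, since
  the selection criteria of the reference analysis are unstated.
* `trait_correlations()` computes Pearson correlations across the
  genotype-level adjusted values within a condition (not across the nine
  group means, where $n = 9$ would make most significance flags
  unattainable; `correlation_scope` switches this). p-values are raw
  two-sided t tests at 5%/1%, with an optional Benjamini–Hochberg column
  in `tidy()`.
* `ward_cluster()` clusters z-scored group mean profiles with Ward's
  minimum-variance method in its squared-Euclidean Lance–Williams form
  (`hclust` method `ward.D2`), whose merge heights are monotone. Profiles
  are sorted by label before clustering so results are invariant to input
  row order. `cut_tree()` extracts flat clusters; `as_newick()` exports
  the dendrogram.

## The synthetic-data generator

`simulate_dataset()` emulates the study design so that every stage is
testable without external data: 105 tests + 9 checks × 5 blocks × 2
conditions, additive genotype, block and condition effects, Gaussian tube
noise. Each genotype carries a latent depth class (expressed through root
length) and density class (through root tissue density), with correlated
propensities (default correlation 0.3). Root tissue density is induced by
co-generating root volume and dry weight so their product hits the latent
target exactly. Secondary traits (fresh weights, seedling traits,
absorbances) follow documented linear maps with noise; positive quantities
are truncated by resampling, not clipping, so distributions stay
continuous.

The defaults are the generator's statement of the study conditions it
emulates:

* Depth class means 15/24/33 cm and density class means 0.06/0.12/0.18,
  i.e. adjacent classes separated by **three tube-noise standard
  deviations** (noise 3 cm on root length, scaled by the separation ratio
  onto tissue density); block SD 2 cm; within-class genotype SD 0.2 ×
  noise.
* Class proportions (0.44, 0.12, 0.44) for both axes. The middle class is
  deliberately a narrow modal core: because the classifier's middle band
  is the CI *of the mean* ($\approx \pm 0.19\,s$ around the grand mean), a
  latent middle class is recoverable only if it is tight and small. A
  power calculation at these defaults predicts roughly 99% recovery for
  the outer classes and ~40% for the narrow middle class, i.e. ~92%
  overall; `recovery_benchmark()` confirms this by Monte Carlo. Broad,
  evenly-populated middle classes are *not* recoverable by a CI-of-the-mean
  rule — a real limitation of the procedure, not of the generator.

What the generator does **not** emulate: non-Gaussian measurement error,
spatial gradients within blocks, genotype × stress interactions beyond an
additive shift, and any genetic structure among genotypes. Passing
recovery benchmarks therefore show the pipeline's statistical machinery is
correct under its own assumptions, not that real data meet them.

`recovery_benchmark()` chains simulate → derive → adjust → classify and
reports per-replicate class recovery and block-effect RMSE; in the
noiseless limit recovery is exactly 1 and the RMSE is 0 (at double
precision). With flat class means it flags the scenario as
non-identifiable.

## Problem sizes in the test suite

The bundled tests run the full 300-tube design where the design shape
itself is under test, and small two-block layouts (10 tubes per condition)
elsewhere; the recovery benchmark uses 50 replicates at full scale,
property checks use 100–200 randomized instances. These sizes give
Monte-Carlo standard errors well below the asserted margins while keeping
the whole suite fast on a laptop.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(
  simulate = simulation_config(seed = 7),
  traits = trait_config(soil_volume = 1000),
  out_dir = "run7"
)
manifest <- run_pipeline(cfg)
manifest$outputs
```

The output directory then holds the tube-level measurements and ground
truth, the derived trait table, block effects, adjusted genotype-level
values, the nine-group assignments, tallies and transition table, per-trait
group ANOVAs, the discriminant eigenvalue/structure/centroid tables,
correlation tables and Newick dendrograms per condition, plus a JSON
manifest (configuration echo, output list, collected warnings). Rerunning
the same configuration reproduces the outputs byte for byte.

## Known limitations

* The per-tube value is treated as the mean of the (up to five) plants in
  the tube; plant-level variation is not modelled.
* The check-based adjustment assumes additive block effects; it cannot
  correct genotype × block interactions.
* The CI-of-the-mean classifier's middle band shrinks with $\sqrt{n}$, so
  class occupancy depends on panel size — comparisons across panels of
  different sizes are not meaningful.
* The discriminant analysis is descriptive; no MANOVA significance tests
  of the functions are provided.
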