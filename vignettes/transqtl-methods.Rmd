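---
title: "Methods: interspecific sample prioritization for QTL detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interspecific sample prioritization for QTL detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(transqtl)
```

## The model

`transqtl` targets one mapping scenario: a quantitative trait controlled
additively by a causal marker whose effect is *trans*-downregulated in an
interspecific F2 hybrid population while remaining intact in the wild
panel the hybrids descend from. The trait model is

* wild and hybrid phenotype: `y_i = a * g_i + e_i`, with `g_i` the causal
  dosage (0/1/2 copies of the non-cultivar allele), `a` the additive
  effect and `e_i ~ N(0, s^2)` i.i.d.;
* noise calibration: `s^2 = Var(a * g) * (1 - VE) / VE`, so the expected
  fraction of phenotypic variance explained by the causal marker equals
  the target `VE` exactly, whatever the realized dosage distribution;
* trans-suppression (hybrids only): in every sample where an unlinked
  suppressor marker carries at least one non-cultivar allele (dosage > 0),
  the genetic term `a * g_i` is removed, leaving pure noise.

The method's premise is that samples whose genotypes, at the markers most
associated with the wild trait, resemble trait-segregating wild samples
are the hybrid samples in which the signal is least likely to be
suppressed; training tree models on probabilistic resamples enriched for
those samples should therefore recover the causal marker more often than
training on the plain hybrid panel.

## Tunable parameters

| parameter | default | domain swept | meaning |
|---|---|---|---|
| `top_marker_cutoff` | 10 | 5, 10, 15, 20 | shared markers, ranked by absolute wild trait–dosage correlation, that define the distance |
| `wild_seg_quantile` | 0.10 | 0.05–0.25 | phenotype quantile defining trait-segregating wild reference samples |
| `hybrid_seg_quantile` | 0.10 | 0.05–0.25 | same filter applied to hybrid samples |
| `metric` | gower | gower, jaccard | genotype distance over the focus markers |
| `target_ve` | 0.4 | 0.4, 0.8 | variance explained by the causal marker (effect size) |
| RF `n_trees` | 1000 | — | regression forest size; RMSE loss, permutation OOB importance |
| GBM `eta` | 0.3 | — | boosting learning rate; squared-error loss, gain importance |
| `n_iter` | 100 | — | independent model iterations averaged into a rank table |
| filter `threshold` | 0.7 | — | marker correlation above which two markers are considered redundant (strict `>`)|

Decisions where the design was genuinely open, and the choices made:

* **Absolute vs signed correlation for marker filtering.** The filter
  connects markers with `|r| > 0.7` by default, since anti-correlated
  markers are equally redundant for ranking purposes; `signed = TRUE`
  restores the literal reading. The threshold comparison is strict, so a
  correlation of exactly 0.7 does not connect.
* **Meaning of "suppressed".** Full removal of the genetic term
  (phenotype = noise) is the default; `factor` in `[0, 1]` generalizes to
  partial attenuation.
* **Noise variance.** `s^2` is set deterministically by the closed form
  above given the realized dosages, rather than being itself drawn at
  random; this makes the expected realized VE equal the target and is
  what the parameter-recovery tests verify.
* **Wild phenotype.** Simulated with the same causal marker, effect and
  target VE as the hybrids but without suppression — the weighting step
  correlates wild trait with dosage, which presumes an intact wild
  signal.
* **Segregation filter tails.** Two-tailed by default ("segregating"
  implies both phenotype classes present); `upper` / `lower` single-tail
  modes exist for sensitivity analysis. A relevant numerical fact: with a
  perfectly balanced two-tailed reference set, the Gower mean distance is
  constant in the hybrid genotype (the per-marker contribution
  `(|x| + |2 - x|)/4` is 0.5 for all `x` in `[0, 2]`), so discrimination
  under `both` comes from imbalance and multi-marker structure; Jaccard
  is nonlinear and discriminates regardless.
* **Unfiltered hybrid samples** are retained at the minimum filtered raw
  weight (baseline inclusion) rather than excluded, so training sets keep
  the panel's size and diversity; `exclude_unfiltered = TRUE` implements
  the strict reading.
* **Resampled training-set size** defaults to the full hybrid panel size.
* **Suppressor choice** excludes the causal marker's whole correlation
  component, so the suppressor is genetically unlinked to the signal it
  masks.
* **Jaccard numerator** is restricted to markers where at least one
  sample has non-zero dosage; otherwise a shared zero would count as a
  match in the numerator while the marker is absent from the denominator,
  allowing distances outside `[0, 1]`.
* **GBM round count (100) and depth (6), RF `mtry`** are the common
  regression defaults of the implementing libraries and are exposed in
  the configs; the learning rate and tree count are fixed by the method.
* **Rank direction and ties.** Rank 1 = most important (or smallest
  p-value); tied scores share the average of their ranks, so every
  per-iteration rank vector sums to `m(m+1)/2`.
* **Quantile definition.** Causal-rank quantiles use the
  linear-interpolation definition (R type 7); fractional published ranks
  imply interpolation without fixing the rule, so it is fixed and
  documented here.

## What the genotype simulator emulates — and what it does not

`simulate_wild_population()` draws two haplotypes per sample through a
Gaussian copula: alleles at markers within one LD block share a latent
block factor (`ld_rho = 0.98`) and a block-level allele frequency drawn
uniformly from `wild_maf_range = [0.1, 0.5]`. Sharing the frequency
within a block is deliberate: two Bernoulli variables with very different
frequencies cannot be strongly correlated, so heterogeneous per-marker
MAFs would cap within-block dosage correlation far below the 0.7
filtering threshold that defines a "block" downstream.

`simulate_f2_population()` crosses each F2 individual's wild parent (one
of 20 wild lines) to a fixed homozygous cultivar (dosage 0 everywhere),
then selfs the F1 with per-adjacent-marker recombination 0.02 within
blocks and free recombination across blocks. The parent's true phased
haplotypes are transmitted (they are kept by the wild simulator); panels
read from disk fall back to block-coherent phasing. Because the cultivar
parent is fixed, the expected hybrid allele frequency is half the wild
one — exactly the wild/hybrid MAF imbalance (ratio ≥ 1.5) that the
causal-marker selection rule requires. A fraction
(`1 - shared_marker_fraction = 0.2`) of hybrid markers is relabelled with
private ids, emulating partial marker overlap between panels.

Default panel shapes follow the real materials the simulator emulates
(143 wild, 140 or 124 hybrids). The scenario studies in the tests use 500
markers in blocks of 4, which the correlation filter reduces to roughly
125–150 independent representatives — the filtered panel size of the
Bari-like material. These LD parameters were calibrated once, at design
time, against that filtered-panel size.

Features of real GBS data the simulator does **not** emulate: missing
genotypes (readers admit them; the simulator emits none), genotyping
error, variable block lengths and recombination hot spots, population
structure within the wild panel, multi-QTL and dominance architectures,
and physical map positions (blocks are positional only by marker order).
Passing tests therefore demonstrate the method's behaviour under an
idealized single-QTL, clean-genotype regime, not its field performance.

## Numerical choices and degenerate inputs

* Correlations are Pearson on pairwise-complete dosages; zero-variance
  markers get correlation 0 (singleton components) with a warning and are
  dropped before filtering.
* Gower's validity weight marks a marker invalid for a pair when either
  dosage is missing or its range over the pooled comparison set is 0.
* The regression baseline uses the closed-form slope t-test
  (`t = r sqrt((n-2)/(1-r^2))`); zero-variance markers get `p = 1`,
  perfect fits `p = 0`. It is cross-checked against `lm()` in the tests.
* All stochastic stages take explicit seeds; grid replicates derive
  per-stage seeds from the master seed by a counter-based rule (successive
  draws of `sample.int(2^31 - 2)` under `set.seed(master + stream)`)
  recorded in every run manifest, so single replicates can be re-run in
  isolation.
* Constant phenotypes, empty marker intersections, components holding two
  causal markers, and all-zero Jaccard pairs raise immediate errors
  rather than propagating NaNs.

## Problem sizes used in the shipped studies

The end-to-end studies in the test suite run 50 replicates of Bari-like
panels (143 wild x 140 hybrid, 500 simulated markers filtering to ~125–150
representatives) with 25 model iterations per rank table; the
parameter-recovery study uses 200 replicates of n = 2000 single-marker
panels. These sizes give detection-rate estimates at ~±7% Monte-Carlo
resolution and VE estimates at ±0.02, which is adequate to verify the
direction and calibration claims the package makes; users exploring the
full 4 x 5 x 5 x 2 x 2 parameter grid should scale `n_replicates` and
`n_iter` up to the defaults (100 each).

## Known limitations

* The weighting scheme presumes the wild panel carries an intact,
  detectable signal at the causal marker; nothing in the method can
  rescue a marker silent in both populations.
* With strong effect sizes and fully independent filtered markers, the
  unweighted models are already near ceiling, so the weighted-vs-
  unweighted contrast is most informative at small effect sizes, low MAF,
  or strong suppression.
* Gower and Jaccard are the only metrics; both treat markers
  symmetrically and ignore LD between focus markers.
* The regression baseline fits no covariates (population structure,
  kinship), matching the simulated data but not general field data.
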