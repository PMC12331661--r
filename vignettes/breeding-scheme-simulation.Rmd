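---
title: "Methods: trial statistics, MAS models and breeding-scheme simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial statistics, MAS models and breeding-scheme simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtnbreed)
```

This vignette records the models behind each stage of the package, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic data do and do not demonstrate.

## The trial model and its statistics

A germplasm panel of inbred varieties is phenotyped in `E` environments
under a randomized complete block design with `R` blocks; each plot record
is a multi-plant mean of a count-like trait. The analysis model is

$$y_{erv} = \mu + E_e + B_{r(e)} + G_v + (GE)_{ve} + \varepsilon_{erv}.$$

`pheno_anova()` computes the least-squares decomposition from cell means,
which is exact for the complete balanced layouts it requires (it refuses
incomplete or single-block designs, naming the missing stratum). Every F
ratio is taken against the error mean square — the convention under which
published multi-environment ANOVA tables of this kind reproduce arithmetically
— rather than a random-effects EMS ladder, and p values come from the F
distribution.

`variance_components()` uses method-of-moments estimators from the expected
mean squares with genotype and genotype-by-environment random:
$\hat\sigma^2_e = MS_{Error}$, $\hat\sigma^2_{GE} = (MS_{GE} - MS_{Error})/R$,
$\hat\sigma^2_G = (MS_G - MS_{GE})/(ER)$, with negative estimates floored at
zero before heritability is formed. This closed form was chosen over
REML deliberately: it is exactly unbiased on the balanced data the generator
produces and testable against an independent oracle without a solver. On
unbalanced data REML and the moment estimators diverge slightly; for
example, plugging the published mean squares 245.538 / 69.915 / 23.949 of a
455-variety, five-environment, three-block trial into the moment formulas
gives $\hat\sigma^2_G = 11.708$ and $\hat\sigma^2_{GE} = 15.322$ where the
trial's own REML software reported 12.421 and 15.357 — the difference is a
property of the estimators under that trial's missing cells, not an error.

Broad-sense heritability is on a variety-mean basis:

$$h^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{GE}/E + \sigma^2_e/(ER)},$$

monotone increasing in $\sigma^2_G$, `E` and `R` and decreasing in the
other components (property-tested over random parameter grids). At the
components above with `E = 5`, `R = 3` it evaluates to 0.727.

Descriptive statistics are computed on per-variety means within
environment, because published panel descriptives reflect variety-level,
not plot-level, dispersion. Skewness and kurtosis use the sample-adjusted
(SAS-convention, "type 2") estimators, matching the software tradition of
these trials.

## MAS models and superior-allele accounting

The two homozygous genotypes of each QTN are coded −1 and +1. One multiple
regression per environment of the variety-mean trait on all QTN codes plus
an intercept gives the per-environment effect of every QTN simultaneously.
Design choices:

* **All loci enter at once, unshrunk.** The model is descriptive of the
  panel, not predictive; `r2` is in-sample. Under a permuted (null) trait
  the expected in-sample $R^2$ is about $p/(n-1)$ (≈ 0.196 for 89 markers
  on 455 varieties) — an overfitting floor the tests document so users do
  not read small fitted $R^2$ values as signal.
* **Failure is loud.** `n ≤ p` or collinear (including sign-flipped
  duplicated) marker columns raise errors naming the offending markers; no
  silent ridging.
* **Superior alleles** follow the sign rule: positive effect → +1 superior,
  negative → −1. Exactly zero effects get no superior allele and are
  excluded from NSA denominators, avoiding an arbitrary sign.
* **Heterozygotes**, absent among inbred parents but unavoidable in
  simulated early generations, are coded 0 (additive midpoint) in genotype
  values and contribute ½ to NSA.
* **Genotype values are floored at 0 by default** because a count-like
  trait cannot go negative while the linear predictor can; the switch is
  recorded in model files, and ranking during selection always uses the raw
  predictor so flooring cannot create ties among poor lines.

## The forward simulator

Physical QTN positions become map positions at a constant rate (default
1 cM/Mb, configurable); recombination between adjacent loci follows the
Haldane map function $r = \tfrac12(1 - e^{-2d})$ with no crossover
interference, implemented as a sequential Markov walk along each chromosome
(start haplotype uniform, switch with probability `r`), chromosomes
assorting independently. The kernel is compiled (Rcpp) and draws from R's
RNG, so runs are fully reproducible under a seed. The simulator's physics
are pinned by tests: 1:2:1 F2 segregation, heterozygosity halving per
selfing generation, Monte-Carlo agreement with the Haldane closed form at
10 cM, and conservation of midparent genotype value under selection-free
descent.

A breeding scheme fixes the advancement method, F2 size, per-family
generation sizes (defaults F1 10, F3–F4 30, F5–F7 50) and the selection
plan. Choices made where the source procedure is under-specified:

* **Selection ratios.** Selection acts at F2, F4, F6 and F7 among and
  within families and at F5 within families only; the exact published
  ratios are not recoverable, so the defaults are `af = 0.5`, `wf = 0.1`
  (F5: `af = 1`). They are configuration, not constants, and absolute
  progeny counts are therefore not comparable to any published count.
* **Selection criterion** is the MAS genotype value — deterministic given
  the genotype — mirroring selection on simulated genotype rather than on
  noisy phenotype. For realism studies, `advance(selection_h2 = )` overlays
  Gaussian noise on the criterion so that its realized heritability at each
  selection stage equals the given value; reported genotype values remain
  noise-free.
* **Rounding and ties.** Selected counts round up with a minimum of one
  survivor per kept family; truncation sorts stably by (GV descending,
  index ascending) so runs are reproducible.
* **Bulk line derivation** happens at F5 (configurable), honouring
  within-generation selection there: before F5 a bulk family advances as
  one mixed population; from F5 on, each selected plant founds a
  single-plant line.
* **Per-cross RNG streams** are derived from the master seed and a stable
  cross index, so any subset of the half-diallel reproduces the
  corresponding slice of a full run.

Terminal F7 lines are scored by genotype value and NSA, pooled into
half-open histograms on a grid anchored at 0 (default width 3, matching the
granularity at which such count traits are tabulated; the grid is reported
with every selection so rule sensitivity is auditable). The optimal-scheme
rule takes the two highest occupied bins of the pooled distribution —
verified against a brute-force raw-line scan — and the breeding-goal rule
uses strict exceedance ("over" a threshold) with a configurable minimum
line count (default 1, since no stricter minimum is published).

## The synthetic-data generator

The generator is the package's stand-in for a real germplasm panel and
emulates: per-environment QTN effects with an equicorrelation structure
(`env_corr = 1` means no QTN-by-environment interaction), an inbred panel
with independent loci at allele frequencies drawn in a configurable range,
and phenotypes with additive QTN signal, a polygenic variety effect,
genotype-by-environment and block effects and plot error, all Gaussian.
Defaults used across the tests and the analysis scripts reflect the study
conditions of a 455-variety, 89-QTN, five-environment, three-block trial
with variance components near (12.4, 15.4, 23.9); environment means and the
QTN share of genetic variance are free parameters, since neither is
published, and the analysis scripts set them once (means 5.7–9.1 trait
units, QTN effect SD 0.35 giving roughly a third of the genetic variance)
at values a breeder would call realistic for a pod-count trait.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: linkage disequilibrium between QTNs, population
structure and subgroups, missing plots (the real trial's ANOVA df imply
missing cells), non-Gaussian count skew (a `nonneg` floor exists but is
cosmetic and off by default because flooring breaks the ANOVA error
model), dominance and epistasis, and genotyping error. Conclusions about
estimator behaviour under those features need real data.

## Problem sizes

The test suite uses panels of 6–455 varieties and 1–89 QTNs: Monte-Carlo
checks run at 10⁴–10⁵ gametes; heritability recovery averages 20
independent 455 × 5 × 3 trials; the rule-equivalence checks use 50 random
instances; and the end-to-end demonstration runs 50 crosses × 6 schemes on
a 30-variety, 20-QTN panel. The half-diallel of 455 parents (103,285
crosses) is enumerated exactly but simulated only on subsets, which the
per-cross RNG streams make representative of the full run.

## Known limitations

Moment-based variance components require balance; there is no REML path.
The MAS model has no dominance or epistasis terms and no cross-validated
accuracy. The simulator does not model doubled haploids or four-way
crosses. Scheme nomination considers one
environment at a time; cross-environment intersection of nominated schemes
is left to downstream tabulation.
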