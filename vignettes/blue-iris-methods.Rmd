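---
title: "Methods: quantitative iris colorimetry, cluster tests, and pedigree-aware association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative iris colorimetry, cluster tests, and pedigree-aware association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`blueiris` implements a pipeline for studying blue-iris pigmentation as a
quantitative trait: photographs are reduced to per-individual median CIE
chromaticity, the shape of the resulting phenotype distribution is tested
for two clusters versus one, and candidate-region variants are tested for
association with the phenotype in a linear mixed model that accounts for
pedigree relatedness. This vignette records the models, the tunable
parameters, and the design decisions that were genuinely open.

## Colorimetry

Iris colour is measured in CIE L\*a\*b\* (D65 white point, 2° observer).
Each photograph is reduced to the median a\* (green–magenta) and median b\*
(blue–yellow) over the masked iris pixels. L\* is computed but never
summarized: it tracks illumination, not pigmentation. Medians of
even-length samples are the mean of the two middle order statistics.

Three preprocessing decisions matter:

* **White balance.** The original interactive automatic adjustment is not
  reproducible, so `white_balance()` uses gray-world scaling: each channel
  gain is set so the channel means over the neutral reference region are
  equal. The reference region is the background (complement of the iris
  mask) when any exists, otherwise the whole image; the gains apply to all
  pixels. The step is deterministic, idempotent up to 8-bit rounding, and
  can be disabled.
* **Highlight/shadow exclusion.** Pixels with all three channels above 250
  (white specular reflections) or all three below 10 (shadows) are
  excluded. The *all-channel* rule is deliberate: both artifact classes are
  achromatic, and an any-channel rule would discard saturated blue iris
  pixels, biasing b\*. `channel_rule = "any"` preserves the alternative. A
  photograph whose iris retains no usable pixel is excluded from the study
  with a logged reason rather than silently summarized.
* **Colour standard.** sRGB companding uses the IEC 61966-2-1 piecewise
  gamma; the RGB→XYZ matrix is the published 7-digit sRGB/D65 matrix, and
  the reference white is taken as that matrix's row sums so that the gray
  axis (R = G = B) maps to a\* = b\* = 0 exactly rather than to ~1e-5.

## Two clusters versus one

Within a group, the phenotype vector $x$ is fitted by a single normal
(MLE, variance divisor $n$) and by a two-component normal mixture
(EM), and compared through $\lambda = 2(\ell_{mix} - \ell_{normal})$.
Because the null hypothesis sits on the boundary of the mixture parameter
space, $\lambda$ has no usable asymptotic reference; instead an empirical
null is built by a parametric bootstrap: $B$ datasets of the observed size
are simulated from the fitted single normal and refitted with the identical
configuration. The p-value uses the add-one estimator
$(n_{exceed}+1)/(B+1)$, which is never exactly zero and has attainable
minimum $1/(B+1)$; the default $B$ = 100,000 matches a full-scale analysis,
and $B$ = 999 is used throughout the test suite and analysis scripts.

**Keeping the likelihood honest.** The unconstrained mixture likelihood
diverges as a component collapses onto a single observation. Two guards are
used, and both are part of the model definition (the bootstrap applies them
identically on the null side):

* a numerical variance floor of `vfloor_rel` (default 1e-6) times the
  sample variance, and
* a relative constraint `var_ratio_min` (default 0.01) bounding the ratio
  of the two component variances, in the spirit of Hathaway's constrained
  mixture MLE.

The floor alone is not enough: with it, the global optimum on samples of
eight is almost always a spurious component sitting on one observation at
the floor, which inflates the null distribution of $\lambda$ and destroys
the power of the bootstrap test. The ratio constraint removes exactly those
solutions while keeping genuinely tight, comparable-spread clusters
feasible — including the extreme case of two point masses, where both
variances land on the floor with ratio 1. The constrained M-step is exact:
when the unconstrained variance update is infeasible the update moves to
the boundary $v_{small} = c\,v_{big}$ with the profile optimum
$v_{big} = (A/c + B)/n$.

**Finding the optimum.** EM runs from a deterministic schedule of starts:
the single-normal solution itself (a fixed point, which guarantees
$\lambda \ge 0$), a symmetric split of it, and — because the local optima
of the constrained likelihood correspond to tight contiguous blocks of the
sorted sample — block-vs-complement partitions. For $n \le 12$ every
contiguous block is scored by its initial log-likelihood (closed form,
cheap) and EM is run from the best-ranked ones within the restart budget
(default 10); for larger $n$, quantile-spaced tail splits plus random
assignments are used. On small samples this reliably attains the global
constrained optimum: the test suite checks agreement with an independent
grid-plus-simplex maximizer to 1e-3 on fifty datasets, and observed
agreement is ~1e-9.

**Small-sample power.** With eight observations the mixture's three extra
parameters let it track noise, so the empirical null of $\lambda$ is wide
(median ≈ 5). Separations of ~4 within-component standard deviations are
therefore not reliably detectable at $n = 8$ at strict significance levels
— the per-observation Kullback–Leibler divergence between such a mixture
and its best single-normal fit is only ≈ 0.11, so even the optimal test of
those two distributions has single-digit power at $\alpha$ = 0.01. The test
suite measures this directly. Separations of ~10 within-component sds, the
regime the two-species b\* contrast actually occupies, are detected
essentially always.

**Relatedness-aware subsets.** To avoid pseudo-replication from relatives,
`min_related_subset()` retains a maximal subset with all pairwise kinship
coefficients ≤ 0.125 (avuncular). Finding the maximum such subset is an
independent-set problem, so a deterministic greedy heuristic is used
(repeatedly remove the individual with most conflicts, ties broken by
removing the lexicographically last identifier); the unit tests confirm it
attains the exhaustive-search optimum on small instances.
`subsample_comparison()` then draws `m` = 1,000 size-`k` = 8 subsamples
from a larger group's pool and counts how many reach the clustered group's
statistic, putting groups of different sizes on a common footing.

## Pedigree kinship

Kinship coefficients use the standard recursion (parents processed first):
$\phi_{ii} = (1+\phi_{f_i m_i})/2$, $\phi_{ij} = (\phi_{f_i j} +
\phi_{m_i j})/2$; founders are pairwise unrelated and non-inbred, and
unknown parents are treated as unique unrelated founders. The random-effect
covariance passed to the mixed model is the numerator relationship matrix
$K = 2\phi$ (diagonal 1 for non-inbred individuals), the convention of the
mixed-model association software family; positive semi-definiteness is
verified by eigendecomposition (tolerance −1e-8 relative). A strict,
acyclic pedigree is assumed; partially known or uncertain relationships are
out of scope.

## Mixed-model association

Phenotypes are quantile-normalized to a standard normal — ranks (average
for ties) mapped through $\Phi^{-1}((r-0.5)/n)$ — except for the
categorical two-species phenotype, which is coded 2 (brown-iris species)
versus 1 (blue-iris species) and used raw. A constant phenotype is an
error, not a silent zero vector. Age enters as *adjusted age* = 2·age /
max age, unitless in [0, 2]; the species' maximum age is a required
configuration input (the synthetic default is 30 years, a realistic
captive-macaque lifespan).

Candidate covariates (adjusted age, sex, origin) are screened one at a
time as the focal fixed effect in the mixed model; those with Wald
p < 0.05 are retained, with collinear retentions dropped in screening
order. The association model for each variant is

$$ y = W\alpha + x\beta + u + \varepsilon, \quad u \sim N(0, \sigma_g^2 K),
\quad \varepsilon \sim N(0, \sigma_e^2 I). $$

The variance ratio $\lambda = \sigma_g^2/\sigma_e^2$ is estimated by REML
(the default of the cited software family; ML is available) through a Brent
search over $\log\lambda \in [-10, 10]$ on the eigenbasis of $K$, so each
candidate costs one weighted least-squares solve. $\hat\beta$ and its
standard error come from GLS at $\hat\lambda$; $\hat\beta^2/se^2$ is
referred to $\chi^2_1$. This is a large-sample reference — at small $n$ the
statistic is closer to $t^2_{n-p}$, so p-values near the threshold deserve
caution; the calibration test at $n$ = 40 finds no detectable departure
from uniformity under the null. Missing genotypes are mean-imputed per
variant by default (`missing = "drop"` drops individuals); a variant that
is constant after handling is reported as an `NA` row, never dropped from
the table. With $K = I$ the ratio is not identifiable and the fit reduces
to ordinary least squares, which the suite verifies to 1e-6 against `lm()`.

## Variant tables from aligned haplotypes

`segregating_sites()` scans alignment columns for exactly two distinct
bases among the ingroup haplotypes (gaps and N treated as missing; more
than two alleles excluded with a warning). Ancestral state is the outgroup
base when it matches an observed allele; otherwise the site is flagged
unpolarized and the major allele listed as ancestral. Positions are
reported as signed offsets from the anchor column (the column orthologous
to the human iris-colour SNP rs12913832) counted on the *ungapped*
reference sequence, so insertion columns where the reference is gapped do
not shift coordinates and themselves have no offset. Derived-allele
frequencies are computed over founder haplotypes of each group only, to
avoid double-counting transmitted alleles; groups with no genotyped founder
at a site report `NA`.

## The synthetic-data generators

Every input has a generator with known ground truth: elliptical iris
images with Gaussian channel noise and exact counts of planted all-channel
highlights (> 250) and shadows (< 10); random colony pedigrees (founders
plus generations of offspring with both parents drawn from earlier
generations); Mendelian gene dropping from Bernoulli founder haplotypes;
phenotypes from the same fixed-plus-kinship-random-effects model the
association stage fits; mixture or single-normal phenotype pools; and
alignments with substitutions planted at chosen anchored offsets, optional
reference-gap columns, and an outgroup carrying ancestral states.

Defaults mirror the study conditions the pipeline targets: group sizes of
8 lemurs, 33 captive and 19 wild macaques, 119 humans and 6 spider
monkeys; two species at base b\* separation 15 with pixel noise sd 2;
variance components $\sigma_g^2 = \sigma_e^2 = 1$ with a causal effect
$\beta$ = 1.25 at founder frequency 0.4 among 11 variants. Pixel and
phenotype noise are Gaussian — the simplest choice consistent with the
normal-model tests. What the generators deliberately do *not* emulate:
iris texture, pupil/limbus structure, spatially correlated illumination,
chromatic highlight fringes, genotyping error, or linkage disequilibrium
between variants (founder haplotypes are independent across variants).
Passing tests therefore certify the statistical machinery under the
model's own assumptions, not robustness to all features of real
photographs or real colonies.

Within the iris mask, non-planted noisy channels are clipped to [10, 250]
so that the planted artifact counts are exact; with mid-range base colours
and noise sd ≤ 3 the clipping is never active in practice.

## Problem sizes and reproducibility

Every stochastic operation takes an explicit seed, and the pipeline is
bit-reproducible given (seed, configuration). The test suite uses B = 999
bootstrap replicates, 500-replicate calibration runs at n = 8 (cluster
test) and n = 40 (association null), 200-replicate recovery runs at
n = 100, and 100 random toy alignments — sizes chosen so the full suite
completes in a few minutes while keeping Monte-Carlo error well inside the
asserted tolerances. `scripts/acceptance.R` regenerates the full synthetic
study from a command-line seed and recomputes the headline quantities from
scratch.

## Known limitations

* The greedy minimal-relatedness subset is maximal, not always maximum.
* Wald p-values use the $\chi^2_1$ reference; no small-sample correction.
* No multiple-testing adjustment is applied (per-variant p-values are
  reported unadjusted), and mixtures with more than two components,
  multivariate (joint a\*, b\*) clustering, and marker-based relatedness
  are out of scope.
* The two-cluster test has little power at n = 8 unless clusters are
  separated by many within-component standard deviations (see above).
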