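# blueiris

Quantitative analysis of blue-iris pigmentation as a convergent trait:
photograph-based CIE L\*a\*b\* colorimetry, parametric-bootstrap tests of
two phenotype clusters versus one, pedigree kinship, and linear mixed-model
association of candidate-region variants with quantitative and categorical
iris phenotypes. The package is aimed at researchers quantifying iris (or
other surface-colour) phenotypes from photographs across related
individuals or sister species, and at anyone needing a small, fully seeded
mixture-LRT / kinship-LMM toolkit.

## What it computes

**Colorimetry.** Masked iris pixels are white-balanced (gray-world),
stripped of achromatic artifacts (all three channels > 250: specular
highlights; all three < 10: shadows), converted sRGB → XYZ (D65, 2°) →
CIE L\*a\*b\*, and summarized as median a\* (green–magenta) and median b\*
(blue–yellow). L\* is excluded as lighting-dependent.

**Two clusters versus one.** For a phenotype vector $x$,
$\lambda = 2\,(\ell_{\hat{mix}} - \ell_{\hat{N}})$ compares the best
two-component normal mixture (constrained EM, ranked-partition restarts)
with the single-normal MLE. The null distribution of $\lambda$ is built by
a parametric bootstrap from the fitted single normal ($B$ datasets, same
fitting configuration) and the p-value is $(n_{exceed}+1)/(B+1)$.
`min_related_subset()` (pairwise kinship ≤ 0.125) and
`subsample_comparison()` (1,000 random size-8 subsamples) support
comparisons across groups of different size and relatedness.

**Kinship and association.** `kinship_from_pedigree()` implements the
standard recursion ($\phi_{ii} = (1+\phi_{fm})/2$,
$\phi_{ij} = (\phi_{fj}+\phi_{mj})/2$); the mixed model
$y = W\alpha + x\beta + u + \varepsilon$, $u \sim N(0, \sigma^2_g K)$ with
$K = 2\phi$, is fitted by REML on the eigenbasis of $K$, and each variant
is tested with the Wald statistic $\hat\beta^2/se^2 \sim \chi^2_1$.
Phenotypes are quantile-normalized (rank-based inverse normal); candidate
covariates are screened one at a time at $\alpha = 0.05$. Aligned
haplotypes are reduced to a variant table with offsets anchored to the
column orthologous to human SNP rs12913832, outgroup-polarized alleles, and
founder allele frequencies per group.

**Synthetic data.** Generators for iris images, pedigrees, Mendelian
genotypes, kinship-structured phenotypes, mixture samples, and haplotype
alignments — each returning its ground truth — so the whole pipeline is
testable end to end without any external data.

## Worked example

The numbered scripts under `analysis/` run the whole study; `01` simulates
it, the rest consume only the files written by earlier stages.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_quantify.R
Rscript analysis/03_cluster.R
Rscript analysis/04_association.R
```

Output (seed 1):

```
Wrote 8 photographs (two species, base b* separated by 15)
Pedigree: 54 individuals; genotypes at 11 variants (causal: v6, beta = 1.25)
Alignment: 14 haplotypes + outgroup, planted offsets -630, -76, -33, -6, 338
Quantified 8 irises; median b* recovered within 0.53 of truth
Species mean b*: black = 7.3, blue-eyed = -7.6
axis a: lambda = 12.66, B = 999, p = 0.039
axis b: lambda = 23.40, B = 999, p = 0.002
Subsampling: 0 of 1000 size-8 subsamples of the continuous-variation pool
  reach the pooled-species b* statistic
Retained covariates: adjusted_age
Top variant: v6 (beta = 0.82, p = 1.66e-05) — the causal variant
Variant table: 5 segregating sites at offsets -630, -76, -33, -6, 338
```

Reading the numbers: the two species' irises separate cleanly on the
blue–yellow axis (mean b\* 7.3 vs −7.6, recovered from pixels within 0.5 of
the generating colour). The pooled b\* sample is far better described by
two clusters than one (λ = 23.4; only 1 of 1000 bootstrap null statistics
is as large, p = 0.002), whereas none of 1,000 size-matched subsamples of a
continuously varying group shows clustering that extreme. In the pedigreed
colony, covariate screening keeps adjusted age, and the mixed-model scan
ranks the planted causal variant first at p = 1.7e-05. The
`results/variant_table.tsv` file lists each segregating site with its
anchored offset, `ancestral > derived` alleles, and per-group founder
frequencies.

Equivalent calls are available directly in R (`run_quantify()`,
`run_cluster_tests()`, `run_association()`, `gen_study()`); see the
methods vignette (`vignettes/blue-iris-methods.Rmd`) for the models,
parameter defaults, and design decisions.

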