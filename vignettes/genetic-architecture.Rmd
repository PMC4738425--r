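---
title: "Dissecting quantitative-trait architecture in wild pedigreed populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting quantitative-trait architecture in wild pedigreed populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

polyarch implements a replicated analysis pipeline for asking, in two wild
populations that share a SNP panel and a linkage map, whether quantitative
traits are controlled by many loci of small effect or a few loci of large
effect, and whether the two populations share their architecture. The
pipeline combines five partly independent lines of evidence: animal-model
heritability from pedigree and from genomic relatedness, chromosome
partitioning of additive variance, variance-components QTL linkage
mapping, kinship-corrected single-SNP association on expected phenotypic
values, and sparse multi-SNP Bayesian regression. A two-population
synthetic data generator makes every stage testable without field data.
This vignette records the models, the defaults and why they were chosen,
the numerical decisions, and what the synthetic experiments do and do not
demonstrate.

## The animal model and its REML engine

Every variance-decomposition stage rests on the Gaussian mixed model

$$ y = X\beta + \sum_t Z_t u_t + e, \qquad
   u_t \sim N(0, \sigma^2_t K_t), \quad e \sim N(0, \sigma^2_e I), $$

where one random term's covariance $K$ is a relatedness matrix — the
pedigree numerator matrix $A$, a genomic matrix $G$, a blended $G^*$, or a
locus-specific IBD matrix — and further i.i.d. terms absorb year, nest and
permanent-environment variance for repeated measures. `fit_reml()`
maximizes the restricted likelihood by average-information updates with an
EM-flavoured opening step and step-halving; non-negative components are
projected to a small positive floor and excluded from the update while
their gradient points outward, which is the boundary behaviour the 50:50
mixture null of the likelihood-ratio test assumes (`mixture_pvalue()`:
an LRT of 2.706 gives p = 0.05). Convergence is declared when the
restricted log-likelihood moves by less than `tol` (default `1e-6`);
the likelihood carries the $\log|X'X|$ convention so it is invariant to
fixed-effect reparameterization. With exactly one relatedness term plus a
residual, the model is rotated into the eigenbasis of $K$, after which
every iteration is $O(n)$; the eigendecomposition can be attached to $K$
and reused, which makes replicate fits on a fixed pedigree essentially
free and is how the package's recovery experiments afford 50 replicates at
$n = 800$.

Heritability is reported as $h^2 = \sigma^2_A / \sum_t \sigma^2_t$ with a
delta-method standard error from the inverse average-information matrix.

## Relatedness matrices

`build_A()` uses the tabular recursion over the whole pedigree.
`build_G()` is the centred cross-product matrix
$G_{ij} = \sum_m (x_{im} - 2p_m)(x_{jm} - 2p_m) / \sum_m 2p_m(1-p_m)$,
with pairwise-complete normalization under missingness, and an optional
variance-in-relatedness anchoring against $A$ (off-diagonal spread matched
over pedigree-linked pairs, mean diagonal anchored).
`blend_G_with_pedigree()` shrinks marker relatedness towards its pedigree
expectation, $G^* = wG + (1-w)A$ with $w = M/(M + 1000)$ by default
($M$ = marker count): sparse panels lean on the pedigree, dense panels on
the markers. A note on this rule: when a simulated trait's causal loci are
a subset of the markers, the generating covariance is the realized marker
relatedness itself, and any shrinkage towards $A$ attenuates the realized
Mendelian-sampling deviations and inflates $\hat\sigma^2_A$ by roughly the
ratio of inner products of the true and modelled covariances (about 9% at
$w = 0.67$). At the panel scale the pipeline targets (several thousand
markers, $w \ge 0.8$) the effect is well inside the estimator's sampling
error, which is why the recovery experiments use a 5,000-marker panel.
A ridge of `1e-6` is added to blended diagonals for factorization.

Cross-population matrices centre each individual's dosages by its own
population's allele frequencies, which removes mean frequency differences
from the between-population block; the equality-of-variances test
(`compare_crosspop_variances()`) then fits population-specific additive
variances plus a free between-population genetic covariance, against a
model with the variances tied, on a full $\chi^2_1$ (the constraint is
interior, unlike the boundary tests).

## QTL linkage mapping

`estimate_ibd_grid()` computes expected pairwise IBD on a 5-cM grid. The
engine is a conditional gene-drop particle filter written in C++: each
particle carries phased founder alleles at the two markers flanking the
grid position and founder-origin labels at the position itself; every
meiosis samples its three inheritance indicators from the Haldane
transition prior restricted to the child's observed flanking dosages, the
restriction mass feeding the particle weight, with systematic resampling
whenever the effective sample size halves. Plain sequential importance
sampling was tried first and degenerates on five-generation pedigrees
(terminal effective sample sizes near 1), which motivated the resampling
step. The sampler is exact against exhaustive enumeration on nuclear
families, reverts to the pedigree expectation far from informative
markers, and two independent runs at the default 400–2,000 samples differ
by an order of magnitude less than the genuine departure of IBD from its
pedigree expectation. Conditioning on the two nearest flanks (rather than
full multipoint peeling) is the deliberate scope compromise: it is
oracle-testable, fast, and converges to the same expectation as marker
density grows.

`qtl_scan()` fits polygenic-plus-QTL versus polygenic models at every
position, with `LOD = LRT / (2\ln 10)`; per-position fits warm-start from
the polygenic fit and use a `1e-4` likelihood tolerance (three orders of
magnitude below the 0.001 LOD display precision). `lod_thresholds()`
solves the dense-map expected-exceedance equation
$\mu(t) = [C + 2\rho G (2\ln 10)t]\, p_{\mathrm{nom}}(t)$ by bisection for
one expected chance exceedance per scan (suggestive) and 0.05
(significant), with $\rho = 1$ for a general-pedigree design; for
$C = 31$, $G = 19.16$ morgans this gives LOD 0.588 / 1.620 / 3.057. The
calibration experiment in the test suite runs null scans on a synthetic
map built to that same specification (31 chromosomes, 19.16 morgans,
~1,530 informative framework markers at 0.3–0.5 minor allele frequency, a
5-cM grid, ~200 genotyped individuals) because the exceedance theory is
regime-dependent: on aggressively shrunken maps the suggestive threshold
falls so low that a 5-cM grid behaves like independent tests and crosses
the level two to three times per scan, while at the published map scale
the measured rate sits near one.

`power_simulation()` drops a biallelic locus through the stored meioses of
the marker panel (so it co-segregates with the map), simulates traits
with the locus explaining 0–40% of phenotypic variance over a polygenic
background (default 30%), and tabulates detection rates at the three
thresholds together with the mean estimated variance share among
detections — the classic upward bias of significant effect sizes (the
Beavis effect) falls straight out of the selection step.

## Association, effective tests, and the multi-SNP model

`compute_EPV()` reduces repeated measures to one value per individual:
fixed effects and the predicted non-individual random effects (year,
nest) are subtracted, records are averaged within individuals, and the
result is standardized. Individual-level random terms are deliberately
rejected there, because a permanent-environment BLUP would absorb the
genetic signal the association stage is meant to find.

`score_test_scan()` fits the null polygenic covariance once (in the
kinship eigenbasis) and computes for each centred dosage vector $g$ the
score statistic $T = (g'Py)^2 / (g'Pg)$ with its $\chi^2_1$ p-value and
the effect estimate $g'Py / (g'Pg)$; genomic-control $\lambda$ is
reported. `effective_tests()` walks each chromosome in map order and
counts $1 + \sum_j \sqrt{1 - \max r^2_j}$ over a 50-SNP sliding window — a
pairwise-bound style reduction that hits the exact limits (independent
SNPs count fully, duplicates count zero, perfect-LD blocks collapse to
their rank) and is cross-checked against an eigenvalue oracle in the
tests. `bonferroni_threshold()` is $\alpha / K_{\mathrm{eff}}$.

`run_bvsr()` is Metropolis–Hastings over the model indicator $\gamma$, a
log-uniform inclusion probability $\pi \in (1/p, 1)$, and a uniform
proportion-of-variance hyperparameter $h$ that sets the effect-size scale
$c = h / ((1-h)\sum_{j\in\gamma} v_j)$; proposals are 40% add / 40% remove
/ 20% swap, with intercept and residual variance integrated out
analytically. Defaults mirror the study design: three chains of 110,000
iterations, thinning 10, burn-in 10,000. PVE per recorded iteration is
Rao-Blackwellised through the conditional posterior mean of the included
effects; summaries are equal-tail 2.5/97.5 percentiles of the pooled
thinned samples, and chains failing a split-half potential-scale-reduction
check (threshold 1.1) are excluded with a message, never silently pooled.
On a three-SNP space with pinned hyperparameters the sampler matches
exact enumeration of all eight models within 0.02. The model does not
correct for relatedness, matching the published design; pre-regression of
EPVs on kinship eigenvectors can be emulated through the merged-scan
covariate machinery if needed.

## Concordance tests

Cross-population and cross-method agreement use: chromosome-block
permutation of whole scans (which preserves within-chromosome
autocorrelation, so its null is wider than a naive per-site permutation —
verified as a property test); linear interpolation of scan LODs to SNP
map positions; a 2×2 chi-square (Fisher below expected counts of 5) for
GWAS×QTL nominal overlap; a two-tailed Fisher test for
partitioning×QTL chromosome flags; a shared-significant-chromosome tail
probability in both a binomial and a margin-conditioned hypergeometric
parameterization (the hypergeometric mode matches exhaustive enumeration
exactly); and a Pearson correlation with a t-test for the per-trait
posterior median SNP numbers, one-sided by default with the two-sided
value also reported. All permutation p-values use the plus-one rule and
are never zero. Run on the published per-trait medians for the seven
traits shared between the two study populations
(`nsnp_medians_example()`), the correlation is r = 0.80 with one-sided
p = 0.016.

## The synthetic study generator

`sim_config()` fixes the world the tests live in: two populations founded
independently but with founder allele frequencies correlated at 0.98
(emulating the weak differentiation of the study populations, global
F_ST ≈ 0.01); overlapping generations from adult survival of 0.45 between
seasons, random within-population pairing with one brood per pair-year,
Poisson brood sizes (mean 4) and chick recruitment at 0.35 — a demography
that yields the sparse close-relative structure typical of wild passerine
nest-box studies. Maps default to a macro-to-micro chromosome gradient;
markers are placed uniformly, founders follow Hardy–Weinberg, and gametes
recombine by the Haldane model without interference. Traits are sums of
causal-SNP effects (polygenic: ~10% of SNPs; oligogenic: one or two loci;
null), year, nest and permanent-environment effects, and residual noise;
each realized component is rescaled so its sample variance matches its
requested fraction, so truth-block heritabilities are exact by
construction. Maternal traits generate one record per brood attached to
the mother's genotypic value.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate — includes: pedigree error and extra-pair paternity
(synthetic pedigrees are error-free), selection, immigration, mutation,
genotype-by-environment interaction, dominance and epistasis, sex
chromosomes (all chromosomes segregate autosomally), and ascertainment
structure in marker placement beyond the configurable minor-allele-
frequency range.

## Problem sizes and numerical choices

The test suite runs the analyses at sizes chosen to keep a full run in the
tens of minutes on one core while leaving each check statistically sharp;
they are recorded here as the package's own experimental design:
relatedness oracles on 20 random pedigrees at 200,000 gene drops each and
a 5,000-SNP panel; REML recovery at $n = 800$ with 50 replicates per
heritability level (0.2/0.4/0.6), sharing one pedigree so the eigen fast
path applies; partitioning discrimination at 20 replicates per
architecture on six chromosomes and ~900 markers; scan calibration on the
31-chromosome / 19.16-morgan map with 30 null scans and a five-effect
power run at four replicates per effect on a six-chromosome subgrid;
association calibration on three null traits over ~1,200 SNPs; multi-SNP
coverage on ten replicate datasets at $n = 600$, $p = 300$; and
concordance calibration at 40–400 replicates per test. Key numerical
decisions, besides those above: variance floors at $10^{-8}$ (relatedness
terms) and $10^{-6}$ (residual blocks) times the phenotypic variance;
grid ties at marker positions resolve towards the marker; markers closer
than 1 cM with $r^2 > 0.95$ are pruned before IBD estimation; monomorphic
SNPs are skipped with a message in every marker-wise stage; and all
stochastic stages derive their streams from a single integer seed.

## Known limitations

The IBD sampler conditions on two flanking markers, not the full
multipoint marker set, so between sparse markers its estimates shrink
towards the pedigree expectation faster than a full-likelihood method
would. The blended-GRM weight rule is a design constant, not estimated
from the data, with the consequences for simulated-from-markers traits
described above. The bivariate cross-population model estimates a free
genetic covariance but no population-specific nuisance structure beyond
the residuals. The BVSR sampler proposes additions uniformly, which is
adequate at the panel sizes used here but would mix slowly on
hundred-thousand-SNP panels. Finally, the expected-exceedance threshold
theory is asymptotic in map density and scale; as the calibration
experiment shows, its constants should not be reused on drastically
smaller maps.
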