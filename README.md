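# polyarch

Tools for dissecting the genetic architecture of quantitative traits in
wild, pedigreed populations genotyped on a shared SNP panel — the setting
of long-term nest-box studies of passerines, where the central questions
are whether traits like clutch size, tarsus length or exploratory
behaviour are controlled by many loci of small effect or a few of large
effect, and whether two populations share that architecture.

The package implements, end to end:

* **Animal-model REML** (`fit_reml()`): average-information restricted
  maximum likelihood for mixed models whose random effects carry arbitrary
  relatedness matrices, with boundary-aware likelihood-ratio machinery
  under the 50:50 mixture null, `h² = V_A / ΣV` with delta-method errors,
  and an eigen-rotation fast path for single-matrix models.
* **Relatedness construction** (`build_A()`, `build_G()`,
  `blend_G_with_pedigree()`, `build_crosspop_G()`, `build_qtl_pedigree()`):
  pedigree, genomic, pedigree-blended and cross-population matrices.
* **Chromosome partitioning** (`partition_variance()`): per-chromosome
  genomic variance components with a leave-one-chromosome-out design and
  regressions of variance explained on chromosome size and gene count —
  a positive slope is the polygenic signature.
* **Variance-components QTL linkage mapping** (`estimate_ibd_grid()`,
  `qtl_scan()`, `lod_thresholds()`, `multi_qtl_fit()`,
  `power_simulation()`): expected pairwise IBD on a 5-cM grid from a
  conditional gene-drop particle filter (C++ core), LOD scans with
  genome-wide suggestive/significant thresholds from the dense-map
  expected-exceedance equation, joint multi-QTL fits, and power /
  effect-size-bias (Beavis effect) simulation.
* **Kinship-corrected GWAS** (`compute_EPV()`, `score_test_scan()`,
  `effective_tests()`, `merged_population_scan()`,
  `effect_size_correlation()`): score tests on standardized expected
  phenotypic values with the polygenic covariance fitted once, an
  LD-aware effective-number-of-tests Bonferroni correction, merged
  two-population scans, and permutation tests of between-population
  effect-size correlation.
* **Bayesian variable selection regression** (`run_bvsr()`): posterior
  distributions of the number of SNPs contributing to a trait and the
  proportion of variance they explain, with split-chain convergence
  checks and broom-style `tidy()`/`glance()` accessors.
* **Concordance tests** (`scan_correlation_permutation()`,
  `gwas_qtl_overlap()`, `partition_qtl_fisher()`,
  `shared_chromosome_binomial()`, `nsnp_correlation()`).
* **A two-population synthetic study generator** (`sim_config()`,
  `simulate_pedigree()`, `gene_drop()`, `simulate_traits()`):
  overlapping-generation pedigrees, Haldane recombination, correlated
  founder allele frequencies (F_ST ≈ 0.01 regime), year/nest/permanent-
  environment variance structure, maternal traits, and exact truth blocks.

Everything is tibble-first and pipes cleanly; scans and partitioning
results have `autoplot()` methods.

## Worked example

Simulate a two-population study, estimate heritability both ways, and
compute the genome-wide linkage thresholds for the published great tit
map specification:

```r
library(polyarch)

cfg   <- sim_config(n_founders_per_pop = 60, n_generations = 5,
                    n_snps = 2000, h2 = 0.4, seed = 42)
ped    <- simulate_pedigree(cfg)
panel  <- gene_drop(ped, cfg)
traits <- simulate_traits(ped, panel, cfg)

nl  <- dplyr::filter(ped, pop == "NL")
d   <- dplyr::filter(traits, pop == "NL")
A   <- build_A(nl)
fitA <- fit_reml(d, "value", fixed = ~sex,
                 random = list(animal = vc_term("id", A),
                               id = "iid", year = "iid", nest = "iid"))
glance(fitA)
#> # A tibble: 1 x 7
#>   logLik    h2  h2_se converged n_iter gradient_norm n_obs
#>    <dbl> <dbl>  <dbl> <lgl>      <int>         <dbl> <int>
#> 1  -439. 0.328 0.0695 TRUE           6       0.00912  1256

Gb   <- blend_G_with_pedigree(build_G(panel, ids = nl$id), A)
fitG <- fit_reml(d, "value", fixed = ~sex,
                 random = list(animal = vc_term("id", Gb),
                               id = "iid", year = "iid", nest = "iid"))
round(c(pedigree_h2 = fitA$h2, marker_h2 = fitG$h2), 3)
#> pedigree_h2   marker_h2
#>       0.328       0.352

lod_thresholds(C = 31, G_morgans = 19.16)
#> # A tibble: 3 x 3
#>   threshold     LOD p_nominal
#>   <chr>       <dbl>     <dbl>
#> 1 nominal     0.588 0.0500
#> 2 suggestive  1.62  0.00316
#> 3 significant 3.06  0.0000876
```

The simulated heritability is 0.40; both the pedigree (0.328 ± 0.070) and
the blended-marker (0.352 ± 0.060) animal models recover it within their
uncertainty. The threshold table says: a pointwise LOD of 0.588
corresponds to nominal p = 0.05; LOD 1.620 is expected to be exceeded by
chance about once per genome scan of a 19.16-morgan, 31-chromosome map;
and LOD 3.057 bounds the genome-wide chance exceedance probability at
0.05.

`run_pipeline()` chains the stages (heritability → partitioning → GWAS →
multi-SNP) on simulated or user-supplied data and writes per-stage CSVs;
`read_inputs()` loads pedigree / PLINK-style genotype / phenotype files
with full cross-validation.

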