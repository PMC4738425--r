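Package: polyarch
Title: Quantitative Genetic Architecture Analysis for Wild Pedigreed Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the genetic architecture of quantitative
    traits in wild populations with overlapping-generation pedigrees and
    genome-wide SNP data. Implements pedigree and genomic relatedness
    matrices, an average-information REML animal-model engine with
    likelihood-ratio machinery, chromosome partitioning of additive
    variance, variance-components QTL linkage mapping with genome-wide
    LOD thresholds and power simulation, kinship-corrected genome-wide
    association on expected phenotypic values, Bayesian variable
    selection regression for the number of contributing loci, and
    cross-population concordance tests. Includes a two-population
    synthetic data generator (pedigree simulation, gene dropping with
    recombination, trait simulation) so the whole pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    tidyr,
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
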