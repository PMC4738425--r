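#' Published multi-SNP posterior medians for two great tit populations
#'
#' Per-trait posterior medians of the proportion of variance explained
#' (PVE) and of the number of contributing SNPs (nSNP), as reported by a
#' two-population quantitative-genetic study of wild great tits (a Dutch
#' and a British long-term nest-box population, eight traits, one of which
#' was measured only in the British population). Used as the worked
#' example for [nsnp_correlation()]: the seven traits shared between the
#' populations give a between-population correlation of posterior median
#' SNP numbers of r = 0.80 (one-sided p = 0.016).
#'
#' @return A tibble with columns `trait`, `pve_NL`, `nsnp_NL`, `pve_UK`,
#'   `nsnp_UK` (`NA` where a trait was not measured in a population).
#' @export
nsnp_medians_example <- function() {
  path <- system.file("extdata", "nsnp_medians.csv", package = "polyarch",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
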