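#' Configuration for the two-population synthetic study generator
#'
#' Collects every knob of the synthetic data generator: demography of the
#' two overlapping-generation populations, the linkage map, founder allele
#' frequencies and their between-population correlation, the trait
#' architecture, and the nuisance variance structure. Defaults emulate a
#' pair of long-term wild passerine study populations: weak differentiation
#' (founder allele-frequency correlation 0.98, global F_ST near 0.01),
#' moderately heritable traits with repeated measures, and year, nest and
#' permanent-environment random effects.
#'
#' @param n_founders_per_pop Founders per population (cohort 0).
#' @param n_generations Number of breeding cohorts simulated after founding.
#' @param mean_offspring Mean brood size per pair-year (Poisson).
#' @param survival_to_breed Probability a chick survives to breeding age.
#' @param adult_survival Probability a breeding adult survives to the next
#'   season; this is what produces overlapping generations.
#' @param n_chromosomes Number of autosomes simulated.
#' @param chrom_lengths_cM Genetic map length per chromosome (cM).
#' @param chrom_sizes_Mbp Physical size per chromosome (Mbp).
#' @param chrom_gene_counts Annotated gene count per chromosome.
#' @param n_snps Total markers, allocated to chromosomes proportionally to
#'   map length.
#' @param founder_maf_range Range of the uniform distribution from which
#'   founder minor allele frequencies are drawn.
#' @param between_pop_freq_corr Target correlation of founder allele
#'   frequencies between the two populations (1 = identical frequencies).
#' @param architecture One of `"polygenic"`, `"oligogenic"`, `"null"`.
#' @param n_causal Number of causal SNPs (0 for `"null"`).
#' @param h2 Narrow-sense heritability of the simulated trait.
#' @param shared_fraction Fraction of causal SNPs whose effect sizes are
#'   identical in the two populations; the remainder get independent draws.
#' @param causal_weighting `"snp"` places causal loci uniformly over SNPs;
#'   `"gene"` weights chromosomes by their gene counts first.
#' @param repeat_structure Records per individual: a single integer for a
#'   fixed count, or a probability vector over counts `1..k`.
#' @param nuisance_variances Named fractions of phenotypic variance for
#'   `year`, `nest` and `permanent_environment`; the residual fraction is
#'   `1 - h2 - sum(nuisance_variances)`.
#' @param maternal If `TRUE` the phenotype is a maternal trait: records are
#'   generated for breeding females and carry the mother's genotypic value.
#' @param missing_rate Per-genotype missingness injected uniformly.
#' @param seed Integer seed; all generator output is reproducible from
#'   `(config, seed)`.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_founders_per_pop = 60,
                       n_generations = 5,
                       mean_offspring = 4,
                       survival_to_breed = 0.35,
                       adult_survival = 0.45,
                       n_chromosomes = 10,
                       chrom_lengths_cM = NULL,
                       chrom_sizes_Mbp = NULL,
                       chrom_gene_counts = NULL,
                       n_snps = 2000,
                       founder_maf_range = c(0.05, 0.5),
                       between_pop_freq_corr = 0.98,
                       architecture = c("polygenic", "oligogenic", "null"),
                       n_causal = NULL,
                       h2 = 0.4,
                       shared_fraction = 1,
                       causal_weighting = c("snp", "gene"),
                       repeat_structure = 2,
                       nuisance_variances = c(year = 0.05, nest = 0.05,
                                              permanent_environment = 0.10),
                       maternal = FALSE,
                       missing_rate = 0,
                       seed = 1L) {
  architecture <- match.arg(architecture)
  causal_weighting <- match.arg(causal_weighting)
  if (architecture == "null") {
    n_causal <- 0L
    h2 <- 0
  }
  if (is.null(n_causal)) {
    # default architectures: many loci of small effect, or a handful
    n_causal <- if (architecture == "polygenic") {
      min(200L, max(1L, n_snps %/% 10L))
    } else {
      min(2L, n_snps)
    }
  }
  if (is.null(chrom_lengths_cM)) {
    # macro-to-micro gradient, scaled to n_chromosomes
    base <- seq(110, 40, length.out = n_chromosomes)
    chrom_lengths_cM <- round(base, 1)
  }
  if (is.null(chrom_sizes_Mbp)) chrom_sizes_Mbp <- round(chrom_lengths_cM * 1.0, 1)
  if (is.null(chrom_gene_counts)) chrom_gene_counts <- round(chrom_sizes_Mbp * 15)
  cfg <- list(
    n_founders_per_pop = as.integer(n_founders_per_pop),
    n_generations = as.integer(n_generations),
    mean_offspring = mean_offspring,
    survival_to_breed = survival_to_breed,
    adult_survival = adult_survival,
    n_chromosomes = as.integer(n_chromosomes),
    chrom_lengths_cM = chrom_lengths_cM,
    chrom_sizes_Mbp = chrom_sizes_Mbp,
    chrom_gene_counts = chrom_gene_counts,
    n_snps = as.integer(n_snps),
    founder_maf_range = founder_maf_range,
    between_pop_freq_corr = between_pop_freq_corr,
    architecture = architecture,
    n_causal = as.integer(n_causal),
    h2 = h2,
    shared_fraction = shared_fraction,
    causal_weighting = causal_weighting,
    repeat_structure = repeat_structure,
    nuisance_variances = nuisance_variances,
    maternal = isTRUE(maternal),
    missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_founders_per_pop < 2) abort("n_founders_per_pop must be >= 2")
  if (cfg$n_generations < 1) abort("n_generations must be >= 1")
  if (cfg$h2 < 0 || cfg$h2 > 1) abort("h2 must be in [0, 1]")
  stopifnot_named(cfg$nuisance_variances, "nuisance_variances")
  tot <- cfg$h2 + sum(cfg$nuisance_variances)
  if (tot > 1 + 1e-9) {
    abort(sprintf("h2 (%.3f) + nuisance variance fractions (%.3f) exceed 1",
                  cfg$h2, sum(cfg$nuisance_variances)))
  }
  for (fld in c("chrom_lengths_cM", "chrom_sizes_Mbp", "chrom_gene_counts")) {
    if (length(cfg[[fld]]) != cfg$n_chromosomes) {
      abort(paste0(fld, " must have length n_chromosomes"))
    }
  }
  if (cfg$n_causal > cfg$n_snps) abort("n_causal cannot exceed n_snps")
  if (cfg$between_pop_freq_corr < 0 || cfg$between_pop_freq_corr > 1) {
    abort("between_pop_freq_corr must be in [0, 1]")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) abort("missing_rate must be in [0, 1)")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  populations: 2 x %d founders, %d cohorts\n",
              x$n_founders_per_pop, x$n_generations))
  cat(sprintf("  map: %d chromosomes, %.1f M total, %d SNPs\n",
              x$n_chromosomes, sum(x$chrom_lengths_cM) / 100, x$n_snps))
  cat(sprintf("  trait: %s, h2 = %.2f, %d causal SNPs, shared fraction %.2f\n",
              x$architecture, x$h2, x$n_causal, x$shared_fraction))
  cat(sprintf("  nuisance fractions: %s; residual %.2f\n",
              paste(names(x$nuisance_variances), round(x$nuisance_variances, 2),
                    sep = "=", collapse = ", "),
              1 - x$h2 - sum(x$nuisance_variances)))
  invisible(x)
}
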