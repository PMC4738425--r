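#' Drop founder genomes through a pedigree with recombination
#'
#' Builds the marker panel for a simulated pedigree. Founders receive
#' Hardy–Weinberg haplotypes drawn from population-specific allele
#' frequencies whose between-population correlation is set by
#' `between_pop_freq_corr`. Non-founders inherit one gamete per parent,
#' with crossovers placed by the Haldane model (no interference) along the
#' cM map; chromosomes segregate independently.
#'
#' @param pedigree A pedigree tibble as returned by [simulate_pedigree()].
#' @param config A [sim_config()] object.
#' @param store_inheritance If `TRUE`, per-meiosis inheritance indicators
#'   (which parental haplotype transmitted each marker allele) are retained
#'   in the panel; needed by the QTL power simulation to place a causal
#'   locus that co-segregates with the markers.
#' @return A `genotype_panel`: a list with the dosage matrix
#'   (individuals x SNPs, counts of the "1" allele, `NA` = missing), the
#'   linkage `map` (snp, chr, cM), per-chromosome metadata, the founder
#'   allele frequencies per population, and the population of each
#'   individual.
#' @export
gene_drop <- function(pedigree, config, store_inheritance = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  validate_pedigree(pedigree)
  with_seed(derive_seed(config$seed, "gene_drop"), {
    map <- build_map(config)
    if (any(is.na(map$cM))) abort("marker with undefined map position")
    freqs <- draw_founder_freqs(config, map$snp)
    panel <- drop_genomes(pedigree, map, freqs, config, store_inheritance)
    panel
  })
}

build_map <- function(config) {
  len <- config$chrom_lengths_cM
  n_chr <- config$n_chromosomes
  # allocate SNP counts proportionally to map length (largest remainder)
  raw <- config$n_snps * len / sum(len)
  counts <- floor(raw)
  rem <- config$n_snps - sum(counts)
  if (rem > 0) {
    top <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1L
  }
  chr <- rep(as.character(seq_len(n_chr)), counts)
  pos <- unlist(lapply(seq_len(n_chr), function(c) {
    sort(round(runif(counts[c], 0, len[c]), 3))
  }))
  tibble::tibble(
    snp = sprintf("snp_%05d", seq_along(chr)),
    chr = chr,
    cM = pos
  )
}

draw_founder_freqs <- function(config, snps) {
  n <- length(snps)
  maf <- runif(n, config$founder_maf_range[1], config$founder_maf_range[2])
  flip <- runif(n) < 0.5
  p1 <- ifelse(flip, 1 - maf, maf)
  rho <- config$between_pop_freq_corr
  if (rho >= 1) {
    p2 <- p1
  } else {
    # additive jitter calibrated so cor(p1, p2) hits the target on average
    sdev <- sd(p1) * sqrt(1 / rho^2 - 1)
    p2 <- pmin(pmax(p1 + rnorm(n, 0, sdev), 0.02), 0.98)
  }
  tibble::tibble(snp = snps, NL = p1, UK = p2)
}

drop_genomes <- function(pedigree, map, freqs, config, store_inheritance) {
  n <- nrow(pedigree)
  m <- nrow(map)
  ids <- pedigree$id
  ord <- ped_order(pedigree)
  idx <- seq_len(n)
  names(idx) <- ids
  # switch probability between consecutive SNPs; 0.5 across chromosome breaks
  d <- c(Inf, diff(map$cM))
  d[c(TRUE, map$chr[-1] != map$chr[-m])] <- Inf
  theta <- ifelse(is.infinite(d), 0.5, haldane_theta(d))
  H1 <- matrix(0L, n, m) # paternally inherited haplotype
  H2 <- matrix(0L, n, m) # maternally inherited haplotype
  S1 <- S2 <- if (store_inheritance) matrix(NA_integer_, n, m) else NULL
  pfreq <- cbind(NL = freqs$NL, UK = freqs$UK)
  gamete <- function(parent_row) {
    sw <- runif(m) < theta
    s <- (cumsum(sw) %% 2L) + 1L # 1 or 2: which parental haplotype
    h <- ifelse(s == 1L, H1[parent_row, ], H2[parent_row, ])
    list(h = h, s = s)
  }
  for (i in ord) {
    si <- pedigree$sire[i]
    di <- pedigree$dam[i]
    p <- pfreq[, pedigree$pop[i]]
    if (is.na(si)) {
      H1[i, ] <- as.integer(runif(m) < p)
    } else {
      g <- gamete(idx[[si]])
      H1[i, ] <- g$h
      if (store_inheritance) S1[i, ] <- g$s
    }
    if (is.na(di)) {
      H2[i, ] <- as.integer(runif(m) < p)
    } else {
      g <- gamete(idx[[di]])
      H2[i, ] <- g$h
      if (store_inheritance) S2[i, ] <- g$s
    }
  }
  dosage <- H1 + H2
  if (config$missing_rate > 0) {
    miss <- runif(length(dosage)) < config$missing_rate
    dosage[miss] <- NA_integer_
  }
  dimnames(dosage) <- list(ids, map$snp)
  panel <- list(
    dosage = dosage,
    map = map,
    chrom_info = tibble::tibble(
      chr = as.character(seq_len(config$n_chromosomes)),
      length_cM = config$chrom_lengths_cM,
      size_Mbp = config$chrom_sizes_Mbp,
      gene_count = config$chrom_gene_counts
    ),
    founder_freqs = freqs,
    pop = setNames(pedigree$pop, ids)
  )
  if (store_inheritance) {
    dimnames(S1) <- dimnames(S2) <- list(ids, map$snp)
    panel$inheritance <- list(paternal = S1, maternal = S2)
  }
  class(panel) <- "genotype_panel"
  panel
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d individuals x %d SNPs on %d chromosomes\n",
              nrow(x$dosage), ncol(x$dosage), nrow(x$chrom_info)))
  cat(sprintf("  populations: %s\n",
              paste(names(table(x$pop)), table(x$pop), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Observed allele frequencies of a panel
#'
#' @param panel A `genotype_panel`.
#' @param by_pop If `TRUE`, return one frequency column per population.
#' @return A tibble with one row per SNP.
#' @export
panel_freqs <- function(panel, by_pop = TRUE) {
  if (by_pop) {
    pops <- unique(panel$pop)
    cols <- lapply(pops, function(p) {
      colMeans(panel$dosage[panel$pop == p, , drop = FALSE], na.rm = TRUE) / 2
    })
    names(cols) <- pops
    tibble::tibble(snp = colnames(panel$dosage), !!!cols)
  } else {
    tibble::tibble(snp = colnames(panel$dosage),
                   freq = colMeans(panel$dosage, na.rm = TRUE) / 2)
  }
}

# Restrict a panel to a subset of individuals and/or markers.
subset_panel <- function(panel, ids = NULL, snps = NULL) {
  ids <- ids %||% rownames(panel$dosage)
  snps <- snps %||% colnames(panel$dosage)
  missing_ids <- setdiff(ids, rownames(panel$dosage))
  if (length(missing_ids)) {
    abort(paste0("individual '", missing_ids[1], "' is not in the panel"))
  }
  panel$dosage <- panel$dosage[ids, snps, drop = FALSE]
  panel$map <- panel$map[match(snps, panel$map$snp), ]
  panel$pop <- panel$pop[ids]
  if (!is.null(panel$inheritance)) {
    panel$inheritance$paternal <- panel$inheritance$paternal[ids, snps, drop = FALSE]
    panel$inheritance$maternal <- panel$inheritance$maternal[ids, snps, drop = FALSE]
  }
  panel
}
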