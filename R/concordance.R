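#' Chromosome-block permutation test for scan correlation
#'
#' Tests whether two QTL scans share signal by correlating their
#' per-position test statistics and permuting whole chromosomes of one
#' scan across the chromosome slots of the other (preserving the
#' within-chromosome autocorrelation of linkage statistics, which a
#' per-site permutation would destroy). Within each pairing, positions are
#' matched in map order and the longer block is truncated. One-sided upper
#' p with the plus-one rule.
#'
#' @param scanA,scanB `qtl_scan` tibbles on the same map grid.
#' @param n_perm Number of chromosome-block permutations.
#' @param statistic Column correlated (default `"LOD"`).
#' @param seed Integer seed.
#' @return A `concordance_report` tibble.
#' @export
scan_correlation_permutation <- function(scanA, scanB, n_perm = 1000,
                                         statistic = "LOD", seed = 1) {
  chrs <- unique(scanA$chr)
  if (length(chrs) < 2) abort("chromosome permutation needs at least 2 chromosomes")
  blocksA <- lapply(chrs, function(cc) scanA[[statistic]][scanA$chr == cc])
  blocksB <- lapply(chrs, function(cc) scanB[[statistic]][scanB$chr == cc])
  pair_up <- function(perm) {
    a <- list()
    b <- list()
    for (i in seq_along(chrs)) {
      x <- blocksA[[i]]
      y <- blocksB[[perm[i]]]
      m <- min(length(x), length(y))
      a[[i]] <- x[seq_len(m)]
      b[[i]] <- y[seq_len(m)]
    }
    cor(unlist(a), unlist(b), use = "complete.obs")
  }
  r_obs <- pair_up(seq_along(chrs))
  with_seed(derive_seed(seed, "scancor"), {
    r_perm <- vapply(seq_len(n_perm), function(i) {
      pair_up(sample(seq_along(chrs)))
    }, numeric(1))
  })
  p <- (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
  new_concordance_report("scan_correlation_permutation", r_obs,
                         "chromosome-block permutation", p, n_perm,
                         extra = list(null_correlations = r_perm))
}

#' Interpolate scan LOD scores at SNP map positions
#'
#' Each SNP's LOD is predicted by linear interpolation between the two
#' flanking grid positions of its chromosome (a SNP at 4.6 cM between grid
#' LODs at 0 and 5 cM gets `0.08 L0 + 0.92 L5`); SNPs beyond the grid ends
#' take the nearest endpoint value and are flagged. The per-SNP p-value is
#' the boundary-mixture p of the implied LRT.
#'
#' @param scan A `qtl_scan`.
#' @param panel `genotype_panel` providing SNP map positions.
#' @return Tibble (snp, chr, cM, LOD, p, extrapolated).
#' @export
interpolate_lod_at_snps <- function(scan, panel) {
  out <- panel$map
  out$LOD <- NA_real_
  out$extrapolated <- FALSE
  for (cc in unique(out$chr)) {
    gi <- which(scan$chr == cc & !is.na(scan$LOD))
    si <- which(out$chr == cc)
    if (!length(si)) next
    if (length(gi) < 2) {
      out$LOD[si] <- if (length(gi)) scan$LOD[gi] else NA_real_
      out$extrapolated[si] <- TRUE
      next
    }
    gx <- scan$cM[gi]
    gy <- scan$LOD[gi]
    x <- out$cM[si]
    below <- x < min(gx)
    above <- x > max(gx)
    y <- stats::approx(gx, gy, xout = pmin(pmax(x, min(gx)), max(gx)),
                       ties = "ordered")$y
    out$LOD[si] <- y
    out$extrapolated[si] <- below | above
  }
  out$p <- mixture_pvalue(out$LOD * 2 * log(10))
  out
}

#' Overlap of nominal significance between GWAS and QTL scans
#'
#' Classifies each shared SNP by nominal significance in the GWAS and in
#' the interpolated QTL scan and tests independence of the two flags with
#' a Pearson chi-square test (switching to Fisher's exact test, with a
#' message, when an expected cell is below 5). Degenerate margins (all
#' flags equal in one input) are reported with `p = NA` and a message.
#'
#' @param gwas_p Named (by snp) or plain vector of GWAS p-values.
#' @param qtl_p Vector of interpolated QTL p-values, same SNPs/order.
#' @param alpha Nominal level (default 0.05).
#' @return A `concordance_report` tibble.
#' @export
gwas_qtl_overlap <- function(gwas_p, qtl_p, alpha = 0.05) {
  ok <- !is.na(gwas_p) & !is.na(qtl_p)
  a <- gwas_p[ok] < alpha
  b <- qtl_p[ok] < alpha
  if (length(unique(a)) < 2 || length(unique(b)) < 2) {
    inform("gwas_qtl_overlap: a margin is degenerate; test skipped")
    return(new_concordance_report("gwas_qtl_overlap", NA_real_,
                                  "degenerate margin", NA_real_, NA_integer_))
  }
  tab <- table(gwas = a, qtl = b)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    inform("gwas_qtl_overlap: expected cell < 5, using Fisher's exact test")
    ft <- fisher.test(tab)
    return(new_concordance_report("gwas_qtl_overlap",
                                  sum(a & b), "Fisher exact", ft$p.value,
                                  NA_integer_))
  }
  ct <- chisq.test(tab, correct = FALSE)
  new_concordance_report("gwas_qtl_overlap", unname(ct$statistic),
                         "chi-square independence", ct$p.value, NA_integer_)
}

#' Fisher test of partitioning vs QTL chromosome flags
#'
#' Compares the chromosomes (or chromosome sets) flagged nominally
#' significant by the partitioning analysis with those carrying nominally
#' significant QTL peaks, by a two-tailed Fisher's exact test on the 2x2
#' classification.
#'
#' @param partition_flags Logical vector, one per chromosome set.
#' @param qtl_flags Logical vector over the same sets.
#' @return A `concordance_report` tibble.
#' @export
partition_qtl_fisher <- function(partition_flags, qtl_flags) {
  stopifnot(length(partition_flags) == length(qtl_flags))
  tab <- table(factor(partition_flags, c(FALSE, TRUE)),
               factor(qtl_flags, c(FALSE, TRUE)))
  ft <- fisher.test(tab, alternative = "two.sided")
  new_concordance_report("partition_qtl_fisher",
                         sum(partition_flags & qtl_flags),
                         "Fisher exact (two-tailed)", ft$p.value, NA_integer_)
}

#' Shared significant chromosomes between populations
#'
#' With `nA` of `n_sets` chromosome sets significant in one population and
#' `nB` in the other, tests whether observing `n_shared` or more sets
#' significant in both exceeds chance. The binomial mode (default) takes
#' `X ~ Binomial(n_sets, (nA/n_sets)(nB/n_sets))` and reports
#' `P(X >= n_shared)`; the hypergeometric mode conditions on both margins
#' (random placement of the nB successes among the n_sets slots given nA).
#'
#' @param nA_significant,nB_significant Per-population significant counts.
#' @param n_sets Number of chromosome sets.
#' @param n_shared_observed Observed shared count.
#' @param mode `"binomial"` or `"hypergeometric"`.
#' @return A `concordance_report` tibble.
#' @export
shared_chromosome_binomial <- function(nA_significant, nB_significant, n_sets,
                                       n_shared_observed,
                                       mode = c("binomial", "hypergeometric")) {
  mode <- match.arg(mode)
  stopifnot(nA_significant <= n_sets, nB_significant <= n_sets,
            n_shared_observed <= n_sets)
  if (mode == "binomial") {
    pr <- (nA_significant / n_sets) * (nB_significant / n_sets)
    p <- pbinom(n_shared_observed - 1, n_sets, pr, lower.tail = FALSE)
  } else {
    p <- phyper(n_shared_observed - 1, nA_significant,
                n_sets - nA_significant, nB_significant, lower.tail = FALSE)
  }
  new_concordance_report(paste0("shared_chromosome_", mode),
                         n_shared_observed,
                         sprintf("%s tail P(X >= %d)", mode, n_shared_observed),
                         p, NA_integer_)
}

#' Between-population correlation of posterior median SNP counts
#'
#' Pearson correlation across traits of the two populations' posterior
#' median numbers of contributing SNPs, with a t-test on `n - 2` degrees
#' of freedom; one-sided (positive sharing) by default, with the
#' two-sided value also reported.
#'
#' @param medianA,medianB Paired per-trait posterior medians.
#' @param sided `"one"` or `"two"`.
#' @return A `concordance_report` tibble with `r`, `p`, and `p_two_sided`.
#' @export
nsnp_correlation <- function(medianA, medianB, sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (length(medianA) != length(medianB) || length(medianA) < 3) {
    abort("need at least 3 paired traits")
  }
  if (sd(medianA) < 1e-12 || sd(medianB) < 1e-12) {
    abort("zero variance in a median vector")
  }
  n <- length(medianA)
  r <- cor(medianA, medianB)
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p_one <- pt(tstat, df = n - 2, lower.tail = FALSE)
  p_two <- 2 * pt(-abs(tstat), df = n - 2)
  out <- new_concordance_report("nsnp_correlation", r,
                                sprintf("t-test, %s-sided, df = %d", sided, n - 2),
                                if (sided == "one") p_one else p_two,
                                NA_integer_)
  out$p_two_sided <- p_two
  out
}

new_concordance_report <- function(test, statistic, null_description, p,
                                   n_perm, extra = NULL) {
  out <- tibble::tibble(test = test, statistic = statistic,
                        null = null_description, p = p, n_perm = n_perm)
  if (!is.null(extra)) {
    for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  }
  class(out) <- c("concordance_report", class(out))
  out
}
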