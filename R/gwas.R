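#' Kinship-corrected single-SNP score-test scan
#'
#' Fits the null polygenic model `y ~ N(X b, sigma2_g K + sigma2_e I)`
#' once (REML in the eigenbasis of the kinship matrix), then tests every
#' SNP with the score statistic `T = (g' P y)^2 / (g' P g)` where `g` is
#' the centred (mean-imputed) dosage vector and `P` the REML projection of
#' the fitted null covariance; `p = P(chisq_1 >= T)`, and the per-SNP
#' effect estimate is `g' P y / (g' P g)`. Monomorphic SNPs are skipped.
#'
#' @param epv Tibble (`id`, `epv`) from [compute_EPV()], or any
#'   one-row-per-individual response table.
#' @param panel `genotype_panel`.
#' @param kinship Relatedness matrix covering the ids.
#' @param covariates Optional matrix of extra fixed covariates (rows
#'   matching `epv$id`).
#' @param response Column of `epv` holding the response.
#' @return A `gwas_result` tibble (snp, chr, cM, beta, T, p) with
#'   genomic-control `lambda`, the fitted variance components, and the ids
#'   used stored as attributes.
#' @export
score_test_scan <- function(epv, panel, kinship, covariates = NULL,
                            response = "epv") {
  ids <- intersect(as.character(epv$id), rownames(panel$dosage))
  ids <- intersect(ids, rownames(kinship))
  if (length(ids) < 10) abort("fewer than 10 phenotyped-genotyped individuals")
  y <- epv[[response]][match(ids, epv$id)]
  K <- kinship[ids, ids] + diag(1e-6, length(ids))
  X <- matrix(1, length(ids), 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    X <- cbind(X, covariates[match(ids, rownames(covariates)), , drop = FALSE])
  }
  eig <- eigen(K, symmetric = TRUE)
  attr(K, "eigen") <- eig
  core <- fit_vc_eigen(y, X, K)
  lam <- pmax(eig$values, 0)
  d <- core$theta[1] * lam + core$theta[2]
  U <- eig$vectors
  Xs <- crossprod(U, X)
  Xd <- Xs / d
  XtViXinv <- core$XtViXinv
  Py_rot <- drop(crossprod(U, core$Py)) # rotate P y into the eigenbasis
  G <- panel$dosage[ids, , drop = FALSE]
  p_hat <- colMeans(G, na.rm = TRUE) / 2
  poly <- p_hat > 0 & p_hat < 1 & !is.na(p_hat)
  if (any(!poly)) {
    inform(sprintf("score_test_scan: skipping %d monomorphic SNPs", sum(!poly)))
  }
  G <- G[, poly, drop = FALSE]
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    nas <- which(is.na(G), arr.ind = TRUE)
    G[nas] <- mu[nas[, 2]]
  }
  G <- scale(G, center = TRUE, scale = FALSE)
  Gs <- crossprod(U, G)
  num <- drop(crossprod(Gs, Py_rot))
  Q <- crossprod(Xd, Gs)
  gPg <- colSums(Gs^2 / d) - colSums(Q * (XtViXinv %*% Q))
  gPg[gPg < 1e-12] <- NA
  Tstat <- num^2 / gPg
  out <- tibble::tibble(
    snp = colnames(panel$dosage)[poly],
    chr = panel$map$chr[poly],
    cM = panel$map$cM[poly],
    beta = num / gPg,
    T = Tstat,
    p = pchisq(Tstat, df = 1, lower.tail = FALSE))
  lambda <- median(out$T, na.rm = TRUE) / qchisq(0.5, df = 1)
  attr(out, "lambda") <- lambda
  attr(out, "varcomp") <- setNames(core$theta, c("kinship", "residual"))
  attr(out, "ids") <- ids
  class(out) <- c("gwas_result", class(out))
  out
}

#' Effective number of independent tests from local LD
#'
#' Sliding-window reduction in the style of Moskvina and Schmidt: walking
#' along each chromosome in map order, SNP `j` contributes
#' `sqrt(1 - max r2)` where the maximum squared correlation is taken over
#' its preceding neighbours within the window; the first SNP of each
#' chromosome contributes 1. The result never exceeds the SNP count, and
#' perfectly duplicated SNPs contribute nothing.
#'
#' @param panel `genotype_panel`.
#' @param window Number of preceding SNPs examined (default 50).
#' @return `K_eff` (numeric scalar).
#' @export
effective_tests <- function(panel, window = 50) {
  X <- panel$dosage
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    nas <- which(is.na(X), arr.ind = TRUE)
    X[nas] <- mu[nas[, 2]]
  }
  keff <- 0
  for (cc in unique(panel$map$chr)) {
    snps <- panel$map$snp[panel$map$chr == cc]
    o <- order(panel$map$cM[panel$map$chr == cc])
    snps <- snps[o]
    if (!length(snps)) next
    keff <- keff + 1
    if (length(snps) == 1) next
    Xi <- X[, snps, drop = FALSE]
    sds <- apply(Xi, 2, sd)
    for (j in 2:length(snps)) {
      lo <- max(1, j - window)
      if (sds[j] == 0) next
      prev <- lo:(j - 1)
      prev <- prev[sds[prev] > 0]
      r2max <- if (length(prev)) {
        max(drop(cor(Xi[, j], Xi[, prev, drop = FALSE]))^2)
      } else 0
      keff <- keff + sqrt(max(1 - r2max, 0))
    }
  }
  min(keff, ncol(X))
}

#' Bonferroni threshold from the effective number of tests
#'
#' @param alpha Genome-wide significance level.
#' @param K_eff Effective number of independent tests.
#' @return `alpha / K_eff`.
#' @export
bonferroni_threshold <- function(alpha, K_eff) {
  stopifnot(K_eff >= 1)
  alpha / K_eff
}

#' Merged two-population association scan
#'
#' Merges within-population standardized EPVs and genotypes from the two
#' populations and runs one kinship-corrected scan over the combined data,
#' with the population indicator and the top 10 eigenvectors of the
#' cross-population kinship matrix as fixed covariates (fewer if the
#' matrix does not support 10 non-trivial ones, with a message).
#'
#' @param epv_list List of two EPV tibbles (one per population).
#' @param panel Shared `genotype_panel`.
#' @param kinship Cross-population relatedness matrix.
#' @param n_pcs Number of kinship eigenvectors used as covariates.
#' @return A `gwas_result` tibble over the merged individuals.
#' @export
merged_population_scan <- function(epv_list, panel, kinship, n_pcs = 10) {
  epv <- dplyr::bind_rows(epv_list)
  if (anyDuplicated(epv$id)) abort("an individual appears in both EPV tables")
  ids <- intersect(as.character(epv$id), rownames(kinship))
  ids <- intersect(ids, rownames(panel$dosage))
  K <- kinship[ids, ids]
  eig <- eigen(K, symmetric = TRUE)
  nontrivial <- sum(eig$values > 1e-8)
  use <- min(n_pcs, nontrivial, length(ids) - 3)
  if (use < n_pcs) {
    inform(sprintf("merged scan: only %d non-trivial kinship eigenvectors available", use))
  }
  pop <- panel$pop[ids]
  covs <- cbind(pop = as.numeric(factor(pop)) - 1,
                eig$vectors[, seq_len(use), drop = FALSE])
  colnames(covs) <- c("pop", paste0("kinPC", seq_len(use)))
  rownames(covs) <- ids
  score_test_scan(epv[match(ids, epv$id), ], panel, kinship, covariates = covs)
}

#' Between-population correlation of absolute SNP effect sizes
#'
#' Pearson correlation of `|beta|` across the shared SNPs of two scans;
#' significance from permuting one scan's effects across SNPs, one-sided
#' for positive correlation, with the plus-one rule so the reported p is
#' never zero.
#'
#' @param resultA,resultB `gwas_result` tibbles.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A tibble with `r`, `p`, `n_snps`, `n_perm`.
#' @export
effect_size_correlation <- function(resultA, resultB, n_perm = 10000, seed = 1) {
  shared <- intersect(resultA$snp, resultB$snp)
  if (length(shared) < 3) abort("fewer than 3 shared SNPs")
  a <- abs(resultA$beta[match(shared, resultA$snp)])
  b <- abs(resultB$beta[match(shared, resultB$snp)])
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]
  b <- b[ok]
  r_obs <- cor(a, b)
  with_seed(derive_seed(seed, "effcor"), {
    r_perm <- vapply(seq_len(n_perm), function(i) cor(a, sample(b)), numeric(1))
  })
  tibble::tibble(r = r_obs,
                 p = (1 + sum(r_perm >= r_obs)) / (n_perm + 1),
                 n_snps = length(a), n_perm = n_perm)
}

#' Manhattan-style plot of a GWAS result
#'
#' @param object A `gwas_result`.
#' @param threshold Optional genome-wide p threshold drawn as a line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gwas_result <- function(object, threshold = NULL, ...) {
  df <- tibble::as_tibble(object)
  df$chr <- factor(df$chr, levels = unique(df$chr))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cM, y = -log10(.data$p))) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::facet_grid(. ~ chr, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (cM)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 linetype = "dashed", colour = "red")
  }
  p
}
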