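#' Pedigree (numerator) relationship matrix
#'
#' Computes the additive (numerator) relationship matrix A by the tabular
#' recursion, working over the full pedigree (so all ancestors contribute)
#' and returning the block for the requested individuals.
#'
#' @param pedigree A pedigree tibble (`id`, `sire`, `dam`, ...).
#' @param subset Individuals to return (default: everyone).
#' @return A symmetric matrix with `kind` attribute `"A"`.
#' @export
build_A <- function(pedigree, subset = NULL) {
  validate_pedigree(pedigree)
  subset <- subset %||% pedigree$id
  missing_ids <- setdiff(subset, pedigree$id)
  if (length(missing_ids)) {
    abort(paste0("individual '", missing_ids[1], "' is not in the pedigree"))
  }
  ord <- ped_order(pedigree)
  ped <- pedigree[ord, ]
  n <- nrow(ped)
  pos <- seq_len(n)
  names(pos) <- ped$id
  si <- unname(pos[as.character(ped$sire)])
  di <- unname(pos[as.character(ped$dam)])
  A <- matrix(0, n, n)
  for (i in pos) {
    s <- si[i]
    d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      as_ <- if (!is.na(s)) A[s, j] else 0
      ad_ <- if (!is.na(d)) A[d, j] else 0
      A[i, j] <- A[j, i] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(ped$id, ped$id)
  out <- A[subset, subset, drop = FALSE]
  attr(out, "kind") <- "A"
  out
}

#' Restrict a pedigree to genotyped individuals with close relatives
#'
#' Returns the sub-pedigree of genotyped individuals that are connected to
#' at least one other genotyped individual by a relationship of degree
#' `max_degree` or closer (expected relatedness at least `0.5^max_degree`),
#' plus all of their pedigree ancestors as linking individuals.
#'
#' @param pedigree A pedigree tibble.
#' @param genotyped Character vector of genotyped individual ids.
#' @param max_degree Maximum relationship degree retained (default 4,
#'   i.e. expected relatedness >= 1/16).
#' @return A pedigree tibble (possibly empty), parents before offspring.
#' @export
build_qtl_pedigree <- function(pedigree, genotyped, max_degree = 4) {
  stopifnot(max_degree >= 1)
  genotyped <- intersect(genotyped, pedigree$id)
  if (length(genotyped) < 2) {
    return(pedigree[0, ])
  }
  A <- build_A(pedigree, subset = genotyped)
  thr <- 0.5^max_degree - 1e-9
  off <- A
  diag(off) <- 0
  keep <- genotyped[apply(off >= thr, 1, any)]
  if (length(keep) == 0) {
    return(pedigree[0, ])
  }
  # add all ancestors of kept individuals as linking members
  members <- character(0)
  frontier <- keep
  parent_of <- pedigree[match(frontier, pedigree$id), ]
  while (length(frontier)) {
    members <- union(members, frontier)
    rows <- pedigree[match(frontier, pedigree$id), ]
    frontier <- setdiff(stats::na.omit(c(rows$sire, rows$dam)), members)
  }
  out <- pedigree[pedigree$id %in% members, ]
  out[ped_order(out), ]
}

#' Genomic relatedness matrix from SNP dosages
#'
#' The raw GRM is the centred-dosage cross-product
#' `G_ij = sum_m (x_im - 2 p_m)(x_jm - 2 p_m) / sum_m 2 p_m (1 - p_m)`,
#' with missing dosages handled by pairwise-complete sums (each pair is
#' normalized by the heterozygosity of the markers observed in both).
#' When a pedigree A matrix is supplied via `anchor_A`, the off-diagonal
#' entries are rescaled so that their empirical spread over pedigree-linked
#' pairs matches the spread of the corresponding A entries, and the mean
#' diagonal is anchored to the mean A diagonal — a variance-in-relatedness
#' anchored genomic matrix.
#'
#' @param panel A `genotype_panel`.
#' @param ids Individuals to include (default all).
#' @param snps Marker subset (default all).
#' @param freq_source `"pooled"` (allele frequencies from the included
#'   individuals), a population label (frequencies from that population's
#'   members of the panel), or `"own_pop"` (each individual centred by its
#'   own population's frequencies; used for cross-population matrices).
#' @param anchor_A Optional pedigree relationship matrix over `ids` used to
#'   anchor the scale (see Details).
#' @return A symmetric matrix with attributes `kind`, `n_markers`.
#' @export
build_G <- function(panel, ids = NULL, snps = NULL,
                    freq_source = "pooled", anchor_A = NULL) {
  ids <- ids %||% rownames(panel$dosage)
  snps <- snps %||% colnames(panel$dosage)
  X <- panel$dosage[ids, snps, drop = FALSE]
  pop_of <- panel$pop[ids]

  freq_for <- function(members) {
    colMeans(panel$dosage[members, snps, drop = FALSE], na.rm = TRUE) / 2
  }
  if (identical(freq_source, "own_pop")) {
    pops <- unique(pop_of)
    P <- matrix(0, nrow(X), ncol(X))
    pf <- lapply(pops, function(p) freq_for(names(panel$pop)[panel$pop == p]))
    names(pf) <- pops
    for (p in pops) P[pop_of == p, ] <- matrix(pf[[p]], sum(pop_of == p),
                                               ncol(X), byrow = TRUE)
    # marker weights use the average within-population heterozygosity
    pbar <- Reduce(`+`, pf) / length(pf)
    w <- 2 * pbar * (1 - pbar)
  } else if (identical(freq_source, "pooled")) {
    p <- colMeans(X, na.rm = TRUE) / 2
    P <- matrix(p, nrow(X), ncol(X), byrow = TRUE)
    w <- 2 * p * (1 - p)
  } else {
    p <- freq_for(names(panel$pop)[panel$pop == freq_source])
    P <- matrix(p, nrow(X), ncol(X), byrow = TRUE)
    w <- 2 * p * (1 - p)
  }
  poly <- w > 1e-12 & !is.na(w)
  if (sum(poly) < 2) abort("fewer than 2 polymorphic markers in the subset")
  if (any(!poly)) {
    X <- X[, poly, drop = FALSE]
    P <- P[, poly, drop = FALSE]
    w <- w[poly]
  }
  W <- X - 2 * P
  if (anyNA(W)) {
    O <- !is.na(W)
    W[!O] <- 0
    denom <- (O %*% (w * t(O)))
    denom[denom < 1e-12] <- NA
    G <- (W %*% t(W)) / denom
  } else {
    G <- (W %*% t(W)) / sum(w)
  }
  dimnames(G) <- list(ids, ids)
  if (!is.null(anchor_A)) {
    G <- anchor_to_pedigree(G, anchor_A[ids, ids, drop = FALSE])
  }
  attr(G, "kind") <- if (is.null(anchor_A)) "G_raw" else "G_anchored"
  attr(G, "n_markers") <- sum(poly)
  G
}

anchor_to_pedigree <- function(G, A) {
  off <- upper.tri(G)
  linked <- off & A > 0.05
  cscale <- 1
  if (sum(linked) >= 8 && sd(G[linked]) > 0) {
    cscale <- sd(A[linked]) / sd(G[linked])
  }
  out <- G
  out[off] <- cscale * G[off]
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  dG <- diag(G)
  diag(out) <- mean(diag(A)) + cscale * (dG - mean(dG))
  attr(out, "anchor_scale") <- cscale
  out
}

#' Blend a genomic relatedness matrix towards its pedigree expectation
#'
#' Entrywise `G* = w G + (1 - w) A`. By default the weight follows a
#' marker-count shrinkage rule `w = M / (M + c)` with `c = 1000`, so that
#' sparse panels lean more on the pedigree expectation and dense panels on
#' the markers; this reduces the sampling error of the relatedness values.
#' A small ridge is added to the diagonal so the blended matrix is safely
#' invertible inside REML.
#'
#' @param G Genomic relatedness matrix.
#' @param A Pedigree relationship matrix with identical individual order.
#' @param weight Blending weight in `[0, 1]`; default from the marker-count
#'   rule using `attr(G, "n_markers")`.
#' @param shrink_c Constant of the marker-count rule.
#' @param ridge Value added to the diagonal (default `1e-6`).
#' @return The blended matrix, `kind = "G_blended"`, with the weight in
#'   `attr(, "weight")`.
#' @export
blend_G_with_pedigree <- function(G, A, weight = NULL, shrink_c = 1000,
                                  ridge = 1e-6) {
  if (!identical(rownames(G), rownames(A))) {
    abort("G and A must be over the same individuals in the same order")
  }
  if (is.null(weight)) {
    M <- attr(G, "n_markers") %||% abort("G carries no marker count; give `weight`")
    weight <- M / (M + shrink_c)
  }
  out <- weight * G + (1 - weight) * A
  diag(out) <- diag(out) + ridge
  attr(out, "kind") <- "G_blended"
  attr(out, "weight") <- weight
  attr(out, "n_markers") <- attr(G, "n_markers")
  out
}

#' Cross-population genomic relatedness matrix
#'
#' Builds a single relatedness matrix over the individuals of both
#' populations. Dosages are centred by each individual's own population
#' allele frequencies before the cross-product, which removes mean
#' between-population frequency differences from the between-block entries.
#' Markers entirely missing (or monomorphic) in one population are dropped
#' with a message. Within-population blocks are typically blended with the
#' population pedigree afterwards via [blend_G_with_pedigree()].
#'
#' @param panel A `genotype_panel` containing both populations.
#' @param ids Individuals to include (default all).
#' @param snps Marker subset (default all).
#' @return A symmetric matrix, `kind = "G_crosspop"`.
#' @export
build_crosspop_G <- function(panel, ids = NULL, snps = NULL) {
  ids <- ids %||% rownames(panel$dosage)
  snps <- snps %||% colnames(panel$dosage)
  pops <- unique(panel$pop[ids])
  usable <- rep(TRUE, length(snps))
  for (p in pops) {
    members <- intersect(ids, names(panel$pop)[panel$pop == p])
    f <- colMeans(panel$dosage[members, snps, drop = FALSE], na.rm = TRUE) / 2
    usable <- usable & !is.na(f) & f > 0 & f < 1
  }
  if (any(!usable)) {
    inform(sprintf(
      "build_crosspop_G: excluding %d markers missing or monomorphic in one population",
      sum(!usable)))
    snps <- snps[usable]
  }
  G <- build_G(panel, ids = ids, snps = snps, freq_source = "own_pop")
  attr(G, "kind") <- "G_crosspop"
  G
}

#' Write / read a relatedness matrix as lower-triangle text
#'
#' Plain-text, whitespace-delimited format: a first line with the ordered
#' individual ids, then row `i` of the lower triangle (including the
#' diagonal) per line, at full double precision so matrices round-trip
#' bit-exactly.
#'
#' @param K A symmetric relatedness matrix with dimnames.
#' @param path File path.
#' @return `write_relmat` returns `path` invisibly; `read_relmat` returns
#'   the matrix.
#' @export
write_relmat <- function(K, path) {
  ids <- rownames(K)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ids, collapse = " "), con)
  for (i in seq_along(ids)) {
    writeLines(paste(sprintf("%.17g", K[i, seq_len(i)]), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_relmat
#' @export
read_relmat <- function(path) {
  lines <- readLines(path)
  ids <- strsplit(lines[1], "\\s+")[[1]]
  n <- length(ids)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    row <- as.numeric(strsplit(lines[i + 1], "\\s+")[[1]])
    K[i, seq_len(i)] <- row
    K[seq_len(i), i] <- row
  }
  K
}
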