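#' Expected pairwise IBD matrices on a genome grid
#'
#' For each grid position, estimates the expected identity-by-descent
#' sharing (on the relationship scale, 0–2) between all pedigree members,
#' conditional on the observed genotypes at the flanking markers. The
#' engine is a conditional gene-drop sequential importance sampler: founder
#' haplotype phases are drawn from their observed genotypes (linkage
#' equilibrium between the two flanking markers), and each meiosis samples
#' inheritance indicators at (left marker, grid point, right marker) from
#' the Haldane-transition prior restricted to the child's observed
#' genotypes; the restriction mass accumulates into the sample's importance
#' weight. Far from any informative marker the estimates revert to the
#' pedigree expectation (the A matrix); at a fully informative marker they
#' converge on the realized segregation.
#'
#' @param pedigree Pedigree tibble; individuals with a single known parent
#'   are given an implicit unobserved founder for the unknown side.
#' @param panel `genotype_panel` holding the framework-map marker genotypes
#'   (individuals absent from the panel are treated as ungenotyped).
#' @param grid_step_cM Grid spacing (default 5 cM); position 0 and the last
#'   marker position of each chromosome are always included.
#' @param n_samples Monte-Carlo samples per position.
#' @param max_r2 Before sampling, one member of any marker pair closer than
#'   1 cM with squared correlation above this cap is dropped (high-LD pairs
#'   destabilize the conditioning).
#' @param seed Integer seed.
#' @param chromosomes Optional subset of chromosome labels.
#' @return An `ibd_grid`: list with `positions` (tibble chr, cM),
#'   `matrices` (one relationship-scale matrix per position over the
#'   pedigree ids), `ids`, and `n_samples`.
#' @export
estimate_ibd_grid <- function(pedigree, panel, grid_step_cM = 5,
                              n_samples = 500, max_r2 = 0.95, seed = 1,
                              chromosomes = NULL) {
  validate_pedigree(pedigree)
  ped <- augment_ghost_parents(pedigree)
  ids <- ped$id
  n <- length(ids)
  map <- panel$map
  chromosomes <- chromosomes %||% unique(map$chr)
  map <- dplyr::filter(map, .data$chr %in% chromosomes)
  map <- prune_ld_markers(map, panel, max_r2)
  geno <- matrix(NA_integer_, n, nrow(map), dimnames = list(ids, map$snp))
  shared <- intersect(ids, rownames(panel$dosage))
  geno[shared, ] <- panel$dosage[shared, map$snp]
  # per-population frequencies for unobserved founder alleles
  pops <- unique(panel$pop)
  pf <- lapply(pops, function(p) {
    members <- names(panel$pop)[panel$pop == p]
    colMeans(panel$dosage[members, map$snp, drop = FALSE], na.rm = TRUE) / 2
  })
  names(pf) <- pops
  pop_of <- ped$pop
  pop_of[!pop_of %in% pops] <- pops[1]

  ord <- ped_order(ped)
  pos_idx <- seq_len(n)
  names(pos_idx) <- ids
  sire_i <- unname(pos_idx[as.character(ped$sire)])
  dam_i <- unname(pos_idx[as.character(ped$dam)])

  positions <- dplyr::bind_rows(lapply(unique(map$chr), function(cc) {
    mx <- max(map$cM[map$chr == cc])
    tibble::tibble(chr = cc, cM = sort(unique(c(seq(0, mx, by = grid_step_cM), mx))))
  }))
  mats <- vector("list", nrow(positions))
  with_seed(derive_seed(seed, "ibd_grid"), {
    for (k in seq_len(nrow(positions))) {
      mats[[k]] <- ibd_at_position(
        chr = positions$chr[k], pos = positions$cM[k], map = map,
        geno = geno, pf = pf, pop_of = pop_of, ord = ord,
        sire_i = sire_i, dam_i = dam_i, n_samples = n_samples)
      dimnames(mats[[k]]) <- list(ids, ids)
    }
  })
  keep <- !grepl("^ghost:", ids)
  mats <- lapply(mats, function(m) m[keep, keep, drop = FALSE])
  out <- list(positions = positions, matrices = mats, ids = ids[keep],
              n_samples = n_samples, grid_step_cM = grid_step_cM)
  class(out) <- "ibd_grid"
  out
}

#' @export
print.ibd_grid <- function(x, ...) {
  cat(sprintf("<ibd_grid> %d positions on %d chromosomes, %d individuals, %d samples/position\n",
              nrow(x$positions), length(unique(x$positions$chr)),
              length(x$ids), x$n_samples))
  invisible(x)
}

augment_ghost_parents <- function(pedigree) {
  ped <- pedigree
  one_known <- xor(is.na(ped$sire), is.na(ped$dam))
  if (!any(one_known)) {
    return(ped)
  }
  ghosts <- list()
  for (i in which(one_known)) {
    gid <- paste0("ghost:", ped$id[i])
    ghosts[[gid]] <- tibble::tibble(
      id = gid, sire = NA_character_, dam = NA_character_,
      sex = if (is.na(ped$sire[i])) "M" else "F",
      cohort = ped$cohort[i] - 1L, pop = ped$pop[i])
    if (is.na(ped$sire[i])) ped$sire[i] <- gid else ped$dam[i] <- gid
  }
  dplyr::bind_rows(dplyr::bind_rows(ghosts), ped)
}

prune_ld_markers <- function(map, panel, max_r2) {
  drop <- character(0)
  for (cc in unique(map$chr)) {
    mc <- map[map$chr == cc, ]
    if (nrow(mc) < 2) next
    for (j in 2:nrow(mc)) {
      if (mc$cM[j] - mc$cM[j - 1] < 1) {
        x <- panel$dosage[, mc$snp[j]]
        y <- panel$dosage[, mc$snp[j - 1]]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) > 10 && sd(x[ok]) > 0 && sd(y[ok]) > 0 &&
            cor(x[ok], y[ok])^2 > max_r2) {
          drop <- c(drop, mc$snp[j])
        }
      }
    }
  }
  if (length(drop)) {
    inform(sprintf("IBD estimation: dropped %d markers in high-LD pairs", length(drop)))
    map <- map[!map$snp %in% drop, ]
  }
  map
}

# One grid position: prepares flank data and calls the C++ sequential
# importance sampler; returns the n x n expected relationship-scale IBD.
ibd_at_position <- function(chr, pos, map, geno, pf, pop_of, ord,
                            sire_i, dam_i, n_samples) {
  n <- nrow(geno)
  mc <- which(map$chr == chr)
  cms <- map$cM[mc]
  left <- mc[cms <= pos]
  right <- mc[cms > pos | (cms == pos & length(left) == 0)]
  Lm <- if (length(left)) left[which.max(map$cM[left])] else NA_integer_
  Rm <- if (length(right)) right[which.min(map$cM[right])] else NA_integer_
  if (identical(Lm, Rm) && !is.na(Lm)) Rm <- NA_integer_
  if (!is.na(Lm) && map$cM[Lm] == pos) {
    # at a marker: condition on that marker and its nearest neighbour
    others <- setdiff(mc, Lm)
    if (length(others) && is.na(Rm)) {
      Rm <- others[which.min(abs(map$cM[others] - pos))]
      if (map$cM[Rm] < pos) { tmp <- Lm; Lm <- Rm; Rm <- tmp }
    }
  }
  thL <- if (is.na(Lm)) 0.5 else haldane_theta(pos - map$cM[Lm])
  thR <- if (is.na(Rm)) 0.5 else haldane_theta(map$cM[Rm] - pos)
  freq_at <- function(mk) {
    if (is.na(mk)) {
      return(rep(0.5, n))
    }
    vapply(pop_of, function(p) pf[[p]][mk], numeric(1))
  }
  gvec <- function(mk) {
    if (is.na(mk)) {
      return(rep(-1L, n))
    }
    g <- geno[, mk]
    g[is.na(g)] <- -1L
    as.integer(g)
  }
  out <- ibd_sample_position(
    ord - 1L,
    ifelse(is.na(sire_i), -1L, sire_i - 1L),
    ifelse(is.na(dam_i), -1L, dam_i - 1L),
    gvec(Lm), gvec(Rm), freq_at(Lm), freq_at(Rm),
    thL, thR, as.integer(n_samples))
  if (attr(out, "ess") < 2) {
    warn(sprintf("IBD sampling at %s:%g cM: importance weights degenerate (ESS %.1f)",
                 chr, pos, attr(out, "ess")))
  }
  out
}
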