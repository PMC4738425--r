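# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately written with different algorithms from the
# package internals it checks.

# Monte-Carlo gene-drop relationship oracle: drop one unlinked locus R times
# and average pairwise founder-allele sharing. Returns a matrix on the same
# (relationship, 0-2) scale as build_A.
mc_kinship <- function(ped, R = 200000, seed = 42) {
  withr::local_seed(seed)
  n <- nrow(ped)
  ord <- polyarch:::ped_order(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  o1 <- matrix(0L, n, R)
  o2 <- matrix(0L, n, R)
  lab <- 0L
  for (i in ord) {
    s <- ped$sire[i]
    d <- ped$dam[i]
    if (is.na(s)) {
      o1[i, ] <- lab + 1L
      lab <- lab + 1L
    } else {
      si <- idx[[s]]
      pick <- stats::runif(R) < 0.5
      o1[i, ] <- ifelse(pick, o1[si, ], o2[si, ])
    }
    if (is.na(d)) {
      o2[i, ] <- lab + 1L
      lab <- lab + 1L
    } else {
      di <- idx[[d]]
      pick <- stats::runif(R) < 0.5
      o2[i, ] <- ifelse(pick, o1[di, ], o2[di, ])
    }
  }
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      cnt <- (o1[i, ] == o1[j, ]) + (o1[i, ] == o2[j, ]) +
        (o2[i, ] == o1[j, ]) + (o2[i, ] == o2[j, ])
      K[i, j] <- K[j, i] <- 0.5 * mean(cnt)
    }
  }
  K
}

# Textbook memoized kinship recursion (phi), independent of the tabular
# method in build_A. Returns the relationship matrix 2*phi off-diagonal
# convention matched to build_A (diag 1 + F).
recursive_relationship <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  ord <- polyarch:::ped_order(ped)
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  si <- unname(idx[as.character(ped$sire)])
  di <- unname(idx[as.character(ped$dam)])
  memo <- new.env(hash = TRUE)
  phi <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    key <- paste(min(i, j), max(i, j))
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i == j) {
      0.5 * (1 + phi(ifelse(is.na(si[i]), 0L, si[i]),
                     ifelse(is.na(di[i]), 0L, di[i])))
    } else {
      # recurse on the individual further down the pedigree
      a <- if (rank[i] >= rank[j]) i else j
      b <- if (rank[i] >= rank[j]) j else i
      0.5 * (phi(ifelse(is.na(si[a]), 0L, si[a]), b) +
               phi(ifelse(is.na(di[a]), 0L, di[a]), b))
    }
    memo[[key]] <- val
    val
  }
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) K[i, j] <- K[j, i] <- (if (i == j) 1 else 2) * phi(i, j)
  }
  K
}

# Hudson-style Fst estimator averaged over SNPs.
hudson_fst <- function(panel) {
  fr <- panel_freqs(panel, by_pop = TRUE)
  pops <- setdiff(names(fr), "snp")
  n1 <- sum(panel$pop == pops[1])
  n2 <- sum(panel$pop == pops[2])
  p1 <- fr[[pops[1]]]
  p2 <- fr[[pops[2]]]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (2 * n1 - 1) - p2 * (1 - p2) / (2 * n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- den > 0
  mean(num[ok]) / mean(den[ok])
}

# Small random pedigree generator for relationship-oracle sweeps.
rand_pedigree <- function(n_founders = 4, n_extra = 4, seed = 1) {
  withr::local_seed(seed)
  ids <- paste0("i", seq_len(n_founders + n_extra))
  sire <- dam <- rep(NA_character_, n_founders + n_extra)
  sex <- rep(c("M", "F"), length.out = n_founders + n_extra)
  for (k in (n_founders + 1):(n_founders + n_extra)) {
    males <- which(sex[seq_len(k - 1)] == "M")
    females <- which(sex[seq_len(k - 1)] == "F")
    sire[k] <- ids[sample(males, 1)]
    dam[k] <- ids[sample(females, 1)]
  }
  tibble::tibble(id = ids, sire = sire, dam = dam, sex = sex,
                 cohort = c(rep(0L, n_founders), seq_len(n_extra)),
                 pop = "NL")
}

# Hand-built genotype panel.
make_panel <- function(dosage, map, pop = NULL,
                       chrom_info = NULL) {
  if (is.null(pop)) pop <- setNames(rep("NL", nrow(dosage)), rownames(dosage))
  if (is.null(chrom_info)) chrom_info <- tibble::tibble(
    chr = unique(map$chr),
    length_cM = vapply(unique(map$chr), function(cc) max(map$cM[map$chr == cc]),
                       numeric(1)),
    size_Mbp = 50, gene_count = 500)
  structure(list(dosage = dosage, map = map, chrom_info = chrom_info,
                 pop = pop), class = "genotype_panel")
}

# Exhaustive enumeration oracle for expected IBD in a nuclear family
# conditional on dosages at one biallelic marker, at a position at Haldane
# recombination fraction `theta` from the marker. Parents must be genotyped.
enumerate_nuclear_ibd <- function(d_father, d_mother, d_kids, theta = 0) {
  phase <- function(d) {
    if (d == 1) list(c(0L, 1L), c(1L, 0L)) else list(c(d %/% 2L, d %/% 2L))
  }
  n_kids <- length(d_kids)
  trans <- function(same) ifelse(same, 1 - theta, theta)
  ids <- c("F", "M", paste0("k", seq_len(n_kids)))
  n <- 2 + n_kids
  acc <- matrix(0, n, n, dimnames = list(ids, ids))
  total_w <- 0
  kid_states <- expand.grid(rep(list(1:2), 4 * n_kids)) # sm_p, sg_p, sm_m, sg_m per kid
  for (fp in phase(d_father)) {
    for (mp in phase(d_mother)) {
      for (r in seq_len(nrow(kid_states))) {
        st <- as.integer(kid_states[r, ])
        w <- 1
        orig <- matrix(0L, n, 2)
        orig[1, ] <- c(1L, 2L) # father's two founder alleles
        orig[2, ] <- c(3L, 4L)
        ok <- TRUE
        for (k in seq_len(n_kids)) {
          sm_p <- st[4 * (k - 1) + 1]
          sg_p <- st[4 * (k - 1) + 2]
          sm_m <- st[4 * (k - 1) + 3]
          sg_m <- st[4 * (k - 1) + 4]
          w <- w * 0.25 * trans(sm_p == sg_p) * trans(sm_m == sg_m)
          if (fp[sm_p] + mp[sm_m] != d_kids[k]) {
            ok <- FALSE
            break
          }
          orig[2 + k, ] <- c(orig[1, sg_p], orig[2, sg_m])
        }
        if (!ok || w == 0) next
        total_w <- total_w + w
        for (i in seq_len(n)) {
          for (j in seq_len(n)) {
            cnt <- sum(outer(orig[i, ], orig[j, ], `==`))
            acc[i, j] <- acc[i, j] + 0.5 * w * cnt
          }
        }
      }
    }
  }
  acc / total_w
}

# Compact two-population study fixture.
make_study <- function(..., seed = 1) {
  cfg <- sim_config(..., seed = seed)
  ped <- simulate_pedigree(cfg)
  panel <- gene_drop(ped, cfg, store_inheritance = TRUE)
  traits <- simulate_traits(ped, panel, cfg)
  list(cfg = cfg, ped = ped, panel = panel, traits = traits)
}
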