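#' Variance-components QTL scan
#'
#' At each grid position of an [estimate_ibd_grid()] result, fits a
#' polygenic-plus-QTL animal model (the QTL is a random effect whose
#' covariance is the position's IBD matrix) and compares it with the
#' polygenic-only model by a likelihood-ratio test under the 50:50
#' boundary mixture null. `LOD = LRT / (2 ln 10)`.
#'
#' @param data Phenotype records for one population.
#' @param response Response column.
#' @param ibd An `ibd_grid`.
#' @param A Pedigree relationship matrix for the polygenic term.
#' @param fixed Fixed-effect formula.
#' @param random Extra i.i.d. random terms (named list).
#' @param id_col Individual id column.
#' @param thresholds Optional tibble from [lod_thresholds()] stored with
#'   the scan and drawn by [autoplot.qtl_scan()].
#' @param tol Restricted-likelihood convergence tolerance for the
#'   per-position fits; the default resolves the LRT far beyond the 0.001
#'   LOD display precision.
#' @return A `qtl_scan` tibble: chr, cM, LRT, LOD, p, qtl_var_prop,
#'   converged.
#' @export
qtl_scan <- function(data, response, ibd, A, fixed = NULL, random = list(),
                     id_col = "id", thresholds = NULL, tol = 1e-4) {
  data <- as.data.frame(data)
  keep <- as.character(data[[id_col]]) %in% intersect(rownames(A), ibd$ids)
  data <- data[keep, , drop = FALSE]
  ids <- as.character(data[[id_col]])
  base_random <- c(list(animal = vc_term(id_col, A)), random)
  poly <- fit_reml(data, response, fixed = fixed, random = base_random)
  if (!poly$converged) abort("polygenic model did not converge")
  npos <- nrow(ibd$positions)
  res <- vector("list", npos)
  init0 <- poly$core$theta
  for (k in seq_len(npos)) {
    Kq <- ibd$matrices[[k]]
    rnd <- c(base_random, list(qtl = vc_term(id_col, Kq)))
    init <- c(init0[1], init0[-c(1, length(init0))],
              0.05 * sum(init0), init0[length(init0)])
    fit <- tryCatch(
      suppressWarnings(fit_reml(data, response, fixed = fixed, random = rnd,
                                init = init, tol = tol)),
      error = function(e) NULL)
    if (is.null(fit)) {
      res[[k]] <- tibble::tibble(LRT = NA_real_, LOD = NA_real_, p = NA_real_,
                                 qtl_var_prop = NA_real_, converged = FALSE)
      next
    }
    lrt <- max(-2 * (poly$logLik - fit$logLik), 0)
    vq <- fit$varcomp$variance[fit$varcomp$term == "qtl"]
    res[[k]] <- tibble::tibble(
      LRT = lrt, LOD = lrt / (2 * log(10)), p = mixture_pvalue(lrt),
      qtl_var_prop = vq / sum(fit$varcomp$variance),
      converged = fit$converged)
  }
  out <- dplyr::bind_cols(ibd$positions, dplyr::bind_rows(res))
  out <- dplyr::arrange(out, .data$chr, .data$cM)
  attr(out, "thresholds") <- thresholds
  attr(out, "polygenic_logLik") <- poly$logLik
  class(out) <- c("qtl_scan", class(out))
  out
}

#' Count distinct exceedance events of a LOD level in a scan
#'
#' An event is a run of consecutive positions above the level within one
#' chromosome (a chromosome whose first position is already above the
#' level starts an event). Used to check the expected-exceedance
#' calibration of the genome-wide thresholds.
#'
#' @param scan A `qtl_scan`.
#' @param level LOD level.
#' @return Integer count of exceedance events.
#' @export
count_exceedances <- function(scan, level) {
  ok <- !is.na(scan$LOD)
  total <- 0L
  for (cc in unique(scan$chr)) {
    x <- scan$LOD[scan$chr == cc & ok] > level
    if (!length(x)) next
    total <- total + sum(x & !c(FALSE, head(x, -1)))
  }
  total
}

#' Plot a QTL scan
#'
#' LOD profile along the genome, faceted by chromosome, with the
#' nominal/suggestive/significant guide lines if thresholds were attached.
#'
#' @param object A `qtl_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qtl_scan <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$chr <- factor(df$chr, levels = unique(df$chr))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cM, y = .data$LOD)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(. ~ chr, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (cM)", y = "LOD") +
    ggplot2::theme_minimal()
  th <- attr(object, "thresholds")
  if (!is.null(th)) {
    p <- p + ggplot2::geom_hline(yintercept = th$LOD, linetype = "dashed",
                                 colour = "blue")
  }
  p
}

#' Joint fit of several QTL positions
#'
#' Fits one model with a random term per listed position plus the
#' polygenic term, and reports each QTL's share of the total genetic
#' variance. Positions whose IBD matrices are near-collinear are rejected.
#'
#' @param data Phenotype records.
#' @param response Response column.
#' @param positions Tibble (chr, cM) of positions from a prior scan.
#' @param ibd The `ibd_grid` used for the scan.
#' @param A Polygenic relationship matrix.
#' @param fixed,random,id_col As in [qtl_scan()].
#' @return A tibble: one row per QTL plus one for the polygenic term, with
#'   variance and share of total genetic variance.
#' @export
multi_qtl_fit <- function(data, response, positions, ibd, A, fixed = NULL,
                          random = list(), id_col = "id") {
  ki <- vapply(seq_len(nrow(positions)), function(r) {
    hit <- which(ibd$positions$chr == positions$chr[r] &
                   abs(ibd$positions$cM - positions$cM[r]) < 1e-9)
    if (!length(hit)) abort(sprintf("position %s:%.1f not on the IBD grid",
                                    positions$chr[r], positions$cM[r]))
    hit[1]
  }, integer(1))
  if (anyDuplicated(ki)) {
    abort("the same grid position was entered twice")
  }
  for (a in seq_along(ki)) {
    for (b in seq_len(a - 1)) {
      Ka <- ibd$matrices[[ki[a]]]
      Kb <- ibd$matrices[[ki[b]]]
      if (cor(Ka[upper.tri(Ka)], Kb[upper.tri(Kb)]) > 0.999) {
        abort(sprintf("IBD structures at positions %d and %d are collinear", b, a))
      }
    }
  }
  rnd <- c(list(animal = vc_term(id_col, A)),
           setNames(lapply(ki, function(k) vc_term(id_col, ibd$matrices[[k]])),
                    sprintf("qtl_%s_%g", positions$chr, positions$cM)),
           random)
  fit <- fit_reml(as.data.frame(data), response, fixed = fixed, random = rnd)
  vc <- fit$varcomp
  genetic <- grepl("^qtl_|^animal$", vc$term)
  vg <- sum(vc$variance[genetic])
  out <- vc[genetic, ]
  out$share_of_genetic <- out$variance / vg
  attr(out, "fit") <- fit
  out
}

# Drop one biallelic locus through the stored meioses of a panel, at an
# arbitrary map position, so that it co-segregates with the markers.
drop_locus_at <- function(pedigree, panel, chr, cM, maf = 0.5, seed = 1) {
  if (is.null(panel$inheritance)) {
    abort("panel was built without store_inheritance = TRUE")
  }
  with_seed(derive_seed(seed, paste0("locus", chr, cM)), {
    map <- panel$map
    on_chr <- which(map$chr == chr)
    if (!length(on_chr)) abort(paste0("no markers on chromosome ", chr))
    cms <- map$cM[on_chr]
    Lp <- on_chr[cms <= cM]
    Rp <- on_chr[cms > cM]
    Lm <- if (length(Lp)) Lp[which.max(map$cM[Lp])] else NA_integer_
    Rm <- if (length(Rp)) Rp[which.min(map$cM[Rp])] else NA_integer_
    thL <- if (is.na(Lm)) 0.5 else haldane_theta(cM - map$cM[Lm])
    thR <- if (is.na(Rm)) 0.5 else haldane_theta(map$cM[Rm] - cM)
    ids <- pedigree$id
    n <- length(ids)
    ord <- ped_order(pedigree)
    idx <- seq_len(n)
    names(idx) <- ids
    sample_sg <- function(S, iparent) {
      # S: inheritance matrix (paternal or maternal) over panel markers
      sL <- if (is.na(Lm)) NA else S[iparent, Lm]
      sR <- if (is.na(Rm)) NA else S[iparent, Rm]
      p1 <- 0.5
      if (!is.na(sL)) p1 <- if (sL == 1L) 1 - thL else thL
      p2 <- 1 - p1
      if (!is.na(sR)) {
        w1 <- p1 * (if (sR == 1L) 1 - thR else thR)
        w2 <- p2 * (if (sR == 2L) 1 - thR else thR)
        p1 <- w1 / (w1 + w2)
      }
      if (runif(1) < p1) 1L else 2L
    }
    h1 <- h2 <- integer(n)
    origin1 <- origin2 <- integer(n)
    nf <- 0L
    for (i in ord) {
      si <- pedigree$sire[i]
      di <- pedigree$dam[i]
      if (is.na(si)) {
        h1[i] <- as.integer(runif(1) < maf)
        origin1[i] <- nf + 1L
        nf <- nf + 1L
      } else {
        s <- sample_sg(panel$inheritance$paternal, idx[[si]])
        h1[i] <- if (s == 1L) h1[idx[[si]]] else h2[idx[[si]]]
        origin1[i] <- if (s == 1L) origin1[idx[[si]]] else origin2[idx[[si]]]
      }
      if (is.na(di)) {
        h2[i] <- as.integer(runif(1) < maf)
        origin2[i] <- nf + 1L
        nf <- nf + 1L
      } else {
        s <- sample_sg(panel$inheritance$maternal, idx[[di]])
        h2[i] <- if (s == 1L) h1[idx[[di]]] else h2[idx[[di]]]
        origin2[i] <- if (s == 1L) origin1[idx[[di]]] else origin2[idx[[di]]]
      }
    }
    setNames(h1 + h2, ids)
  })
}

#' QTL-mapping power and effect-size bias simulation
#'
#' Simulates traits with a single QTL of known effect size placed at a
#' random grid position (co-segregating with the marker panel), scans the
#' genome with [qtl_scan()], and tabulates detection rates at the nominal,
#' suggestive and significant thresholds plus the mean estimated variance
#' share among detections (the Beavis effect makes this exceed the
#' simulated share among significant detections).
#'
#' @param pedigree Pedigree of the study individuals.
#' @param panel `genotype_panel` built with `store_inheritance = TRUE`.
#' @param ibd An `ibd_grid` over the scan region.
#' @param A Polygenic relationship matrix.
#' @param effect_sizes QTL variance fractions to simulate (0 = null).
#' @param n_reps Replicates per effect size.
#' @param thresholds Tibble from [lod_thresholds()].
#' @param h2_background Polygenic background heritability.
#' @param seed Integer seed.
#' @return A `power_sim` tibble: one row per effect size with detection
#'   proportions and mean estimated shares among detections at each
#'   threshold; per-replicate results in `attr(, "replicates")`.
#' @export
power_simulation <- function(pedigree, panel, ibd, A,
                             effect_sizes = c(0, 0.05, 0.10, 0.20, 0.40),
                             n_reps = 5, thresholds, h2_background = 0.3,
                             seed = 1) {
  stopifnot(n_reps >= 1)
  ids <- intersect(pedigree$id, ibd$ids)
  Ai <- A[ids, ids]
  chA <- chol(Ai + diag(1e-8, length(ids)))
  lod_at <- setNames(thresholds$LOD, thresholds$threshold)
  rows <- list()
  with_seed(derive_seed(seed, "power"), {
    for (ef in effect_sizes) {
      for (r in seq_len(n_reps)) {
        k <- sample(nrow(ibd$positions), 1)
        qg <- drop_locus_at(pedigree, panel, ibd$positions$chr[k],
                            ibd$positions$cM[k], maf = 0.5,
                            seed = sample.int(2^30, 1))[ids]
        qv <- qg - mean(qg)
        qscale <- if (sd(qv) > 0 && ef > 0) sqrt(ef) / sd(qv) else 0
        bg <- drop(crossprod(chA, rnorm(length(ids))))
        bg <- bg * sqrt(h2_background) / sd(bg)
        e <- rnorm(length(ids))
        e <- e * sqrt(max(1 - ef - h2_background, 0.05)) / sd(e)
        df <- tibble::tibble(id = ids, value = qv * qscale + bg + e)
        sc <- qtl_scan(df, "value", ibd, Ai, thresholds = thresholds)
        peak <- which.max(ifelse(is.na(sc$LOD), -Inf, sc$LOD))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          effect = ef, rep = r,
          true_chr = ibd$positions$chr[k], true_cM = ibd$positions$cM[k],
          peak_LOD = sc$LOD[peak], peak_share = sc$qtl_var_prop[peak],
          hit_nominal = sc$LOD[peak] >= lod_at[["nominal"]],
          hit_suggestive = sc$LOD[peak] >= lod_at[["suggestive"]],
          hit_significant = sc$LOD[peak] >= lod_at[["significant"]])
      }
    }
  })
  reps <- dplyr::bind_rows(rows)
  out <- reps |>
    dplyr::group_by(.data$effect) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      power_nominal = mean(.data$hit_nominal),
      power_suggestive = mean(.data$hit_suggestive),
      power_significant = mean(.data$hit_significant),
      mean_share_suggestive = mean(.data$peak_share[.data$hit_suggestive]),
      mean_share_significant = mean(.data$peak_share[.data$hit_significant]),
      .groups = "drop")
  attr(out, "replicates") <- reps
  class(out) <- c("power_sim", class(out))
  out
}
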