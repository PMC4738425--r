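#' Group chromosomes into partitioning sets
#'
#' Chromosomes with at least `min_snps` markers stand alone; the rest are
#' pooled into a single set (mirroring the treatment of marker-poor
#' microchromosomes). Set sizes are reported with a message.
#'
#' @param panel `genotype_panel`.
#' @param min_snps Minimum marker count for a chromosome to stand alone.
#' @return A named list of marker subsets; each element also carries the
#'   combined `size_Mbp` and `gene_count` of its chromosomes as attributes.
#' @export
define_chromosome_sets <- function(panel, min_snps = 50) {
  counts <- table(panel$map$chr)
  solo <- names(counts)[counts >= min_snps]
  pooled <- setdiff(names(counts), solo)
  sets <- lapply(solo, function(cc) panel$map$snp[panel$map$chr == cc])
  names(sets) <- solo
  if (length(pooled) == 1) {
    solo <- c(solo, pooled)
    sets[[pooled]] <- panel$map$snp[panel$map$chr == pooled]
    pooled <- character(0)
  }
  if (length(pooled)) {
    sets[["pooled_micro"]] <- panel$map$snp[panel$map$chr %in% pooled]
  }
  info <- panel$chrom_info
  for (nm in names(sets)) {
    chrs <- if (nm == "pooled_micro") pooled else nm
    attr(sets[[nm]], "size_Mbp") <- sum(info$size_Mbp[info$chr %in% chrs])
    attr(sets[[nm]], "gene_count") <- sum(info$gene_count[info$chr %in% chrs])
  }
  inform(sprintf("chromosome sets: %s",
                 paste(names(sets), vapply(sets, length, integer(1)),
                       sep = "=", collapse = ", ")))
  sets
}

#' Partition additive variance across chromosome sets
#'
#' For each chromosome set, fits (1) a model with a genomic relatedness
#' matrix built from all markers except the focal set and (2) the same
#' model plus a relatedness matrix built from the focal set only, recording
#' the focal set's proportion of phenotypic variance and the boundary
#' likelihood-ratio test between the two models. Finally regresses the
#' per-set proportions on physical size (Mbp) and on gene count; under a
#' polygenic architecture the proportion of variance scales with
#' chromosome size, so a positive, significant regression indicates
#' polygenicity while an oligogenic trait shows a significant focal set
#' without a size relationship.
#'
#' @param data Phenotype records for one population.
#' @param response Response column.
#' @param panel `genotype_panel`.
#' @param sets Output of [define_chromosome_sets()].
#' @param pedigree Optional pedigree; when given, each GRM is blended with
#'   the pedigree expectation via [blend_G_with_pedigree()].
#' @param fixed,random,id_col As in [fit_reml()].
#' @return A `partition_result` list: `per_set` tibble (set, n_snps,
#'   proportion, SE, LRT, p) and `regression` tibble (predictor, slope,
#'   slope_x1e4, R2, p); sets whose REML fit fails are recorded with `NA`
#'   and excluded from the regressions.
#' @export
partition_variance <- function(data, response, panel, sets, pedigree = NULL,
                               fixed = NULL, random = list(), id_col = "id") {
  data <- as.data.frame(data)
  ids <- unique(as.character(data[[id_col]]))
  ids <- intersect(ids, rownames(panel$dosage))
  data <- data[as.character(data[[id_col]]) %in% ids, , drop = FALSE]
  A <- if (!is.null(pedigree)) build_A(pedigree, subset = ids) else NULL
  grm <- function(snps) {
    G <- build_G(panel, ids = ids, snps = snps)
    if (!is.null(A)) blend_G_with_pedigree(G, A) else G + diag(1e-6, length(ids))
  }
  rows <- list()
  for (nm in names(sets)) {
    focal <- sets[[nm]]
    rest <- setdiff(panel$map$snp, focal)
    fit2 <- tryCatch({
      G_rest <- grm(rest)
      G_focal <- grm(focal)
      base <- suppressWarnings(fit_reml(
        data, response, fixed = fixed,
        random = c(list(genome = vc_term(id_col, G_rest)), random)))
      full <- suppressWarnings(fit_reml(
        data, response, fixed = fixed,
        random = c(list(genome = vc_term(id_col, G_rest),
                        focal = vc_term(id_col, G_focal)), random)))
      list(base = base, full = full)
    }, error = function(e) NULL)
    if (is.null(fit2) || !fit2$full$converged || !fit2$base$converged) {
      inform(sprintf("partition_variance: set %s failed to fit; excluded", nm))
      rows[[nm]] <- tibble::tibble(set = nm, n_snps = length(focal),
                                   size_Mbp = attr(focal, "size_Mbp"),
                                   gene_count = attr(focal, "gene_count"),
                                   proportion = NA_real_, SE = NA_real_,
                                   LRT = NA_real_, p = NA_real_)
      next
    }
    vc <- fit2$full$varcomp
    prop <- vc$variance[vc$term == "focal"] / sum(vc$variance)
    se <- vc$SE[vc$term == "focal"] / sum(vc$variance)
    lrt <- max(-2 * (fit2$base$logLik - fit2$full$logLik), 0)
    rows[[nm]] <- tibble::tibble(set = nm, n_snps = length(focal),
                                 size_Mbp = attr(focal, "size_Mbp"),
                                 gene_count = attr(focal, "gene_count"),
                                 proportion = prop, SE = se, LRT = lrt,
                                 p = mixture_pvalue(lrt))
  }
  per_set <- dplyr::bind_rows(rows)
  reg_for <- function(pred) {
    d <- per_set[!is.na(per_set$proportion), ]
    if (nrow(d) < 3) {
      return(tibble::tibble(predictor = pred, slope = NA_real_,
                            slope_x1e4 = NA_real_, R2 = NA_real_, p = NA_real_))
    }
    m <- lm(d$proportion ~ d[[pred]])
    sm <- summary(m)
    tibble::tibble(predictor = pred, slope = coef(m)[2],
                   slope_x1e4 = coef(m)[2] * 1e4,
                   R2 = sm$r.squared,
                   p = sm$coefficients[2, 4])
  }
  out <- list(per_set = per_set,
              regression = dplyr::bind_rows(reg_for("size_Mbp"),
                                            reg_for("gene_count")))
  class(out) <- "partition_result"
  out
}

#' @export
print.partition_result <- function(x, ...) {
  cat("<partition_result>\n")
  print(as.data.frame(x$per_set), row.names = FALSE, digits = 3)
  cat("regressions of proportion on chromosome size / gene count:\n")
  print(as.data.frame(x$regression), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @rdname tidy.vc_fit
#' @export
tidy.partition_result <- function(x, ...) x$per_set

#' @rdname glance.vc_fit
#' @export
glance.partition_result <- function(x, ...) {
  r <- x$regression
  tibble::tibble(
    slope_size = r$slope[r$predictor == "size_Mbp"],
    p_size = r$p[r$predictor == "size_Mbp"],
    slope_genes = r$slope[r$predictor == "gene_count"],
    p_genes = r$p[r$predictor == "gene_count"],
    total_proportion = sum(x$per_set$proportion, na.rm = TRUE))
}

#' Plot a chromosome-partitioning result
#'
#' Proportion of phenotypic variance per chromosome set against physical
#' size, with the fitted regression line.
#'
#' @param object A `partition_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.partition_result <- function(object, ...) {
  d <- object$per_set[!is.na(object$per_set$proportion), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$size_Mbp, y = .data$proportion)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$proportion - .data$SE,
                                        ymax = .data$proportion + .data$SE),
                           width = 0) +
    ggplot2::labs(x = "chromosome size (Mbp)",
                  y = "proportion of phenotypic variance") +
    ggplot2::theme_minimal()
}
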