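#' Simulate phenotype records on a pedigree and marker panel
#'
#' Phenotypes are the sum of a mean, a sex effect, additive effects of the
#' causal SNPs, year / nest / permanent-environment random effects and a
#' residual. Each realized component is rescaled so its sample variance
#' matches the requested fraction of phenotypic variance, so the realized
#' heritability in the truth block equals `config$h2` up to cross-term
#' noise. For a maternal trait one record is generated per brood and
#' attached to the mother's genotypic value.
#'
#' @param pedigree A pedigree tibble.
#' @param panel A `genotype_panel` from [gene_drop()].
#' @param config A [sim_config()] object.
#' @param trait_name Name recorded in the `trait` column.
#' @return A tibble of records (`id`, `trait`, `value`, `sex`, `pop`,
#'   `cohort`, `year`, `nest`) of class `trait_data`, with a `truth`
#'   attribute (causal SNPs with per-population effects, per-individual
#'   breeding values, simulated h2) retrievable via [sim_truth()].
#' @export
simulate_traits <- function(pedigree, panel, config, trait_name = "trait") {
  stopifnot(inherits(config, "sim_config"))
  nv <- config$nuisance_variances
  v_res <- 1 - config$h2 - sum(nv)
  if (v_res < -1e-9) abort("h2 plus nuisance variance fractions exceed 1")
  if (config$n_causal > ncol(panel$dosage)) abort("n_causal exceeds the number of SNPs")
  with_seed(derive_seed(config$seed, "traits"), {
    ids <- pedigree$id
    pops <- unique(pedigree$pop)

    # --- causal architecture -------------------------------------------
    causal <- character(0)
    if (config$n_causal > 0) {
      if (config$causal_weighting == "gene") {
        w <- panel$chrom_info$gene_count[match(panel$map$chr, panel$chrom_info$chr)]
        causal <- sample(panel$map$snp, config$n_causal, prob = w)
      } else {
        causal <- sample(panel$map$snp, config$n_causal)
      }
    }
    beta <- matrix(0, length(causal), length(pops),
                   dimnames = list(causal, pops))
    if (length(causal)) {
      b1 <- rnorm(length(causal))
      beta[, 1] <- b1
      if (length(pops) > 1) {
        shared <- runif(length(causal)) < config$shared_fraction
        b2 <- ifelse(shared, b1, rnorm(length(causal)))
        beta[, 2] <- b2
      }
    }

    # --- breeding values, scaled to h2 within each population ----------
    bv <- setNames(numeric(length(ids)), ids)
    if (length(causal) && config$h2 > 0) {
      X <- panel$dosage[ids, causal, drop = FALSE]
      # mean-impute missing dosages for the genotypic value
      if (anyNA(X)) {
        mu <- colMeans(X, na.rm = TRUE)
        nas <- which(is.na(X), arr.ind = TRUE)
        X[nas] <- mu[nas[, 2]]
      }
      for (p in pops) {
        in_p <- pedigree$pop == p
        g <- drop(X[in_p, , drop = FALSE] %*% beta[, p])
        g <- g - mean(g)
        s <- sd(g)
        sc <- if (s > 0) sqrt(config$h2) / s else 0
        bv[ids[in_p]] <- g * sc
        beta[, p] <- beta[, p] * sc
      }
    }

    # --- record skeleton ----------------------------------------------
    if (config$maternal) {
      broods <- dplyr::distinct(
        dplyr::filter(pedigree, !is.na(.data$dam)),
        .data$dam, .data$cohort, .data$pop)
      if (nrow(broods) == 0) abort("maternal trait requires at least one brood")
      rec <- tibble::tibble(
        id = broods$dam,
        pop = broods$pop,
        year = broods$cohort,
        nest = paste0(broods$dam, ":", broods$cohort)
      )
    } else {
      nrep <- config$repeat_structure
      n_rec <- if (length(nrep) == 1) {
        rep(as.integer(nrep), length(ids))
      } else {
        sample(seq_along(nrep), length(ids), replace = TRUE, prob = nrep)
      }
      rec <- tibble::tibble(
        id = rep(ids, n_rec),
        pop = rep(pedigree$pop, n_rec),
        year = rep(pedigree$cohort, n_rec) +
          unlist(lapply(n_rec, seq_len)) - 1L,
        nest = rep(ifelse(is.na(pedigree$dam), paste0("fnest:", ids),
                          paste0(pedigree$dam, ":", pedigree$cohort)), n_rec)
      )
    }
    rec$sex <- pedigree$sex[match(rec$id, pedigree$id)]
    rec$cohort <- pedigree$cohort[match(rec$id, pedigree$id)]
    rec$year_f <- paste0(rec$pop, ":", rec$year)

    # --- random components, rescaled per population --------------------
    scale_component <- function(x, target, grp) {
      for (p in pops) {
        i <- grp == p
        s <- sd(x[i])
        x[i] <- if (s > 0) x[i] * sqrt(target) / s else 0
      }
      x
    }
    year_eff <- rnorm(length(unique(rec$year_f)))
    names(year_eff) <- unique(rec$year_f)
    nest_eff <- rnorm(length(unique(rec$nest)))
    names(nest_eff) <- unique(rec$nest)
    pe_eff <- rnorm(length(ids))
    names(pe_eff) <- ids

    comp_g <- bv[rec$id]
    comp_year <- scale_component(unname(year_eff[rec$year_f]), nv[["year"]], rec$pop)
    comp_nest <- scale_component(unname(nest_eff[rec$nest]), nv[["nest"]], rec$pop)
    comp_pe <- scale_component(unname(pe_eff[rec$id]),
                               nv[["permanent_environment"]], rec$pop)
    comp_res <- scale_component(rnorm(nrow(rec)), max(v_res, 0), rec$pop)

    sex_effect <- ifelse(rec$sex == "M", 0.25, 0)
    rec$value <- 10 + sex_effect + comp_g + comp_year + comp_nest +
      comp_pe + comp_res
    rec$trait <- trait_name
    out <- rec[, c("id", "trait", "value", "sex", "pop", "cohort", "year", "nest")]
    truth <- list(
      causal = tibble::tibble(snp = causal,
                              !!!as.data.frame(beta, optional = TRUE)),
      bv = tibble::tibble(id = ids, pop = pedigree$pop, bv = unname(bv[ids])),
      h2 = config$h2,
      variance_fractions = c(h2 = config$h2, nv, residual = max(v_res, 0))
    )
    attr(out, "truth") <- truth
    class(out) <- c("trait_data", class(out))
    out
  })
}

#' Truth block of a simulated trait dataset
#'
#' @param traits A `trait_data` tibble from [simulate_traits()].
#' @return A list with elements `causal` (SNPs and per-population effect
#'   sizes), `bv` (true breeding values), `h2` and `variance_fractions`.
#' @export
sim_truth <- function(traits) {
  attr(traits, "truth")
}
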