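#' Boundary likelihood-ratio test for a variance component
#'
#' For a component constrained to be non-negative, the null distribution of
#' `LRT = -2 (L0 - L1)` is the 50:50 mixture of a point mass at zero and a
#' chi-square with one degree of freedom, so
#' `p = 1` when `LRT <= 0` and `p = 0.5 P(chisq_1 >= LRT)` otherwise
#' (an LRT of 2.706 corresponds to p = 0.05).
#'
#' @param lrt Likelihood-ratio statistic(s).
#' @return p-value(s) under the mixture null.
#' @export
mixture_pvalue <- function(lrt) {
  ifelse(lrt <= 0, 1, 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE))
}

#' Likelihood-ratio test between nested REML fits
#'
#' Compares a full fit against a reduced fit in which one non-negative
#' variance component is dropped (fixed at zero); the p-value uses the
#' 50:50 mixture null of [mixture_pvalue()].
#'
#' @param fit_full,fit_reduced `vc_fit` objects on the same records; the
#'   reduced model's random terms must be a subset of the full model's.
#' @return A tibble with `LRT` and `p`.
#' @export
lrt_variance <- function(fit_full, fit_reduced) {
  if (fit_full$n_obs != fit_reduced$n_obs) {
    abort("models were fitted to different numbers of observations")
  }
  extra <- setdiff(names(fit_full$terms), names(fit_reduced$terms))
  if (length(setdiff(names(fit_reduced$terms), names(fit_full$terms)))) {
    abort("models are not nested: reduced model has terms absent from the full model")
  }
  if (length(extra) != 1) {
    abort("reduced model must drop exactly one random term")
  }
  lrt <- -2 * (fit_reduced$logLik - fit_full$logLik)
  tibble::tibble(LRT = lrt, p = mixture_pvalue(lrt))
}

#' Test equality of additive genetic variances across two populations
#'
#' Fits a bivariate (population-as-trait) animal model on the merged
#' records of both populations, using a cross-population relatedness
#' matrix: the additive structure has a free variance per population and a
#' free between-population genetic covariance. The free model is compared
#' with a model in which the two additive variances are forced to be equal
#' (the covariance stays free); since the equality constraint is interior,
#' the LRT is referred to a full chi-square with one degree of freedom.
#' Residual variances are population-specific; any additional i.i.d.
#' random terms are shared across populations.
#'
#' @param data Records for both populations (must have a `pop` column with
#'   exactly two levels).
#' @param response Response column name.
#' @param K Cross-population relatedness matrix covering all ids in `data`.
#' @param fixed Fixed-effect formula measured in both populations.
#' @param random Extra i.i.d. random terms (named list, as in [fit_reml()]).
#' @param id_col Column linking records to rows of `K`.
#' @return A tibble with the two log-likelihoods, `LRT` and `p`.
#' @export
compare_crosspop_variances <- function(data, response, K, fixed = NULL,
                                       random = list(), id_col = "id") {
  pops <- sort(unique(as.character(data$pop)))
  if (length(pops) != 2) abort("data must contain exactly two populations")
  y <- data[[response]]
  if (is.null(y)) abort(paste0("response column '", response, "' not found; ",
                               "is the trait measured in both populations?"))
  X <- if (is.null(fixed)) {
    matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    model.matrix(fixed, data)
  }
  ids <- as.character(data[[id_col]])
  missing_ids <- setdiff(ids, rownames(K))
  if (length(missing_ids)) {
    abort(paste0("individual '", missing_ids[1], "' absent from K"))
  }
  Kn <- K[ids, ids, drop = FALSE] + diag(1e-6, length(ids))
  in1 <- data$pop == pops[1]
  m1 <- outer(in1, in1)
  m2 <- outer(!in1, !in1)
  C_within1 <- Kn * m1
  C_within2 <- Kn * m2
  C_cross <- Kn * (!m1 & !m2)
  extra <- lapply(normalize_random(random, data), term_structure, data = data)
  resid_masks <- list(as.numeric(in1), as.numeric(!in1))
  free <- fit_vc(y, X, c(list(C_within1, C_within2, C_cross), extra),
                 nonneg = c(TRUE, TRUE, FALSE, rep(TRUE, length(extra))),
                 resid_masks = resid_masks)
  eq <- fit_vc(y, X, c(list(C_within1 + C_within2, C_cross), extra),
               nonneg = c(TRUE, FALSE, rep(TRUE, length(extra))),
               resid_masks = resid_masks)
  lrt <- -2 * (eq$logLik - free$logLik)
  tibble::tibble(
    logLik_free = free$logLik, logLik_equal = eq$logLik,
    VA = list(setNames(free$theta[1:2], pops)),
    LRT = lrt,
    p = pchisq(pmax(lrt, 0), df = 1, lower.tail = FALSE)
  )
}

#' Expected phenotypic values (EPVs)
#'
#' Fits a mixed model with the trait's fixed effects and its non-genetic,
#' non-individual random effects (year, nest, ...) but no additive genetic
#' or permanent-environment term, subtracts the fitted fixed effects and
#' the predicted random effects from each record, averages the adjusted
#' records within individuals, and standardizes the per-individual values
#' to mean 0 and variance 1. The result is the single-value-per-individual
#' response used by the association and multi-SNP analyses.
#'
#' @param data Phenotype records.
#' @param response Response column.
#' @param fixed Fixed-effect formula.
#' @param random Named list of i.i.d. random terms (no relatedness
#'   matrices allowed here).
#' @param id_col Individual id column.
#' @return A tibble (`id`, `epv`), one row per individual with records.
#' @export
compute_EPV <- function(data, response, fixed = NULL, random = list(),
                        id_col = "id") {
  terms <- normalize_random(random, data)
  if (any(!vapply(terms, function(t) is.null(t$K), logical(1)))) {
    abort("compute_EPV models must not contain relatedness-structured terms")
  }
  if (any(vapply(terms, function(t) identical(t$factor, id_col), logical(1)))) {
    abort("compute_EPV models must not contain individual-level random terms")
  }
  y <- data[[response]]
  if (sd(y) < 1e-12) abort("phenotype is constant; EPVs are undefined")
  adj <- if (length(terms) == 0 && is.null(fixed)) {
    y - mean(y)
  } else {
    fit <- fit_reml(data, response, fixed = fixed, random = random)
    X <- if (is.null(fixed)) {
      matrix(1, length(y), 1)
    } else {
      model.matrix(fixed, data)
    }
    res <- y - drop(X %*% fit$beta$estimate)
    for (nm in names(terms)) {
      bl <- ranef_blup(fit, nm)
      f <- as.character(data[[terms[[nm]]$factor]])
      res <- res - bl$blup[match(f, bl$level)]
    }
    res
  }
  out <- tibble::tibble(id = as.character(data[[id_col]]), adj = adj) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(epv = mean(.data$adj), .groups = "drop")
  if (sd(out$epv) < 1e-12) abort("EPVs have zero variance")
  out$epv <- as.numeric(scale(out$epv))
  out
}
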