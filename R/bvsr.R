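#' Configuration for Bayesian variable selection regression
#'
#' Defaults follow the study design for the multi-SNP analysis: three
#' chains of 110,000 Metropolis–Hastings iterations, recording every 10th
#' iteration after a burn-in of 10,000. The inclusion probability `pi` has
#' a log-uniform prior on `(1/p, 1)` and the effect-size scale is tied to
#' a proportion-of-variance-explained hyperparameter `h` with a uniform
#' prior on (0, 1); proposals are 40% add, 40% remove, 20% swap.
#'
#' @param iterations MCMC iterations per chain.
#' @param burn_in Iterations discarded per chain.
#' @param thin Recording interval.
#' @param chains Number of chains.
#' @param seed Base seed (each chain derives its own stream).
#' @param fix_h,fix_pi Optionally pin the hyperparameters (used by the
#'   exact-enumeration checks on toy problems).
#' @param h_prop_sd,logpi_prop_sd Random-walk proposal scales.
#' @param rhat_threshold Chains whose split-half potential-scale-reduction
#'   exceeds this are excluded from the pooled summaries.
#' @return A `bvsr_config` list.
#' @export
bvsr_config <- function(iterations = 110000, burn_in = 10000, thin = 10,
                        chains = 3, seed = 1, fix_h = NULL, fix_pi = NULL,
                        h_prop_sd = 0.05, logpi_prop_sd = 0.5,
                        rhat_threshold = 1.1) {
  stopifnot(burn_in < iterations, thin >= 1, chains >= 1)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 chains = as.integer(chains), seed = as.integer(seed),
                 fix_h = fix_h, fix_pi = fix_pi, h_prop_sd = h_prop_sd,
                 logpi_prop_sd = logpi_prop_sd,
                 rhat_threshold = rhat_threshold),
            class = "bvsr_config")
}

# log marginal likelihood of model gamma given effect-scale c (relative to
# the residual variance), with centred y and X, flat intercept and
# Jeffreys prior on the residual variance:
# log p(y | gamma, c) = -0.5 log|M| - 0.5 k log c - (n-1)/2 log(y'y - b'M^-1 b),
# M = X_g'X_g + I/c, b = X_g'y.
bvsr_logml <- function(gam, XtX, Xty, yty, n, cscale) {
  k <- length(gam)
  if (k == 0) {
    return(-(n - 1) / 2 * log(yty))
  }
  M <- XtX[gam, gam, drop = FALSE] + diag(1 / cscale, k)
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    return(-Inf)
  }
  b <- Xty[gam]
  z <- backsolve(ch, forwardsolve(t(ch), b))
  rss <- yty - sum(b * z)
  if (rss <= 0) {
    return(-Inf)
  }
  -sum(log(diag(ch))) - 0.5 * k * log(cscale) - (n - 1) / 2 * log(rss)
}

bvsr_cscale <- function(h, gam, v) {
  sv <- sum(v[gam])
  if (sv <= 0) {
    return(1)
  }
  h / ((1 - h) * sv)
}

run_bvsr_chain <- function(y, X, XtX, Xty, yty, v, cfg, chain_seed) {
  n <- length(y)
  p <- ncol(X)
  vy <- var(y)
  with_seed(chain_seed, {
    gam <- integer(0)
    h <- cfg$fix_h %||% runif(1, 0.05, 0.6)
    logpi <- if (is.null(cfg$fix_pi)) log(runif(1, 1.5 / p, 0.5)) else log(cfg$fix_pi)
    log_prior_gam <- function(k, logpi) {
      k * logpi + (p - k) * log1p(-exp(logpi))
    }
    cur_ml <- bvsr_logml(gam, XtX, Xty, yty, n, bvsr_cscale(h, gam, v))
    cur_lp <- cur_ml + log_prior_gam(0, logpi)
    n_rec <- (cfg$iterations - cfg$burn_in) %/% cfg$thin
    rec_k <- integer(n_rec)
    rec_pve <- numeric(n_rec)
    rec_model <- if (p <= 30) integer(n_rec) else NULL
    beta_sum <- numeric(p)
    acc <- c(move = 0, h = 0, pi = 0)
    ri <- 0L
    in_model <- logical(p)
    for (it in seq_len(cfg$iterations)) {
      k <- length(gam)
      mv <- runif(1)
      prop <- NULL
      log_q <- 0
      pick1 <- function(v) v[sample.int(length(v), 1)]
      if (mv < 0.4) { # add
        if (k < p) {
          j <- pick1(which(!in_model))
          prop <- c(gam, j)
          log_q <- log(p - k) - log(k + 1) # q(back)/q(fwd)
        }
      } else if (mv < 0.8) { # remove
        if (k > 0) {
          drop_i <- sample.int(k, 1)
          prop <- gam[-drop_i]
          log_q <- log(k) - log(p - k + 1)
        }
      } else { # swap
        if (k > 0 && k < p) {
          drop_i <- sample.int(k, 1)
          j <- pick1(which(!in_model))
          prop <- c(gam[-drop_i], j)
          log_q <- 0
        }
      }
      if (!is.null(prop)) {
        ml <- bvsr_logml(prop, XtX, Xty, yty, n, bvsr_cscale(h, prop, v))
        lp <- ml + log_prior_gam(length(prop), logpi)
        if (log(runif(1)) < lp - cur_lp + log_q) {
          in_model[gam] <- FALSE
          gam <- prop
          in_model[gam] <- TRUE
          cur_ml <- ml
          cur_lp <- lp
          acc["move"] <- acc["move"] + 1
        }
      }
      if (is.null(cfg$fix_h)) {
        hp <- h + rnorm(1, 0, cfg$h_prop_sd)
        if (hp > 1e-4 && hp < 1 - 1e-4) {
          ml <- bvsr_logml(gam, XtX, Xty, yty, n, bvsr_cscale(hp, gam, v))
          if (log(runif(1)) < ml - cur_ml) {
            h <- hp
            cur_ml <- ml
            cur_lp <- ml + log_prior_gam(length(gam), logpi)
            acc["h"] <- acc["h"] + 1
          }
        }
      }
      if (is.null(cfg$fix_pi)) {
        lpp <- logpi + rnorm(1, 0, cfg$logpi_prop_sd)
        if (lpp > log(1 / p) && lpp < 0) {
          # log-uniform prior on pi is flat in log pi
          lp_new <- cur_ml + log_prior_gam(length(gam), lpp)
          if (log(runif(1)) < lp_new - cur_lp) {
            logpi <- lpp
            cur_lp <- lp_new
            acc["pi"] <- acc["pi"] + 1
          }
        }
      }
      if (it > cfg$burn_in && (it - cfg$burn_in) %% cfg$thin == 0) {
        ri <- ri + 1L
        rec_k[ri] <- length(gam)
        if (!is.null(rec_model)) rec_model[ri] <- sum(2L^(gam - 1L))
        rec_pve[ri] <- if (length(gam)) {
          cs <- bvsr_cscale(h, gam, v)
          M <- XtX[gam, gam, drop = FALSE] + diag(1 / cs, length(gam))
          bhat <- solve(M, Xty[gam])
          min(drop(crossprod(bhat, XtX[gam, gam, drop = FALSE] %*% bhat)) /
                ((n - 1) * vy), 1)
        } else 0
        if (length(gam)) {
          beta_sum[gam] <- beta_sum[gam] + bhat
        }
      }
    }
    list(k = rec_k[seq_len(ri)], pve = rec_pve[seq_len(ri)],
         model = if (is.null(rec_model)) NULL else rec_model[seq_len(ri)],
         beta_mean = beta_sum / max(ri, 1), acc = acc / cfg$iterations)
  })
}

split_rhat <- function(x) {
  m <- length(x) %/% 2
  if (m < 4) {
    return(NA_real_)
  }
  halves <- list(x[seq_len(m)], x[m + seq_len(m)])
  W <- mean(vapply(halves, var, numeric(1)))
  B <- m * var(vapply(halves, mean, numeric(1)))
  if (W <= 0) {
    return(1)
  }
  sqrt(((m - 1) / m * W + B / m) / W)
}

#' Bayesian variable selection regression on EPVs
#'
#' Sparse multi-SNP regression estimating the posterior number of SNPs
#' contributing to trait variance (`nSNP = |gamma|`) and the proportion of
#' phenotypic variance they explain (PVE), by Metropolis–Hastings over the
#' model indicator, the inclusion probability and the PVE hyperparameter.
#' PVE per recorded iteration is Rao-Blackwellised through the conditional
#' posterior mean of the included effects. Chains failing the split-half
#' potential-scale-reduction check are excluded from the pooled summaries
#' (with a message), never silently pooled.
#'
#' @param epv Tibble (`id`, response column) one row per individual.
#' @param panel `genotype_panel` (missing dosages are mean-imputed here).
#' @param config A [bvsr_config()].
#' @param response Response column of `epv`.
#' @return A `bvsr_fit`: samples tibble (chain, iter, n_snp, pve),
#'   summaries with medians, means and 95% equal-tail credible intervals,
#'   per-chain diagnostics, and marginal posterior-mean effects.
#' @export
run_bvsr <- function(epv, panel, config = bvsr_config(), response = "epv") {
  ids <- intersect(as.character(epv$id), rownames(panel$dosage))
  y <- epv[[response]][match(ids, epv$id)]
  if (sd(y) < 1e-12) abort("phenotype is constant")
  X <- panel$dosage[ids, , drop = FALSE]
  if (ncol(X) == 0) abort("panel contains no SNPs")
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    nas <- which(is.na(X), arr.ind = TRUE)
    X[nas] <- mu[nas[, 2]]
  }
  v <- apply(X, 2, var)
  keep <- v > 1e-12
  X <- scale(X[, keep, drop = FALSE], center = TRUE, scale = FALSE)
  v <- v[keep]
  y <- y - mean(y)
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  yty <- sum(y^2)
  n <- length(y)
  chains <- lapply(seq_len(config$chains), function(cc) {
    run_bvsr_chain(y, X, XtX, Xty, yty, v, config,
                   derive_seed(config$seed, paste0("bvsr_chain", cc)))
  })
  samples <- dplyr::bind_rows(lapply(seq_along(chains), function(cc) {
    tibble::tibble(chain = cc, iter = seq_along(chains[[cc]]$k),
                   n_snp = chains[[cc]]$k, pve = chains[[cc]]$pve,
                   model = chains[[cc]]$model %||% NA_integer_)
  }))
  diag_tbl <- tibble::tibble(
    chain = seq_along(chains),
    rhat_pve = vapply(chains, function(ch) split_rhat(ch$pve), numeric(1)),
    rhat_nsnp = vapply(chains, function(ch) split_rhat(ch$k), numeric(1)),
    accept_move = vapply(chains, function(ch) ch$acc[["move"]], numeric(1)))
  diag_tbl$converged <- with(diag_tbl, ifelse(
    is.na(rhat_pve) | is.na(rhat_nsnp), TRUE,
    rhat_pve <= config$rhat_threshold & rhat_nsnp <= config$rhat_threshold))
  kept <- diag_tbl$chain[diag_tbl$converged]
  if (length(kept) == 0) {
    warn("no BVSR chain passed the convergence check; pooling all chains anyway")
    kept <- diag_tbl$chain
  } else if (length(kept) < nrow(diag_tbl)) {
    inform(sprintf("run_bvsr: excluding chain(s) %s (split-half Rhat > %.2f)",
                   paste(setdiff(diag_tbl$chain, kept), collapse = ", "),
                   config$rhat_threshold))
  }
  pooled <- dplyr::filter(samples, .data$chain %in% kept)
  qs <- function(x) quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
  qp <- qs(pooled$pve)
  qk <- qs(pooled$n_snp)
  summaries <- tibble::tibble(
    quantity = c("PVE", "nSNP"),
    median = c(qp[2], qk[2]),
    mean = c(mean(pooled$pve), mean(pooled$n_snp)),
    ci_lower = c(qp[1], qk[1]),
    ci_upper = c(qp[3], qk[3]))
  beta_mean <- Reduce(`+`, lapply(chains[kept], `[[`, "beta_mean")) / length(kept)
  names(beta_mean) <- colnames(panel$dosage)[keep]
  out <- list(samples = samples, summaries = summaries, diagnostics = diag_tbl,
              beta_mean = beta_mean, chains_pooled = kept, config = config)
  class(out) <- "bvsr_fit"
  out
}

#' @export
print.bvsr_fit <- function(x, ...) {
  cat(sprintf("<bvsr_fit> %d chains (%d pooled), %d recorded samples\n",
              nrow(x$diagnostics), length(x$chains_pooled), nrow(x$samples)))
  print(as.data.frame(x$summaries), row.names = FALSE)
  invisible(x)
}

#' @rdname tidy.vc_fit
#' @export
tidy.bvsr_fit <- function(x, ...) x$samples

#' @rdname glance.vc_fit
#' @export
glance.bvsr_fit <- function(x, ...) {
  s <- x$summaries
  tibble::tibble(
    pve_median = s$median[s$quantity == "PVE"],
    pve_lower = s$ci_lower[s$quantity == "PVE"],
    pve_upper = s$ci_upper[s$quantity == "PVE"],
    nsnp_median = s$median[s$quantity == "nSNP"],
    nsnp_lower = s$ci_lower[s$quantity == "nSNP"],
    nsnp_upper = s$ci_upper[s$quantity == "nSNP"],
    chains_pooled = length(x$chains_pooled))
}

#' Concordance between multi-SNP and single-SNP effect estimates
#'
#' Rank correlation between the marginal posterior-mean effects of the
#' sparse model and the GWAS score-test effect estimates on the shared
#' SNPs, plus the paired values for plotting.
#'
#' @param bvsr A `bvsr_fit`.
#' @param gwas A `gwas_result`.
#' @return A list: `report` tibble (rho, p, n_snps) and `scatter` tibble.
#' @export
compare_bvsr_to_gwas <- function(bvsr, gwas) {
  shared <- intersect(names(bvsr$beta_mean), gwas$snp)
  a <- bvsr$beta_mean[shared]
  b <- gwas$beta[match(shared, gwas$snp)]
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
  list(report = tibble::tibble(rho = unname(ct$estimate), p = ct$p.value,
                               n_snps = length(shared)),
       scatter = tibble::tibble(snp = shared, bvsr_effect = unname(a),
                                gwas_effect = unname(b)))
}
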