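test_that("REML matches closed forms on balanced and trivial designs", {
  # balanced one-way layout: sigma_e = MSE, sigma_g = (MSB - MSE)/k
  withr::local_seed(3)
  s <- 12
  k <- 5
  g <- rep(paste0("g", seq_len(s)), each = k)
  y <- rep(rnorm(s, 0, 1.2), each = k) + rnorm(s * k, 0, 0.8)
  d <- data.frame(y = y, g = g)
  fit <- fit_reml(d, "y", random = list(g = "iid"))
  ybar <- tapply(y, g, mean)
  msb <- k * var(ybar)
  mse <- sum((y - ybar[g])^2) / (s * (k - 1))
  expect_equal(fit$varcomp$variance[fit$varcomp$term == "residual"], mse,
               tolerance = 1e-6)
  expect_equal(fit$varcomp$variance[fit$varcomp$term == "g"],
               (msb - mse) / k, tolerance = 1e-5)
  # two observations, intercept only: REML residual variance is the
  # sample variance (y1 - y2)^2 / 2
  d2 <- data.frame(y = c(1.3, 2.9))
  fit2 <- fit_reml(d2, "y")
  expect_equal(fit2$varcomp$variance, (1.3 - 2.9)^2 / 2, tolerance = 1e-8)
})

test_that("restricted likelihood is invariant to fixed-effect reparameterization", {
  st <- make_study(n_founders_per_pop = 25, n_generations = 3, n_snps = 200,
                   repeat_structure = 1, seed = 71)
  d <- as.data.frame(st$traits[st$traits$pop == "NL", ])
  d$cov1 <- rnorm(nrow(d))
  d$cov2 <- d$cov1 * 2 + 3 # affine transform of the same covariate
  A <- build_A(st$ped[st$ped$pop == "NL", ])
  f1 <- fit_reml(d, "value", fixed = ~ sex + cov1,
                 random = list(animal = vc_term("id", A)))
  f2 <- fit_reml(d, "value", fixed = ~ cov2 + sex,
                 random = list(animal = vc_term("id", A)))
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
  expect_equal(f1$h2, f2$h2, tolerance = 1e-5)
  expect_lt(f1$gradient_norm, 1e-2)
  # aliased fixed effects are named
  d$dupsex <- d$sex
  expect_error(fit_reml(d, "value", fixed = ~ sex + dupsex,
                        random = list(animal = vc_term("id", A))),
               "aliased")
})

test_that("null genetic variance estimates sit at the boundary", {
  st <- make_study(n_founders_per_pop = 60, n_generations = 3, n_snps = 200,
                   architecture = "null", repeat_structure = 1,
                   nuisance_variances = c(year = 0, nest = 0,
                                          permanent_environment = 0),
                   seed = 72)
  d <- as.data.frame(st$traits[st$traits$pop == "NL", ])
  A <- build_A(st$ped[st$ped$pop == "NL", ])
  fit <- fit_reml(d, "value", random = list(animal = vc_term("id", A)))
  expect_lt(fit$h2, 0.15)
})

test_that("h2 is recovered by pedigree and blended-GRM animal models", {
  st <- make_study(n_founders_per_pop = 60, n_generations = 4, n_snps = 1000,
                   h2 = 0.4, repeat_structure = 1,
                   nuisance_variances = c(year = 0, nest = 0,
                                          permanent_environment = 0),
                   seed = 73)
  nl <- st$ped[st$ped$pop == "NL", ]
  d <- as.data.frame(st$traits[st$traits$pop == "NL", ])
  A <- build_A(nl)
  fitA <- fit_reml(d, "value", fixed = ~sex,
                   random = list(animal = vc_term("id", A)))
  G <- build_G(st$panel, ids = nl$id)
  Gb <- blend_G_with_pedigree(G, A)
  fitG <- fit_reml(d, "value", fixed = ~sex,
                   random = list(animal = vc_term("id", Gb)))
  expect_lt(abs(fitA$h2 - 0.4), 3 * fitA$h2_se)
  expect_lt(abs(fitG$h2 - 0.4), 3 * fitG$h2_se)
  # the two estimators agree within their joint uncertainty
  expect_lt(abs(fitA$h2 - fitG$h2),
            3 * sqrt(fitA$h2_se^2 + fitG$h2_se^2))
  # eigen fast path and dense path agree
  dense <- polyarch:::fit_vc(d$value,
                             matrix(1, nrow(d), 1, dimnames = list(NULL, "i")),
                             list(polyarch:::term_structure(
                               vc_term("id", A), d, ridge = 1e-6)))
  fast <- fit_reml(d, "value", random = list(animal = vc_term("id", A)))
  expect_equal(dense$logLik, fast$logLik, tolerance = 1e-4)
  expect_equal(dense$theta, fast$core$theta, tolerance = 1e-3)
})

test_that("boundary LRT follows the 50:50 mixture null", {
  expect_equal(mixture_pvalue(2.706), 0.05, tolerance = 1e-3)
  expect_identical(mixture_pvalue(0), 1)
  expect_identical(mixture_pvalue(-3), 1)
  expect_equal(mixture_pvalue(7.460), 0.00316, tolerance = 1e-2)
  st <- make_study(n_founders_per_pop = 30, n_generations = 3, n_snps = 200,
                   repeat_structure = 2, seed = 74)
  d <- as.data.frame(st$traits[st$traits$pop == "NL", ])
  A <- build_A(st$ped[st$ped$pop == "NL", ])
  full <- fit_reml(d, "value", random = list(animal = vc_term("id", A),
                                             id = "iid"))
  red <- fit_reml(d, "value", random = list(id = "iid"))
  out <- lrt_variance(full, red)
  expect_equal(out$p, mixture_pvalue(out$LRT))
  expect_error(lrt_variance(red, full), "not nested|drop exactly one")
  expect_error(lrt_variance(full, fit_reml(d, "value")),
               "drop exactly one")
})

test_that("cross-population variance test is null on mirrored data", {
  st <- make_study(n_founders_per_pop = 40, n_generations = 3, n_snps = 600,
                   h2 = 0.4, repeat_structure = 1,
                   nuisance_variances = c(year = 0, nest = 0,
                                          permanent_environment = 0),
                   seed = 75)
  nl <- st$ped[st$ped$pop == "NL", ]
  d <- st$traits[st$traits$pop == "NL", ]
  # mirror one population into a fake second population
  d2 <- d
  d2$id <- paste0("cp_", d2$id)
  d2$pop <- "UK"
  both <- as.data.frame(dplyr::bind_rows(d, d2))
  A <- build_A(nl)
  K <- matrix(0, 2 * nrow(A), 2 * nrow(A),
              dimnames = list(c(rownames(A), paste0("cp_", rownames(A))),
                              c(rownames(A), paste0("cp_", rownames(A)))))
  K[seq_len(nrow(A)), seq_len(nrow(A))] <- A
  K[nrow(A) + seq_len(nrow(A)), nrow(A) + seq_len(nrow(A))] <- A
  res <- compare_crosspop_variances(both, "value", K, fixed = ~sex)
  expect_lt(res$LRT, 1)
  expect_gt(res$p, 0.3)
  # the trait must be measured in both populations
  expect_error(compare_crosspop_variances(as.data.frame(d), "value", K),
               "two populations")
})

test_that("cross-population variance test detects a genuine difference", {
  withr::local_seed(8)
  st <- make_study(n_founders_per_pop = 60, n_generations = 3, n_snps = 400,
                   architecture = "null", repeat_structure = 1,
                   nuisance_variances = c(year = 0, nest = 0,
                                          permanent_environment = 0),
                   seed = 76)
  ped <- st$ped
  A <- build_A(ped)
  # inject genetic signal with a 4:1 variance ratio between populations
  rejections <- 0L
  for (r in 1:3) {
    bv <- drop(crossprod(chol(A + diag(1e-8, nrow(A))), rnorm(nrow(A))))
    names(bv) <- rownames(A)
    va <- ifelse(ped$pop == "NL", 0.64, 0.16)
    d <- tibble::tibble(
      id = ped$id, pop = ped$pop,
      value = sqrt(va) * bv[ped$id] / sd(bv) + rnorm(nrow(ped), 0, sqrt(0.5)))
    res <- compare_crosspop_variances(as.data.frame(d), "value", A)
    if (res$p < 0.05) rejections <- rejections + 1L
    expect_gte(res$LRT, -1e-6)
  }
  expect_gte(rejections, 2L)
})

test_that("EPVs standardize phenotypes adjusted for non-genetic effects", {
  # no terms, one record each: EPV is the z-scored phenotype
  d <- data.frame(id = paste0("i", 1:40), value = rnorm(40, 5, 2))
  epv <- compute_EPV(d, "value")
  expect_equal(epv$epv[match(d$id, epv$id)], as.numeric(scale(d$value)),
               tolerance = 1e-12)
  expect_error(compute_EPV(data.frame(id = c("a", "b"), value = c(1, 1)),
                           "value"), "constant")
  # relatedness-structured and individual-level terms are rejected
  A <- diag(2)
  dimnames(A) <- list(c("a", "b"), c("a", "b"))
  expect_error(compute_EPV(data.frame(id = c("a", "b"), value = c(1, 2)),
                           "value", random = list(animal = vc_term("id", A))),
               "relatedness")
  expect_error(compute_EPV(data.frame(id = c("a", "b"), value = c(1, 2)),
                           "value", random = list(id = "iid")),
               "individual-level")
  # a strong year effect is removed from the EPVs
  withr::local_seed(9)
  n <- 150
  yr <- sample(paste0("y", 1:6), n * 2, replace = TRUE)
  yr_eff <- setNames(rnorm(6, 0, sqrt(0.3)), paste0("y", 1:6))
  ind <- rep(paste0("i", seq_len(n)), 2)
  ind_eff <- setNames(rnorm(n, 0, sqrt(0.4)), paste0("i", seq_len(n)))
  d3 <- data.frame(id = ind, year = yr,
                   value = yr_eff[yr] + ind_eff[ind] +
                     rnorm(2 * n, 0, sqrt(0.3)))
  epv3 <- compute_EPV(d3, "value", random = list(year = "iid"))
  raw <- tapply(d3$value, d3$id, mean)
  raw_year_r2 <- summary(lm(raw ~ 0 + sapply(split(yr, ind), `[`, 1)))$r.squared
  epv_year_r2 <- summary(lm(epv3$epv ~ 0 + sapply(split(yr, ind), `[`, 1)[epv3$id]))$r.squared
  expect_lt(epv_year_r2, raw_year_r2)
  expect_equal(sd(epv3$epv), 1, tolerance = 1e-9)
  expect_equal(mean(epv3$epv), 0, tolerance = 1e-9)
})

test_that("tidy and glance expose the fit in broom style", {
  d <- data.frame(y = rnorm(30), g = rep(letters[1:6], each = 5))
  fit <- fit_reml(d, "y", random = list(g = "iid"))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("term", "variance", "SE"))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(all(c("logLik", "h2", "converged") %in% names(gl)))
})
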