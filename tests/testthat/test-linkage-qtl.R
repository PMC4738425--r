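test_that("genome-wide LOD thresholds are analytically self-consistent", {
  th <- lod_thresholds(C = 31, G_morgans = 19.16, rho = 1)
  lods <- setNames(th$LOD, th$threshold)
  expect_equal(lods[["nominal"]], 0.588)
  # the suggestive and significant levels solve the expected-exceedance
  # equation for mu = 1 and mu = 0.05
  expect_equal(expected_exceedances(lods[["suggestive"]], 31, 19.16), 1,
               tolerance = 0.01)
  expect_equal(expected_exceedances(lods[["significant"]], 31, 19.16), 0.05,
               tolerance = 0.002 / 0.05)
  expect_equal(lods[["suggestive"]], 1.620)
  # nominal pointwise p at each threshold
  expect_equal(th$p_nominal[th$threshold == "nominal"], 0.05, tolerance = 1e-3)
  expect_equal(th$p_nominal[th$threshold == "suggestive"], 0.003,
               tolerance = 0.06)
  # a tiny genome is exceeded less than once per scan even at LOD ~ 0
  tiny <- lod_thresholds(2, 0.001, targets = c(suggestive = 1e9,
                                               significant = 1e8))
  expect_true(all(tiny$LOD[tiny$threshold != "nominal"] == 0))
  expect_error(lod_thresholds(0, 19.16), "C >= 1")
})

nuclear_panel <- function(d_father, d_mother, d_kids, marker_cM = 0,
                          chrom_len = 40) {
  n_kids <- length(d_kids)
  ids <- c("F", "M", paste0("k", seq_len(n_kids)))
  ped <- tibble::tibble(
    id = ids,
    sire = c(NA, NA, rep("F", n_kids)),
    dam = c(NA, NA, rep("M", n_kids)),
    sex = c("M", "F", rep("M", n_kids)),
    cohort = c(0L, 0L, rep(1L, n_kids)), pop = "NL")
  dos <- matrix(c(d_father, d_mother, d_kids), ncol = 1,
                dimnames = list(ids, "m1"))
  panel <- make_panel(dos, tibble::tibble(snp = "m1", chr = "1",
                                          cM = marker_cM))
  list(ped = ped, panel = panel)
}

test_that("IBD sampler matches exhaustive enumeration on nuclear families", {
  cases <- list(
    list(f = 1L, m = 1L, kids = c(0L, 0L)),
    list(f = 1L, m = 1L, kids = c(1L, 1L)),
    list(f = 1L, m = 0L, kids = c(1L, 0L)),
    list(f = 2L, m = 1L, kids = c(2L, 1L)))
  for (cs in cases) {
    fx <- nuclear_panel(cs$f, cs$m, cs$kids)
    g <- suppressWarnings(estimate_ibd_grid(fx$ped, fx$panel,
                                            grid_step_cM = 40,
                                            n_samples = 6000, seed = 5))
    # grid position 0 coincides with the marker
    got <- g$matrices[[which(g$positions$cM == 0)]]
    want <- enumerate_nuclear_ibd(cs$f, cs$m, cs$kids, theta = 0)
    expect_lt(max(abs(got[rownames(want), colnames(want)] - want)), 0.04)
  }
  # at recombination distance from the marker the conditioning is damped;
  # an ungenotyped far marker extends the grid without adding information
  fx <- nuclear_panel(1L, 1L, c(0L, 0L), marker_cM = 0, chrom_len = 100)
  fx$panel$dosage <- cbind(fx$panel$dosage,
                           m2 = rep(NA_integer_, nrow(fx$panel$dosage)))
  fx$panel$map <- tibble::tibble(snp = c("m1", "m2"), chr = "1", cM = c(0, 50))
  g <- suppressWarnings(estimate_ibd_grid(fx$ped, fx$panel, grid_step_cM = 25,
                                          n_samples = 6000, seed = 6))
  want25 <- enumerate_nuclear_ibd(1L, 1L, c(0L, 0L),
                                  theta = polyarch:::haldane_theta(25))
  got25 <- g$matrices[[which(g$positions$cM == 25)]]
  expect_lt(max(abs(got25[rownames(want25), colnames(want25)] - want25)), 0.04)
})

test_that("IBD estimates revert to pedigree expectation without marker information", {
  # founders only: no sharing, matrices are the identity scale
  fped <- tibble::tibble(id = paste0("f", 1:5), sire = NA_character_,
                         dam = NA_character_, sex = "F", cohort = 0L,
                         pop = "NL")
  dos <- matrix(1L, 5, 1, dimnames = list(fped$id, "m1"))
  g0 <- estimate_ibd_grid(fped, make_panel(dos, tibble::tibble(
    snp = "m1", chr = "1", cM = 0)), grid_step_cM = 10, n_samples = 200,
    seed = 2)
  expect_identical(nrow(g0$positions), 1L)
  expect_equal(unname(g0$matrices[[1]]), diag(5), tolerance = 1e-12)
  # deep pedigree, marker 90 cM away: IBD ~ A
  st <- make_study(n_founders_per_pop = 14, n_generations = 4, n_snps = 4,
                   n_chromosomes = 1, chrom_lengths_cM = 90,
                   chrom_sizes_Mbp = 90, chrom_gene_counts = 900,
                   architecture = "null", seed = 81)
  nl <- st$ped[st$ped$pop == "NL", ]
  pan <- st$panel
  keepsnp <- pan$map$snp[which.min(pan$map$cM)]
  pan <- polyarch:::subset_panel(pan, snps = keepsnp)
  pan$map$cM <- 0
  pan$dosage <- cbind(pan$dosage,
                      far = rep(NA_integer_, nrow(pan$dosage)))
  pan$map <- tibble::tibble(snp = c(keepsnp, "far"), chr = "1", cM = c(0, 90))
  g <- estimate_ibd_grid(nl, pan, grid_step_cM = 90, n_samples = 4000,
                         seed = 3)
  A <- build_A(nl)
  far <- g$matrices[[which(g$positions$cM == 90)]]
  expect_lt(mean(abs(far - A[rownames(far), colnames(far)])), 0.03)
})

test_that("QTL scan statistics satisfy their definitional identities", {
  st <- make_study(n_founders_per_pop = 20, n_generations = 4,
                   n_chromosomes = 2, chrom_lengths_cM = c(50, 40),
                   chrom_sizes_Mbp = c(50, 40), chrom_gene_counts = c(500, 400),
                   n_snps = 40, h2 = 0.3, repeat_structure = 1,
                   nuisance_variances = c(year = 0, nest = 0,
                                          permanent_environment = 0),
                   seed = 82)
  nl <- st$ped[st$ped$pop == "NL", ]
  ibd <- suppressMessages(estimate_ibd_grid(nl, st$panel, grid_step_cM = 25,
                                            n_samples = 150, seed = 4))
  A <- build_A(nl)
  d <- st$traits[st$traits$pop == "NL", ]
  th <- lod_thresholds(10, 5)
  sc <- qtl_scan(as.data.frame(d), "value", ibd, A, thresholds = th)
  expect_s3_class(sc, "qtl_scan")
  expect_equal(sc$LOD, sc$LRT / (2 * log(10)))
  expect_equal(sc$p, mixture_pvalue(sc$LRT))
  expect_true(all(diff(order(sc$chr, sc$cM)) == 1))
  expect_true(all(sc$LRT >= 0, na.rm = TRUE))
  # plotting works
  expect_s3_class(autoplot(sc), "ggplot")
  # multi-QTL: duplicated or collinear positions are rejected
  expect_error(multi_qtl_fit(as.data.frame(d), "value",
                             tibble::tibble(chr = c("1", "1"), cM = c(0, 0)),
                             ibd, A), "twice")
  dup_ibd <- ibd
  dup_ibd$matrices[[2]] <- ibd$matrices[[1]]
  expect_error(multi_qtl_fit(as.data.frame(d), "value",
                             tibble::tibble(chr = "1", cM = c(0, 25)),
                             dup_ibd, A), "collinear")
  # exceedance counting: one event per contiguous run
  fake <- sc
  fake$LOD <- rep(0, nrow(sc))
  fake$LOD[sc$chr == "1"] <- c(1, 1, 0)[seq_len(sum(sc$chr == "1"))]
  expect_identical(count_exceedances(fake, 0.5), 1L)
})

test_that("power simulation detects large QTL and shows the Beavis effect", {
  st <- make_study(n_founders_per_pop = 30, n_generations = 4,
                   n_chromosomes = 2, chrom_lengths_cM = c(50, 50),
                   chrom_sizes_Mbp = c(50, 50), chrom_gene_counts = c(500, 500),
                   n_snps = 60, architecture = "null", seed = 83)
  nl <- st$ped[st$ped$pop == "NL", ]
  ibd <- suppressMessages(estimate_ibd_grid(nl, st$panel, grid_step_cM = 12.5,
                                            n_samples = 200, seed = 7))
  A <- build_A(nl)
  th <- lod_thresholds(10, 5)
  ps <- suppressWarnings(power_simulation(
    nl, st$panel, ibd, A, effect_sizes = c(0, 0.4), n_reps = 4,
    thresholds = th, seed = 11))
  expect_s3_class(ps, "power_sim")
  expect_identical(nrow(ps), 2L)
  p0 <- ps$power_suggestive[ps$effect == 0]
  p40 <- ps$power_suggestive[ps$effect == 0.4]
  expect_gte(p40, p0)
  expect_gte(p40, 0.5)
  reps <- attr(ps, "replicates")
  hits <- reps[reps$effect == 0.4 & reps$hit_suggestive, ]
  if (nrow(hits) > 0) {
    expect_gt(mean(hits$peak_share), 0.2)
  }
})
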