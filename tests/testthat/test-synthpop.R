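test_that("config validation catches impossible settings", {
  expect_error(sim_config(h2 = 0.9,
                          nuisance_variances = c(year = 0.1, nest = 0.1,
                                                 permanent_environment = 0.1)),
               "exceed 1")
  expect_error(sim_config(n_founders_per_pop = 1), "n_founders_per_pop")
  expect_error(sim_config(n_causal = 50, n_snps = 10), "n_causal")
  expect_error(sim_config(chrom_lengths_cM = c(1, 2)), "length n_chromosomes")
  cfg0 <- sim_config(architecture = "null")
  expect_identical(cfg0$h2, 0)
  expect_identical(cfg0$n_causal, 0L)
})

test_that("pedigree simulation is deterministic, acyclic and structured", {
  cfg <- sim_config(n_founders_per_pop = 20, n_generations = 3, n_snps = 50,
                    seed = 31)
  ped1 <- simulate_pedigree(cfg)
  ped2 <- simulate_pedigree(cfg)
  expect_identical(ped1, ped2)
  # founders-only when no breeding cohorts produce parents
  cfg1 <- sim_config(n_founders_per_pop = 10, n_generations = 1, n_snps = 50,
                     seed = 5)
  ped_f <- simulate_pedigree(cfg1)
  founders <- ped_f[ped_f$cohort == 0, ]
  expect_true(all(is.na(founders$sire)) && all(is.na(founders$dam)))
  # offspring cohort exceeds both parents' cohorts; no cross-population matings
  kids <- ped1[!is.na(ped1$sire), ]
  by_id <- setNames(ped1$cohort, ped1$id)
  pop_of <- setNames(ped1$pop, ped1$id)
  expect_true(all(kids$cohort > by_id[kids$sire]))
  expect_true(all(kids$cohort > by_id[kids$dam]))
  expect_true(all(pop_of[kids$sire] == kids$pop))
  expect_true(all(pop_of[kids$dam] == kids$pop))
  expect_silent(polyarch:::validate_pedigree(ped1))
  # extinction is reported with actionable parameters
  expect_error(
    simulate_pedigree(sim_config(n_founders_per_pop = 4, n_generations = 6,
                                 mean_offspring = 0.1, survival_to_breed = 0.01,
                                 adult_survival = 0.01, n_snps = 10, seed = 2)),
    "survival")
})

test_that("parent-offspring pair fraction matches a brute-force pair count", {
  cfg <- sim_config(n_founders_per_pop = 15, n_generations = 5,
                    mean_offspring = 4, survival_to_breed = 0.25,
                    n_snps = 10, seed = 77)
  ped <- simulate_pedigree(cfg)
  nl <- ped[ped$pop == "NL", ]
  n <- nrow(nl)
  # brute force over all unordered pairs
  brute <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (identical(nl$sire[j], nl$id[i]) || identical(nl$dam[j], nl$id[i]) ||
          identical(nl$sire[i], nl$id[j]) || identical(nl$dam[i], nl$id[j])) {
        brute <- brute + 1L
      }
    }
  }
  direct <- sum(!is.na(nl$sire)) + sum(!is.na(nl$dam))
  expect_identical(brute, direct)
  expect_gt(brute / choose(n, 2), 0)
})

test_that("gene drop recombines by the Haldane map function", {
  cfg <- sim_config(n_founders_per_pop = 150, n_generations = 4,
                    mean_offspring = 5, survival_to_breed = 0.5,
                    n_chromosomes = 1, chrom_lengths_cM = 60,
                    chrom_sizes_Mbp = 60, chrom_gene_counts = 600,
                    n_snps = 3, seed = 13)
  ped <- simulate_pedigree(cfg)
  map <- tibble::tibble(snp = c("a", "b", "c"), chr = "1", cM = c(0, 0, 50))
  freqs <- tibble::tibble(snp = map$snp, NL = rep(0.5, 3), UK = rep(0.5, 3))
  panel <- withr::with_seed(7, polyarch:::drop_genomes(
    ped, map, freqs, cfg, store_inheritance = TRUE))
  S <- rbind(panel$inheritance$paternal, panel$inheritance$maternal)
  S <- S[stats::complete.cases(S), ]
  expect_gt(nrow(S), 5000)
  # markers 0 cM apart always co-transmitted
  expect_identical(sum(S[, "a"] != S[, "b"]), 0L)
  # 50 cM apart: Haldane recombination fraction (1 - exp(-1))/2
  rf <- mean(S[, "a"] != S[, "c"])
  expect_equal(rf, (1 - exp(-1)) / 2, tolerance = 0.02 / 0.316)
})

test_that("founder allele frequencies respect the between-population correlation", {
  st <- make_study(n_founders_per_pop = 250, n_generations = 1, n_snps = 2500,
                   between_pop_freq_corr = 0.98, architecture = "null",
                   seed = 21)
  founders <- st$ped$id
  fr <- panel_freqs(st$panel)
  r <- cor(fr$NL, fr$UK)
  expect_equal(r, 0.98, tolerance = 0.011 / 0.98)
  expect_lt(abs(hudson_fst(st$panel)), 0.02)
  # identical founder frequency draw: Fst ~ 0 within Monte-Carlo error
  st1 <- make_study(n_founders_per_pop = 250, n_generations = 1, n_snps = 2000,
                    between_pop_freq_corr = 1, architecture = "null", seed = 22)
  expect_lt(abs(hudson_fst(st1$panel)), 0.005)
})

test_that("offspring dosages are Mendelian-consistent", {
  st <- make_study(n_founders_per_pop = 30, n_generations = 3, n_snps = 300,
                   seed = 41)
  ped <- st$ped
  D <- st$panel$dosage
  kids <- which(!is.na(ped$sire))
  for (i in kids) {
    s <- D[ped$sire[i], ]
    d <- D[ped$dam[i], ]
    lo <- (s == 2) + (d == 2)
    hi <- 2 - ((s == 0) + (d == 0))
    expect_true(all(D[i, ] >= lo & D[i, ] <= hi))
  }
})

test_that("trait simulation realizes the requested variance structure", {
  st <- make_study(n_founders_per_pop = 80, n_generations = 4, n_snps = 800,
                   h2 = 0.4, n_causal = 200, repeat_structure = 1,
                   nuisance_variances = c(year = 0, nest = 0,
                                          permanent_environment = 0),
                   seed = 51)
  truth <- sim_truth(st$traits)
  for (p in c("NL", "UK")) {
    bv <- truth$bv$bv[truth$bv$pop == p]
    vp <- var(st$traits$value[st$traits$pop == p])
    expect_equal(var(bv) / vp, 0.40, tolerance = 0.02 / 0.40)
  }
  # null architecture: phenotype does not track breeding values
  st0 <- make_study(n_founders_per_pop = 60, n_generations = 3, n_snps = 300,
                    architecture = "null", repeat_structure = 1, seed = 52)
  tr0 <- sim_truth(st0$traits)
  expect_true(all(tr0$bv$bv == 0))
  # repeated measures: intra-individual correlation ~ h2 + pe (+ nest)
  st3 <- make_study(n_founders_per_pop = 80, n_generations = 3, n_snps = 500,
                    h2 = 0.4, n_causal = 150, repeat_structure = 3,
                    nuisance_variances = c(year = 0.1, nest = 0,
                                           permanent_environment = 0.2),
                    seed = 53)
  d <- st3$traits[st3$traits$pop == "UK", ]
  wide <- tidyr::pivot_wider(
    dplyr::mutate(dplyr::group_by(d, id), rec = dplyr::row_number()),
    id_cols = "id", names_from = "rec", values_from = "value")
  icc <- cor(wide$`1`, wide$`2`)
  expect_equal(icc, 0.6, tolerance = 0.1 / 0.6)
  # maternal traits attach records to breeding females only
  stm <- make_study(n_founders_per_pop = 40, n_generations = 3, n_snps = 200,
                    maternal = TRUE, seed = 54)
  dams <- unique(stm$ped$dam[!is.na(stm$ped$dam)])
  expect_true(all(stm$traits$id %in% dams))
  expect_error(
    simulate_traits(st3$ped, st3$panel,
                    local({
                      cfg <- st3$cfg
                      cfg$h2 <- 0.95
                      cfg
                    })),
    "exceed 1")
})
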