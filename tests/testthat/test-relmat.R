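founder_ped <- function(n) {
  tibble::tibble(id = paste0("f", seq_len(n)), sire = NA_character_,
                 dam = NA_character_, sex = rep(c("M", "F"), length.out = n),
                 cohort = 0L, pop = "NL")
}

test_that("A matrix reproduces textbook relationship coefficients", {
  ped <- tibble::tibble(
    id = c("gm", "gf", "m", "f", "u", "x", "c1", "c2", "h1"),
    sire = c(NA, NA, "gf", NA, "gf", NA, "f", "f", "x"),
    dam = c(NA, NA, "gm", NA, "gm", NA, "m", "m", "m"),
    sex = c("F", "M", "F", "M", "M", "M", "M", "F", "M"),
    cohort = c(0L, 0L, 1L, 0L, 1L, 0L, 2L, 2L, 2L), pop = "NL")
  A <- build_A(ped)
  expect_equal(A["gm", "gf"], 0)
  expect_equal(diag(A)[c("gm", "gf", "m", "f")], c(gm = 1, gf = 1, m = 1, f = 1))
  expect_equal(A["m", "gm"], 0.5)   # parent-offspring
  expect_equal(A["c1", "f"], 0.5)
  expect_equal(A["c1", "c2"], 0.5)  # full sibs
  expect_equal(A["c1", "h1"], 0.25) # half sibs (shared mother)
  expect_equal(A["m", "u"], 0.5)    # full sibs in the parental generation
  # restriction computes over ancestors
  sub <- build_A(ped, subset = c("c1", "c2", "h1"))
  expect_equal(sub, A[c("c1", "c2", "h1"), c("c1", "c2", "h1")],
               ignore_attr = TRUE)
  expect_error(build_A(ped, subset = "nobody"), "nobody")
})

test_that("A matrix agrees with the gene-drop Monte-Carlo oracle and is PSD", {
  for (s in 1:3) {
    ped <- rand_pedigree(n_founders = 4, n_extra = 5, seed = s)
    A <- build_A(ped)
    K <- mc_kinship(ped, R = 200000, seed = 100 + s)
    expect_lt(max(abs(A - K)), 0.005)
    expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("QTL pedigree keeps genotyped individuals with close relatives", {
  # mutually unrelated founders -> empty
  expect_identical(nrow(build_qtl_pedigree(founder_ped(6),
                                           paste0("f", 1:6))), 0L)
  # one full-sib family at max_degree 1 -> that family only
  fam <- tibble::tibble(id = c("p1", "p2", "k1", "k2", "lone"),
                        sire = c(NA, NA, "p1", "p1", NA),
                        dam = c(NA, NA, "p2", "p2", NA),
                        sex = c("M", "F", "M", "F", "M"),
                        cohort = c(0L, 0L, 1L, 1L, 0L), pop = "NL")
  qp <- build_qtl_pedigree(fam, c("k1", "k2", "lone"), max_degree = 1)
  expect_setequal(qp$id, c("p1", "p2", "k1", "k2"))
  # simulated pedigree: genotyped membership matches the independent
  # recursive-kinship enumeration of degree <= 4 links
  st <- make_study(n_founders_per_pop = 12, n_generations = 3, n_snps = 20,
                   seed = 9)
  nl <- st$ped[st$ped$pop == "NL", ]
  genotyped <- sample(nl$id, ceiling(nrow(nl) * 0.7))
  qp <- build_qtl_pedigree(nl, genotyped, max_degree = 4)
  K <- recursive_relationship(nl)[genotyped, genotyped]
  diag(K) <- 0
  expected <- rownames(K)[apply(K >= 0.5^4 - 1e-9, 1, any)]
  expect_setequal(intersect(qp$id, genotyped), expected)
  # every member of the returned pedigree has its parents included
  expect_true(all(stats::na.omit(c(qp$sire, qp$dam)) %in% qp$id))
})

test_that("genomic relatedness has the centred cross-product structure", {
  st <- make_study(n_founders_per_pop = 120, n_generations = 1, n_snps = 3000,
                   architecture = "null", seed = 61)
  founders <- st$ped$id[st$ped$pop == "NL"]
  G <- build_G(st$panel, ids = founders)
  off <- G[upper.tri(G)]
  expect_lt(abs(mean(off)), 0.01)
  expect_equal(mean(diag(G)), 1, tolerance = 0.05)
  # duplicated genotypes look like identical twins
  dup <- st$panel
  dup$dosage <- rbind(dup$dosage, twin = dup$dosage[founders[1], ])
  dup$pop <- c(dup$pop, twin = "NL")
  Gd <- build_G(dup, ids = c(founders, "twin"))
  expect_equal(Gd["twin", founders[1]], Gd[founders[1], founders[1]],
               tolerance = 1e-10)
  expect_error(build_G(make_panel(
    matrix(2L, 5, 3, dimnames = list(paste0("i", 1:5), paste0("s", 1:3))),
    tibble::tibble(snp = paste0("s", 1:3), chr = "1", cM = 1:3))),
    "polymorphic")
})

test_that("GRM off-diagonals regress on pedigree relatedness with slope 1", {
  st <- make_study(n_founders_per_pop = 40, n_generations = 3, n_snps = 3000,
                   architecture = "null", seed = 62)
  nl <- st$ped[st$ped$pop == "NL", ]
  A <- build_A(nl)
  G <- build_G(st$panel, ids = nl$id)
  ut <- upper.tri(A)
  slope <- coef(lm(G[ut] ~ A[ut]))[2]
  expect_equal(unname(slope), 1, tolerance = 0.1)
})

test_that("blending follows G* = wG + (1-w)A and the marker-count rule", {
  st <- make_study(n_founders_per_pop = 20, n_generations = 2, n_snps = 400,
                   architecture = "null", seed = 63)
  nl <- st$ped[st$ped$pop == "NL", ]
  A <- build_A(nl)
  G <- build_G(st$panel, ids = nl$id)
  for (w in c(0, 0.8, 1)) {
    Gb <- blend_G_with_pedigree(G, A, weight = w, ridge = 0)
    expect_equal(unclass(Gb), unclass(w * G + (1 - w) * A),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  Gb <- blend_G_with_pedigree(G, A)
  M <- attr(G, "n_markers")
  expect_equal(attr(Gb, "weight"), M / (M + 1000))
  expect_error(blend_G_with_pedigree(G, A[rev(rownames(A)), rev(rownames(A))]),
               "same individuals")
})

test_that("cross-population centring controls between-block structure", {
  # unrelated populations: between-population entries average ~ 0
  st <- make_study(n_founders_per_pop = 80, n_generations = 1, n_snps = 2000,
                   between_pop_freq_corr = 0.9, architecture = "null",
                   seed = 64)
  Gx <- suppressMessages(build_crosspop_G(st$panel))
  between <- outer(st$panel$pop == "NL", st$panel$pop == "UK", `&`)
  expect_lt(abs(mean(Gx[between])), 0.01)
  # with drifted frequencies, own-population centring beats pooled centring
  st2 <- make_study(n_founders_per_pop = 80, n_generations = 1, n_snps = 2000,
                    between_pop_freq_corr = 0.6, architecture = "null",
                    seed = 65)
  Gx2 <- suppressMessages(build_crosspop_G(st2$panel))
  Gpool <- build_G(st2$panel, freq_source = "pooled")
  b2 <- outer(st2$panel$pop == "NL", st2$panel$pop == "UK", `&`)
  expect_lt(abs(mean(Gx2[b2])), abs(mean(Gpool[b2])))
})

test_that("relatedness matrices round-trip through the text format", {
  st <- make_study(n_founders_per_pop = 10, n_generations = 2, n_snps = 100,
                   architecture = "null", seed = 66)
  A <- build_A(st$ped)
  path <- withr::local_tempfile(fileext = ".grm.txt")
  write_relmat(A, path)
  expect_identical(unname(read_relmat(path)), unname(unclass(A)[,]))
  expect_identical(rownames(read_relmat(path)), rownames(A))
})
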