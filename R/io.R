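#' Write and read the package's plain-text data formats
#'
#' Pedigrees are tab-separated (`id`, `sire`, `dam`, `sex`, `cohort`,
#' `pop`) with `0` for an unknown parent; genotypes are PLINK-style
#' `.ped`/`.map` pairs (alleles coded `A`/`B`, `0 0` missing, family id =
#' population) or a compact dosage-matrix text; phenotypes and simulation
#' truth blocks are CSV with a header. All files round-trip through the
#' matching readers.
#'
#' @param pedigree,panel,traits The objects to write.
#' @param path,prefix Output locations (`prefix` produces `prefix.ped` and
#'   `prefix.map`).
#' @return The written path(s), invisibly; readers return the objects.
#' @name io_formats
NULL

#' @rdname io_formats
#' @export
write_pedigree <- function(pedigree, path) {
  out <- pedigree
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io_formats
#' @export
read_pedigree <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c(id = "character", sire = "character",
                                  dam = "character"))
  df$sire[df$sire == "0"] <- NA_character_
  df$dam[df$dam == "0"] <- NA_character_
  ped <- tibble::as_tibble(df)
  errors <- character(0)
  for (col in c("sire", "dam")) {
    bad <- setdiff(ped[[col]][!is.na(ped[[col]])], ped$id)
    if (length(bad)) {
      errors <- c(errors, paste0("unknown ", col, ": ",
                                 paste(bad, collapse = ", ")))
    }
  }
  if (length(errors)) abort(paste(errors, collapse = "; "))
  validate_pedigree(ped)
  ped
}

#' @rdname io_formats
#' @export
write_plink <- function(panel, pedigree, prefix) {
  map <- panel$map
  write.table(
    data.frame(chr = map$chr, snp = map$snp, cM = map$cM, bp = 0L),
    paste0(prefix, ".map"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  ids <- rownames(panel$dosage)
  ped <- pedigree[match(ids, pedigree$id), ]
  code <- function(d) {
    # dosage = count of allele B
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1, "B", "A"))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2, "B", "A"))
    paste(a1, a2)
  }
  geno_cols <- apply(panel$dosage, 1, code)
  lines <- vapply(seq_along(ids), function(i) {
    paste(c(ped$pop[i], ids[i],
            ifelse(is.na(ped$sire[i]), "0", ped$sire[i]),
            ifelse(is.na(ped$dam[i]), "0", ped$dam[i]),
            ifelse(ped$sex[i] == "M", "1", "2"), "-9",
            geno_cols[, i]), collapse = " ")
  }, character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
}

#' @rdname io_formats
#' @export
read_plink <- function(prefix) {
  map <- read.table(paste0(prefix, ".map"), sep = "\t",
                    col.names = c("chr", "snp", "cM", "bp"),
                    colClasses = c("character", "character", "numeric",
                                   "integer"))
  raw <- strsplit(readLines(paste0(prefix, ".ped")), " ")
  n <- length(raw)
  m <- nrow(map)
  dosage <- matrix(NA_integer_, n, m)
  ids <- character(n)
  pops <- character(n)
  for (i in seq_len(n)) {
    f <- raw[[i]]
    if (length(f) != 6 + 2 * m) {
      abort(sprintf("line %d of .ped has %d fields, expected %d",
                    i, length(f), 6 + 2 * m))
    }
    pops[i] <- f[1]
    ids[i] <- f[2]
    g <- matrix(f[-(1:6)], nrow = 2)
    missing <- g[1, ] == "0" | g[2, ] == "0"
    d <- (g[1, ] == "B") + (g[2, ] == "B")
    d[missing] <- NA_integer_
    dosage[i, ] <- d
  }
  dimnames(dosage) <- list(ids, map$snp)
  structure(list(dosage = dosage,
                 map = tibble::as_tibble(map[, c("snp", "chr", "cM")]),
                 chrom_info = tibble::tibble(
                   chr = unique(map$chr),
                   length_cM = vapply(unique(map$chr), function(cc) {
                     max(map$cM[map$chr == cc])
                   }, numeric(1)),
                   size_Mbp = NA_real_, gene_count = NA_real_),
                 pop = setNames(pops, ids)),
            class = "genotype_panel")
}

#' @rdname io_formats
#' @export
write_phenotypes <- function(traits, path) {
  utils::write.csv(as.data.frame(traits), path, row.names = FALSE)
  invisible(path)
}

#' @rdname io_formats
#' @export
read_phenotypes <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, colClasses = c(id = "character")))
  class(df) <- c("trait_data", class(df))
  df
}

#' Read and cross-validate a full input bundle
#'
#' Reads a pedigree, a PLINK genotype pair and a phenotype CSV, collecting
#' every cross-reference failure (unknown parents, cycles, phenotype
#' records for individuals absent from the pedigree, unmapped SNPs) into a
#' single itemized error.
#'
#' @param pedigree_file,plink_prefix,phenotype_file File locations.
#' @return A list (`pedigree`, `panel`, `traits`).
#' @export
read_inputs <- function(pedigree_file, plink_prefix, phenotype_file) {
  errors <- character(0)
  ped <- tryCatch(read_pedigree(pedigree_file),
                  error = function(e) {
                    errors <<- c(errors, conditionMessage(e))
                    NULL
                  })
  panel <- read_plink(plink_prefix)
  traits <- read_phenotypes(phenotype_file)
  if (any(is.na(panel$map$cM))) {
    errors <- c(errors, "unmapped SNPs in .map file")
  }
  if (!is.null(ped)) {
    orphan <- setdiff(unique(traits$id), ped$id)
    if (length(orphan)) {
      errors <- c(errors, paste0("phenotype records for individuals not in pedigree: ",
                                 paste(head(orphan, 5), collapse = ", ")))
    }
  }
  if (length(errors)) {
    abort(paste0("input validation failed:\n  - ",
                 paste(errors, collapse = "\n  - ")))
  }
  list(pedigree = ped, panel = panel, traits = traits)
}

#' Write a QTL scan as tab-separated text
#'
#' Columns chr, cM, LRT, LOD, p, qtl_var_prop; any attached thresholds are
#' recorded as `#`-comment header lines.
#'
#' @param scan A `qtl_scan`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_qtl_scan <- function(scan, path) {
  con <- file(path, "w")
  th <- attr(scan, "thresholds")
  if (!is.null(th)) {
    writeLines(sprintf("# threshold %s LOD=%.3f", th$threshold, th$LOD), con)
  }
  close(con)
  suppressWarnings(write.table(
    as.data.frame(scan)[, c("chr", "cM", "LRT", "LOD", "p", "qtl_var_prop")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, append = !is.null(th)))
  invisible(path)
}

#' Run the analysis pipeline on a dataset
#'
#' Executes the requested stages in dependency order on one population's
#' records — heritability (pedigree and blended-GRM animal models),
#' chromosome partitioning, variance-components QTL scan on the QTL
#' pedigree, scan power simulation, kinship-corrected GWAS on EPVs, the
#' multi-SNP (BVSR) analysis, and within-run concordance tests — and
#' writes one file per stage when `out_dir` is given. Every output carries
#' a header comment with the configuration hash and seed; all stochastic
#' stages are seeded, so a rerun with the same inputs is reproducible.
#'
#' @param pedigree,panel,traits Input objects (e.g. from the simulator or
#'   [read_inputs()]).
#' @param stages Subset of `c("heritability", "partition", "qtlscan",
#'   "power", "gwas", "bvsr", "concordance")`; an empty vector validates
#'   the inputs and returns.
#' @param population Population label to analyse.
#' @param fixed Fixed-effect formula for the mixed models.
#' @param nuisance Named list of i.i.d. random terms for the mixed models.
#' @param bvsr Optional [bvsr_config()].
#' @param qtl Options for the linkage stages: `grid_step_cM`, `n_samples`,
#'   `max_degree`, `effect_sizes`, `n_reps`.
#' @param min_snps_per_set Passed to [define_chromosome_sets()].
#' @param out_dir Optional output directory.
#' @param seed Integer seed.
#' @return A named list of stage results.
#' @export
run_pipeline <- function(pedigree, panel, traits,
                         stages = c("heritability", "partition", "gwas", "bvsr"),
                         population = NULL, fixed = ~sex,
                         nuisance = list(year = "iid"),
                         bvsr = NULL,
                         qtl = list(), min_snps_per_set = 50,
                         out_dir = NULL, seed = 1) {
  allowed <- c("heritability", "partition", "qtlscan", "power", "gwas",
               "bvsr", "concordance")
  bad <- setdiff(stages, allowed)
  if (length(bad)) abort(paste0("unknown stage: ", bad[1]))
  if (!is.null(population)) {
    pedigree <- pedigree[pedigree$pop == population, ]
    traits <- traits[traits$pop == population, ]
  }
  data <- as.data.frame(traits)
  ids <- intersect(unique(data$id), rownames(panel$dosage))
  results <- list()
  cfg_hash <- sprintf("%08x", sum(utf8ToInt(paste(
    nrow(pedigree), ncol(panel$dosage), nrow(data), seed, collapse = ":"))))
  stamp <- function(path, df) {
    con <- file(path, "w")
    writeLines(sprintf("# polyarch pipeline config=%s seed=%d", cfg_hash, seed), con)
    close(con)
    suppressWarnings(utils::write.table(df, path, sep = ",", row.names = FALSE,
                                        append = TRUE, quote = FALSE))
  }
  A <- build_A(pedigree, subset = ids)
  if ("heritability" %in% stages) {
    rnd_extra <- c(nuisance, if (anyDuplicated(data$id)) list(id = "iid"))
    fitA <- suppressWarnings(fit_reml(
      data[data$id %in% ids, ], "value", fixed = fixed,
      random = c(list(animal = vc_term("id", A)), rnd_extra)))
    G <- build_G(panel, ids = ids)
    Gb <- blend_G_with_pedigree(G, A)
    fitG <- suppressWarnings(fit_reml(
      data[data$id %in% ids, ], "value", fixed = fixed,
      random = c(list(animal = vc_term("id", Gb)), rnd_extra)))
    results$heritability <- dplyr::bind_rows(
      dplyr::mutate(glance(fitA), estimator = "pedigree"),
      dplyr::mutate(glance(fitG), estimator = "blended_grm"))
  }
  epv <- compute_EPV(data, "value", fixed = fixed, random = nuisance)
  if ("partition" %in% stages) {
    sets <- suppressMessages(define_chromosome_sets(panel, min_snps_per_set))
    results$partition <- partition_variance(
      data, "value", panel, sets, pedigree = pedigree, fixed = fixed,
      random = nuisance)
  }
  if ("gwas" %in% stages) {
    G <- build_G(panel, ids = ids)
    Gb <- blend_G_with_pedigree(G, A)
    gw <- suppressMessages(score_test_scan(epv, panel, Gb))
    keff <- effective_tests(panel)
    attr(gw, "K_eff") <- keff
    attr(gw, "threshold") <- bonferroni_threshold(0.05, keff)
    results$gwas <- gw
  }
  if ("bvsr" %in% stages) {
    cfg <- bvsr %||% bvsr_config(iterations = 6000, burn_in = 1000,
                                 chains = 2, seed = derive_seed(seed, "bvsr"))
    results$bvsr <- suppressMessages(run_bvsr(epv, panel, cfg))
  }
  if (any(c("qtlscan", "power") %in% stages)) {
    qo <- utils::modifyList(list(grid_step_cM = 5, n_samples = 300,
                                 max_degree = 4,
                                 effect_sizes = c(0, 0.2, 0.4), n_reps = 2),
                            qtl)
    qped <- build_qtl_pedigree(pedigree, ids, max_degree = qo$max_degree)
    if (nrow(qped) < 20) {
      inform("qtlscan: fewer than 20 linked genotyped individuals; stage skipped")
    } else {
      ibd <- suppressMessages(suppressWarnings(estimate_ibd_grid(
        qped, panel, grid_step_cM = qo$grid_step_cM,
        n_samples = qo$n_samples, seed = derive_seed(seed, "ibd"))))
      Aq <- build_A(qped)
      th <- lod_thresholds(C = nrow(panel$chrom_info),
                           G_morgans = sum(panel$chrom_info$length_cM) / 100)
      if ("qtlscan" %in% stages) {
        dq <- data[data$id %in% qped$id, , drop = FALSE]
        rnd_q <- c(nuisance, if (anyDuplicated(dq$id)) list(id = "iid"))
        results$qtlscan <- suppressWarnings(qtl_scan(
          dq, "value", ibd, Aq, fixed = fixed, random = rnd_q,
          thresholds = th))
      }
      if ("power" %in% stages) {
        results$power <- suppressWarnings(power_simulation(
          qped, panel, ibd, Aq, effect_sizes = qo$effect_sizes,
          n_reps = qo$n_reps, thresholds = th,
          seed = derive_seed(seed, "power")))
      }
    }
  }
  if ("concordance" %in% stages) {
    reports <- list()
    if (!is.null(results$qtlscan) && !is.null(results$gwas)) {
      at_snps <- interpolate_lod_at_snps(results$qtlscan, panel)
      shared <- intersect(at_snps$snp, results$gwas$snp)
      reports$gwas_qtl <- suppressMessages(gwas_qtl_overlap(
        results$gwas$p[match(shared, results$gwas$snp)],
        at_snps$p[match(shared, at_snps$snp)]))
    }
    if (!is.null(results$qtlscan) && !is.null(results$partition)) {
      per_set <- results$partition$per_set
      sets <- suppressMessages(define_chromosome_sets(panel, min_snps_per_set))
      qtl_flag <- vapply(per_set$set, function(nm) {
        chrs <- unique(panel$map$chr[panel$map$snp %in% sets[[nm]]])
        rows <- results$qtlscan$chr %in% chrs
        any(results$qtlscan$p[rows] < 0.05, na.rm = TRUE)
      }, logical(1))
      reports$partition_qtl <- partition_qtl_fisher(
        !is.na(per_set$p) & per_set$p < 0.05, qtl_flag)
    }
    if (length(reports)) {
      results$concordance <- dplyr::bind_rows(reports)
    } else {
      inform("concordance: requires qtlscan plus gwas and/or partition results")
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(results$heritability)) {
      stamp(file.path(out_dir, "heritability.csv"), results$heritability)
    }
    if (!is.null(results$partition)) {
      stamp(file.path(out_dir, "partition.csv"), results$partition$per_set)
      stamp(file.path(out_dir, "partition_regression.csv"),
            results$partition$regression)
    }
    if (!is.null(results$gwas)) {
      stamp(file.path(out_dir, "gwas.csv"), tibble::as_tibble(results$gwas))
    }
    if (!is.null(results$bvsr)) {
      stamp(file.path(out_dir, "bvsr_summary.csv"), results$bvsr$summaries)
      stamp(file.path(out_dir, "bvsr_samples.csv"), results$bvsr$samples)
    }
    if (!is.null(results$qtlscan)) {
      write_qtl_scan(results$qtlscan, file.path(out_dir, "qtl_scan.tsv"))
    }
    if (!is.null(results$power)) {
      stamp(file.path(out_dir, "power.csv"), tibble::as_tibble(results$power))
    }
    if (!is.null(results$concordance)) {
      stamp(file.path(out_dir, "concordance.csv"), results$concordance)
    }
  }
  results
}
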