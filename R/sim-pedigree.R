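#' Simulate a two-population, overlapping-generation pedigree
#'
#' Founders form cohort 0 of each population. In each subsequent cohort,
#' surviving adults are paired at random within their population (one brood
#' per pair-year, Poisson brood sizes); chicks enter the pedigree whether or
#' not they survive to breed. Adults may survive across seasons, so
#' generations overlap and the pedigree contains relatively few close
#' relative pairs, as is typical of wild passerine study populations. There
#' are no cross-population matings.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with columns `id`, `sire`, `dam` (`NA` = unknown),
#'   `sex` (`"F"`/`"M"`), `cohort` and `pop`, ordered so parents precede
#'   offspring.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "pedigree"), {
    pops <- c("NL", "UK")
    out <- vector("list", length(pops))
    for (k in seq_along(pops)) {
      out[[k]] <- simulate_one_population(config, pops[k])
    }
    ped <- dplyr::bind_rows(out)
    ped
  })
}

simulate_one_population <- function(config, pop) {
  nf <- config$n_founders_per_pop
  counter <- nf
  id <- sprintf("%s_%05d", pop, seq_len(nf))
  sex <- rep(c("F", "M"), length.out = nf)[sample.int(nf)]
  rows <- list(tibble::tibble(
    id = id, sire = NA_character_, dam = NA_character_,
    sex = sex, cohort = 0L, pop = pop
  ))
  # alive breeders carried between seasons
  alive <- tibble::tibble(id = id, sex = sex)
  # n_generations counts generations inclusive of the founders, so a value
  # of 1 yields a founders-only pedigree with no matings
  for (g in seq_len(config$n_generations - 1L)) {
    females <- alive$id[alive$sex == "F"]
    males <- alive$id[alive$sex == "M"]
    n_pairs <- min(length(females), length(males))
    if (n_pairs == 0) {
      abort(sprintf(paste0(
        "no breeding pairs available in population %s at cohort %d; ",
        "increase n_founders_per_pop, mean_offspring, survival_to_breed ",
        "or adult_survival"), pop, g))
    }
    dams <- sample(females, n_pairs)
    sires <- sample(males, n_pairs)
    brood <- rpois(n_pairs, config$mean_offspring)
    n_chicks <- sum(brood)
    chicks <- NULL
    if (n_chicks > 0) {
      cid <- sprintf("%s_%05d", pop, counter + seq_len(n_chicks))
      counter <- counter + n_chicks
      csex <- c("F", "M")[rbinom(n_chicks, 1, 0.5) + 1L]
      chicks <- tibble::tibble(
        id = cid,
        sire = rep(sires, brood),
        dam = rep(dams, brood),
        sex = csex,
        cohort = g,
        pop = pop
      )
      rows[[length(rows) + 1L]] <- chicks
    }
    # survival to the next season: adults and recruiting chicks
    keep_adult <- alive[runif(nrow(alive)) < config$adult_survival, ]
    recruits <- if (is.null(chicks)) NULL else {
      chicks[runif(nrow(chicks)) < config$survival_to_breed, c("id", "sex")]
    }
    alive <- dplyr::bind_rows(keep_adult, recruits)
    if (nrow(alive) == 0 && g < config$n_generations) {
      abort(sprintf(paste0(
        "population %s went extinct after cohort %d; increase ",
        "survival_to_breed or mean_offspring"), pop, g))
    }
  }
  dplyr::bind_rows(rows)
}
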