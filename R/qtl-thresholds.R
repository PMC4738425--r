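#' Genome-wide LOD thresholds for a variance-components scan
#'
#' Computes nominal, suggestive and significant LOD thresholds for a
#' dense-map genome scan following the expected-exceedance argument of
#' Lander and Kruglyak. With `C` mapped chromosomes, a map of `G` morgans
#' and crossover-rate constant `rho`, the expected number of independent
#' exceedances of LOD level `t` in one scan is
#' `mu(t) = [C + 2 rho G (2 ln 10) t] * p_nom(t)`, where
#' `p_nom(t) = 0.5 P(chisq_1 >= (2 ln 10) t)` is the nominal pointwise
#' p-value under the 50:50 boundary mixture. The suggestive threshold
#' solves `mu(t) = 1` (one chance exceedance per scan) and the significant
#' threshold solves `mu(t) = 0.05`; the nominal threshold solves
#' `p_nom(t) = 0.05`. Thresholds are rounded to 3 decimals for display.
#'
#' @param C Number of mapped chromosomes.
#' @param G_morgans Total map length in morgans.
#' @param rho Crossover-rate design constant (1 for a general pedigree
#'   design).
#' @param targets Expected exceedances defining the suggestive and
#'   significant levels.
#' @return A tibble with `threshold` (`nominal`, `suggestive`,
#'   `significant`), `LOD`, and the pointwise p-value `p_nominal` at each
#'   LOD.
#' @export
lod_thresholds <- function(C, G_morgans, rho = 1,
                           targets = c(suggestive = 1, significant = 0.05)) {
  stopifnot(C >= 1, G_morgans > 0, rho > 0)
  l10 <- 2 * log(10)
  p_nom <- function(t) 0.5 * pchisq(l10 * t, df = 1, lower.tail = FALSE)
  mu <- function(t) (C + 2 * rho * G_morgans * l10 * t) * p_nom(t)
  solve_mu <- function(target) {
    lo <- 1e-8
    hi <- 100
    # tiny genomes: even a LOD of ~0 is exceeded less often than the target
    if (mu(lo) <= target) {
      return(0)
    }
    if (mu(hi) > target) {
      abort("no LOD threshold root in (0, 100) for the requested exceedance level")
    }
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (mu(mid) > target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  nominal <- qchisq(0.1, df = 1, lower.tail = FALSE) / l10
  lods <- c(nominal = nominal,
            suggestive = solve_mu(targets[["suggestive"]]),
            significant = solve_mu(targets[["significant"]]))
  tibble::tibble(
    threshold = names(lods),
    LOD = round(unname(lods), 3),
    p_nominal = p_nom(unname(lods))
  )
}

#' Expected exceedances of a LOD level in one genome scan
#'
#' The dense-map expected-exceedance function used to calibrate
#' [lod_thresholds()]; exposed for self-consistency checks.
#'
#' @param t LOD level.
#' @inheritParams lod_thresholds
#' @return Expected number of chance exceedances per scan.
#' @export
expected_exceedances <- function(t, C, G_morgans, rho = 1) {
  l10 <- 2 * log(10)
  (C + 2 * rho * G_morgans * l10 * t) *
    0.5 * pchisq(l10 * t, df = 1, lower.tail = FALSE)
}
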