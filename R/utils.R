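#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats rnorm runif rbinom rpois sd var cor median pchisq qchisq
#'   pnorm qnorm pt quantile model.matrix as.formula setNames complete.cases
#'   lm coef fisher.test chisq.test dhyper rhyper phyper pbinom optimize
#' @importFrom utils head tail write.table read.table
#' @importFrom Rcpp evalCpp
#' @useDynLib polyarch, .registration = TRUE
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and a stream label, staying < 2^31.
derive_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 7919 + offs) %% 2147483647L)
}

# Haldane map function: recombination fraction for a distance in cM.
haldane_theta <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

stopifnot_named <- function(x, what) {
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    abort(paste0("`", what, "` must be a fully named vector"))
  }
}

# Topological order of a pedigree tibble (parents before offspring).
# Errors on cycles, naming an individual on the cycle.
ped_order <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  sire_i <- unname(idx[as.character(ped$sire)])
  dam_i <- unname(idx[as.character(ped$dam)])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in idx) {
    for (p in c(sire_i[i], dam_i[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    bad <- ped$id[setdiff(idx, out)][1]
    abort(paste0("pedigree contains a cycle involving individual '", bad, "'"))
  }
  out
}

validate_pedigree <- function(ped) {
  req <- c("id", "sire", "dam")
  if (!all(req %in% names(ped))) {
    abort("pedigree must have columns id, sire, dam")
  }
  if (anyDuplicated(ped$id)) {
    abort(paste0("duplicated pedigree id: '", ped$id[duplicated(ped$id)][1], "'"))
  }
  for (col in c("sire", "dam")) {
    known <- !is.na(ped[[col]])
    missing_parent <- setdiff(ped[[col]][known], ped$id)
    if (length(missing_parent)) {
      abort(paste0("pedigree ", col, " '", missing_parent[1], "' is not a listed individual"))
    }
  }
  ped_order(ped) # errors on cycles
  invisible(ped)
}
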