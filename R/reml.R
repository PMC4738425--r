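#' Random-term specification for the animal model
#'
#' @param factor Name of the grouping column in the data.
#' @param K Covariance matrix over the factor's levels (dimnames required),
#'   or `NULL` for an identity (i.i.d.) term.
#' @return A `vc_term` list.
#' @export
vc_term <- function(factor, K = NULL) {
  structure(list(factor = factor, K = K), class = "vc_term")
}

normalize_random <- function(random, data) {
  if (length(random) == 0) {
    return(list())
  }
  if (is.null(names(random)) || any(!nzchar(names(random)))) {
    abort("`random` must be a fully named list")
  }
  out <- list()
  for (nm in names(random)) {
    el <- random[[nm]]
    if (inherits(el, "vc_term")) {
      out[[nm]] <- el
    } else if (is.matrix(el)) {
      out[[nm]] <- vc_term(nm, el)
    } else if (identical(el, "iid")) {
      out[[nm]] <- vc_term(nm, NULL)
    } else {
      abort(paste0("random term '", nm, "' must be a vc_term, a matrix or \"iid\""))
    }
    fac <- out[[nm]]$factor
    if (!fac %in% names(data)) {
      abort(paste0("random term '", nm, "': column '", fac, "' not in data"))
    }
  }
  out
}

# Build the record-level covariance structure matrix Z K Z' for one term.
term_structure <- function(term, data, ridge = 0) {
  f <- as.character(data[[term$factor]])
  if (is.null(term$K)) {
    lev <- unique(f)
    Z <- outer(f, lev, `==`) * 1
    tcrossprod(Z)
  } else {
    K <- term$K
    lev <- rownames(K)
    missing_lev <- setdiff(unique(f), lev)
    if (length(missing_lev)) {
      abort(paste0("random term on '", term$factor, "': level '",
                   missing_lev[1], "' absent from covariance matrix"))
    }
    if (ridge > 0) {
      K <- K + diag(ridge, nrow(K))
    }
    idx <- match(f, lev)
    K[idx, idx, drop = FALSE]
  }
}

# ---------------------------------------------------------------------------
# Core variance-component REML solver.
#
# V = sum_t theta_t * C_t, where the last `n_resid` components are diagonal
# residual blocks. Average-information updates with an initial EM-flavoured
# step and step-halving whenever a proposal does not improve the restricted
# likelihood; components are floored at a small positive value (residual
# blocks) or at ~0 (other non-negative components) and excluded from the
# update while their gradient points outward.
# ---------------------------------------------------------------------------
fit_vc <- function(y, X, Clist, nonneg = NULL, resid_masks = NULL,
                   init = NULL, max_iter = 100, tol = 1e-6) {
  n <- length(y)
  if (is.null(resid_masks)) resid_masks <- list(rep(1, n))
  r <- length(Clist)
  ncomp <- r + length(resid_masks)
  nonneg <- nonneg %||% rep(TRUE, r)
  nonneg <- c(nonneg, rep(TRUE, length(resid_masks)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("fixed-effect design is singular; aliased terms: ",
                 paste(aliased, collapse = ", ")))
  }
  if (n <= ncol(X)) abort("more fixed effects than observations")
  vp <- var(y)
  if (!is.finite(vp) || vp <= 0) abort("response has zero variance")
  theta <- init %||% rep(vp / ncomp, ncomp)
  floors <- c(ifelse(nonneg[seq_len(r)], 1e-8 * vp, -Inf),
              rep(1e-6 * vp, length(resid_masks)))
  theta <- pmax(theta, floors + ifelse(is.finite(floors), 0, 0))

  # constant making the restricted likelihood invariant to fixed-effect
  # reparameterization (log|X'X| convention)
  ldXtX <- 2 * sum(log(abs(diag(qr.R(qrX)))))
  build_V <- function(th) {
    V <- matrix(0, n, n)
    for (t in seq_len(r)) V <- V + th[t] * Clist[[t]]
    dg <- rep(0, n)
    for (s in seq_along(resid_masks)) {
      dg <- dg + th[r + s] * resid_masks[[s]]
    }
    V + diag(dg, n)
  }
  eval_ll <- function(th) {
    V <- build_V(th)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) {
      return(list(ll = -Inf))
    }
    Vinv <- chol2inv(ch)
    W <- Vinv %*% X
    XtViX <- crossprod(X, W)
    chX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chX)) {
      return(list(ll = -Inf))
    }
    XtViXinv <- chol2inv(chX)
    Py <- Vinv %*% y - W %*% (XtViXinv %*% crossprod(W, y))
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) -
                    ldXtX + sum(y * Py))
    list(ll = ll, Vinv = Vinv, W = W, XtViXinv = XtViXinv, Py = drop(Py))
  }
  comp_mat <- function(t) {
    if (t <= r) Clist[[t]] else diag(resid_masks[[t - r]], n)
  }

  st <- eval_ll(theta)
  if (!is.finite(st$ll)) abort("initial variance components give a singular covariance")
  trajectory <- st$ll
  converged <- FALSE
  grad <- rep(NA_real_, ncomp)
  AI <- matrix(NA_real_, ncomp, ncomp)
  for (iter in seq_len(max_iter)) {
    Py <- st$Py
    u <- vector("list", ncomp)
    trPG <- numeric(ncomp)
    for (t in seq_len(ncomp)) {
      Ct <- comp_mat(t)
      u[[t]] <- drop(Ct %*% Py)
      WtC <- crossprod(st$W, Ct)
      trPG[t] <- sum(st$Vinv * Ct) - sum(st$XtViXinv * (WtC %*% st$W))
      grad[t] <- -0.5 * (trPG[t] - sum(Py * u[[t]]))
    }
    Pu <- lapply(u, function(v) {
      drop(st$Vinv %*% v - st$W %*% (st$XtViXinv %*% crossprod(st$W, v)))
    })
    for (t in seq_len(ncomp)) {
      for (s in t:ncomp) {
        AI[t, s] <- AI[s, t] <- 0.5 * sum(u[[t]] * Pu[[s]])
      }
    }
    pinned <- theta <= floors + 1e-12 & grad < 0 & is.finite(floors)
    free <- which(!pinned)
    if (length(free) == 0) {
      converged <- TRUE
      break
    }
    if (iter == 1) {
      # EM-flavoured opening step: scaled gradient, always defensible
      delta_full <- theta^2 * (sapply(seq_len(ncomp), function(t) {
        sum(Py * u[[t]])
      }) - trPG) / n
      delta <- delta_full[free]
    } else {
      Afree <- AI[free, free, drop = FALSE]
      delta <- tryCatch(solve(Afree + diag(1e-10, length(free)), grad[free]),
                        error = function(e) grad[free] * 1e-3)
    }
    step <- 1
    improved <- FALSE
    for (half in 1:12) {
      prop <- theta
      prop[free] <- theta[free] + step * delta
      prop <- pmax(prop, floors)
      cand <- eval_ll(prop)
      if (is.finite(cand$ll) && cand$ll > st$ll - 1e-10) {
        theta <- prop
        ll_prev <- st$ll
        st <- cand
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) {
      converged <- abs(max(abs(grad[free]))) < 1e-3
      break
    }
    trajectory <- c(trajectory, st$ll)
    if (abs(st$ll - ll_prev) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && length(trajectory) >= max_iter) {
    converged <- FALSE
  }
  se <- rep(NA_real_, ncomp)
  free <- which(!(theta <= floors + 1e-12))
  covfree <- NULL
  if (length(free)) {
    covfree <- tryCatch(solve(AI[free, free, drop = FALSE]),
                        error = function(e) NULL)
    if (!is.null(covfree)) se[free] <- sqrt(pmax(diag(covfree), 0))
  }
  beta_cov <- st$XtViXinv
  beta <- drop(beta_cov %*% crossprod(st$W, y))
  names(beta) <- colnames(X)
  list(theta = theta, se = se, logLik = st$ll, beta = beta,
       beta_cov = beta_cov, converged = converged, n_iter = iter,
       gradient = grad, gradient_norm = sqrt(sum(grad^2)),
       trajectory = trajectory, Py = st$Py, Vinv = st$Vinv, W = st$W,
       XtViXinv = st$XtViXinv, theta_cov = covfree, free = free)
}

# Fast path for a single covariance component plus one residual block:
# rotate into the eigenbasis of C once, after which every REML iteration is
# O(n). The eigendecomposition may be precomputed and attached to C as
# attr(C, "eigen") and reused across fits (e.g. replicate simulations on a
# fixed pedigree).
fit_vc_eigen <- function(y, X, C, max_iter = 100, tol = 1e-6) {
  eig <- attr(C, "eigen") %||% eigen(C, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)
  n <- length(ys)
  qrX <- qr(Xs)
  if (qrX$rank < ncol(Xs)) {
    aliased <- colnames(Xs)[qrX$pivot[(qrX$rank + 1):ncol(Xs)]]
    abort(paste0("fixed-effect design is singular; aliased terms: ",
                 paste(aliased, collapse = ", ")))
  }
  vp <- var(y)
  theta <- c(vp / 2, vp / 2)
  floors <- c(1e-8 * vp, 1e-6 * vp)
  ldXtX <- 2 * sum(log(abs(diag(qr.R(qrX)))))
  eval_ll <- function(th) {
    d <- th[1] * lam + th[2]
    if (any(d <= 0)) {
      return(list(ll = -Inf))
    }
    Xd <- Xs / d
    XtViX <- crossprod(Xs, Xd)
    chX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chX)) {
      return(list(ll = -Inf))
    }
    XtViXinv <- chol2inv(chX)
    Xty <- crossprod(Xd, ys)
    Py <- ys / d - Xd %*% (XtViXinv %*% Xty)
    ll <- -0.5 * (sum(log(d)) + 2 * sum(log(diag(chX))) - ldXtX + sum(ys * Py))
    list(ll = ll, d = d, Py = drop(Py), Xd = Xd, XtViXinv = XtViXinv)
  }
  st <- eval_ll(theta)
  trajectory <- st$ll
  converged <- FALSE
  grad <- c(NA_real_, NA_real_)
  AI <- matrix(NA_real_, 2, 2)
  for (iter in seq_len(max_iter)) {
    Py <- st$Py
    d <- st$d
    u1 <- lam * Py
    u2 <- Py
    Pv <- function(v) {
      drop(v / d - st$Xd %*% (st$XtViXinv %*% crossprod(st$Xd, v)))
    }
    # tr(P C) = tr(Vinv C) - tr((X'VinvX)^-1 X'Vinv C Vinv X)
    tr1 <- sum(lam / d) - sum(st$XtViXinv * crossprod(st$Xd, lam * st$Xd))
    tr2 <- sum(1 / d) - sum(st$XtViXinv * crossprod(st$Xd, st$Xd))
    grad <- -0.5 * c(tr1 - sum(Py * u1), tr2 - sum(Py * u2))
    P1 <- Pv(u1)
    P2 <- Pv(u2)
    AI <- 0.5 * matrix(c(sum(u1 * P1), sum(u1 * P2),
                         sum(u1 * P2), sum(u2 * P2)), 2, 2)
    pinned <- theta <= floors + 1e-12 & grad < 0
    free <- which(!pinned)
    if (!length(free)) {
      converged <- TRUE
      break
    }
    delta <- if (iter == 1) {
      (theta^2 * (c(sum(Py * u1), sum(Py * u2)) - c(tr1, tr2)) / n)[free]
    } else {
      tryCatch(solve(AI[free, free, drop = FALSE] + diag(1e-12, length(free)),
                     grad[free]),
               error = function(e) grad[free] * 1e-3)
    }
    step <- 1
    improved <- FALSE
    for (half in 1:12) {
      prop <- theta
      prop[free] <- theta[free] + step * delta
      prop <- pmax(prop, floors)
      cand <- eval_ll(prop)
      if (is.finite(cand$ll) && cand$ll > st$ll - 1e-10) {
        theta <- prop
        ll_prev <- st$ll
        st <- cand
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) {
      converged <- max(abs(grad[free])) < 1e-3
      break
    }
    trajectory <- c(trajectory, st$ll)
    if (abs(st$ll - ll_prev) < tol) {
      converged <- TRUE
      break
    }
  }
  se <- rep(NA_real_, 2)
  free <- which(theta > floors + 1e-12)
  covfree <- tryCatch(solve(AI[free, free, drop = FALSE]),
                      error = function(e) NULL)
  if (!is.null(covfree)) se[free] <- sqrt(pmax(diag(covfree), 0))
  XtViXinv <- st$XtViXinv
  beta <- drop(XtViXinv %*% crossprod(st$Xd, ys))
  names(beta) <- colnames(X)
  # back-rotate the projected residual for downstream use
  Py_orig <- drop(U %*% st$Py)
  list(theta = theta, se = se, logLik = st$ll, beta = beta,
       beta_cov = XtViXinv, converged = converged, n_iter = iter,
       gradient = grad, gradient_norm = sqrt(sum(grad^2)),
       trajectory = trajectory, Py = Py_orig, Vinv = NULL, W = NULL,
       XtViXinv = XtViXinv, theta_cov = covfree, free = free)
}

#' Fit an animal model by average-information REML
#'
#' Fits a Gaussian mixed model with arbitrary relatedness-structured and
#' i.i.d. random terms by restricted maximum likelihood, using
#' average-information updates with an EM-flavoured opening step,
#' step-halving, and non-negativity constraints handled by projection to
#' the boundary. With exactly one relatedness term plus a residual the
#' model is solved in the eigenbasis of the relatedness matrix, which makes
#' replicate fits on a fixed pedigree essentially free.
#'
#' @param data A data frame of records.
#' @param response Name of the response column.
#' @param fixed One-sided formula of fixed effects (default intercept only).
#' @param random Named list of random terms: a [vc_term()], a covariance
#'   matrix (grouping column = the term's name), or the string `"iid"`.
#' @param genetic Label of the term whose variance enters the reported
#'   heritability (default `"animal"` if present, else the first
#'   matrix-structured term).
#' @param ridge Diagonal ridge added to relatedness matrices for numerical
#'   invertibility.
#' @param init,max_iter,tol Optimizer controls; convergence is declared
#'   when the restricted log-likelihood changes by less than `tol`.
#' @return A `vc_fit` object; see [tidy.vc_fit()] and [glance.vc_fit()].
#' @export
fit_reml <- function(data, response, fixed = NULL, random = list(),
                     genetic = NULL, ridge = 1e-6, init = NULL,
                     max_iter = 100, tol = 1e-6) {
  y <- data[[response]]
  if (is.null(y)) abort(paste0("response column '", response, "' not found"))
  X <- if (is.null(fixed)) {
    matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    model.matrix(fixed, data)
  }
  if (nrow(X) != length(y)) abort("fixed-effect covariates contain missing values")
  terms <- normalize_random(random, data)
  Clist <- lapply(terms, term_structure, data = data, ridge = ridge)
  use_eigen <- length(terms) == 1 && !is.null(terms[[1]]$K) && is.null(init)
  core <- if (use_eigen) {
    C <- Clist[[1]]
    f <- as.character(data[[terms[[1]]$factor]])
    if (!anyDuplicated(f)) {
      K <- terms[[1]]$K
      keig <- attr(K, "eigen")
      if (!is.null(keig) && identical(rownames(K), f)) attr(C, "eigen") <- keig
    }
    fit_vc_eigen(y, X, C, max_iter = max_iter, tol = tol)
  } else {
    fit_vc(y, X, Clist, init = init, max_iter = max_iter, tol = tol)
  }
  if (!core$converged) {
    warn(sprintf("REML did not converge after %d iterations (|grad| = %.2e)",
                 core$n_iter, max(abs(core$gradient), na.rm = TRUE)))
  }
  term_names <- c(names(terms), "residual")
  vc <- tibble::tibble(term = term_names,
                       variance = core$theta,
                       SE = core$se)
  genetic <- genetic %||% {
    km <- names(terms)[!vapply(terms, function(t) is.null(t$K), logical(1))]
    if ("animal" %in% names(terms)) "animal" else if (length(km)) km[1] else NA
  }
  h2 <- h2_se <- NA_real_
  if (!is.na(genetic) && genetic %in% names(terms)) {
    gi <- match(genetic, term_names)
    tot <- sum(core$theta)
    h2 <- core$theta[gi] / tot
    if (!is.null(core$theta_cov)) {
      # delta method on h = theta_g / sum(theta) over the free components
      free <- core$free
      gvec <- (as.numeric(free == gi) * tot - core$theta[gi]) / tot^2
      h2_se <- sqrt(max(drop(t(gvec) %*% core$theta_cov %*% gvec), 0))
    }
  }
  out <- list(varcomp = vc, beta = tibble::tibble(term = names(core$beta),
                                                  estimate = core$beta),
              logLik = core$logLik, h2 = h2, h2_se = h2_se,
              converged = core$converged, n_iter = core$n_iter,
              gradient_norm = core$gradient_norm, n_obs = length(y),
              genetic = genetic, core = core, terms = terms,
              response = response, data = data)
  class(out) <- "vc_fit"
  out
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("<vc_fit> %s, n = %d, logLik(REML) = %.3f%s\n", x$response,
              x$n_obs, x$logLik,
              if (x$converged) "" else " (NOT converged)"))
  print(as.data.frame(x$varcomp), row.names = FALSE)
  if (!is.na(x$h2)) {
    cat(sprintf("  h2 = %.3f (SE %.3f)\n", x$h2, x$h2_se))
  }
  invisible(x)
}

#' Tidy a REML fit
#'
#' @param x A `vc_fit`.
#' @param ... Unused.
#' @return One row per variance component (`term`, `variance`, `SE`).
#' @export
tidy.vc_fit <- function(x, ...) x$varcomp

#' One-row summary of a REML fit
#'
#' @param x A `vc_fit`.
#' @param ... Unused.
#' @return A tibble with log-likelihood, heritability and diagnostics.
#' @export
glance.vc_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, h2 = x$h2, h2_se = x$h2_se,
                 converged = x$converged, n_iter = x$n_iter,
                 gradient_norm = x$gradient_norm, n_obs = x$n_obs)
}

#' @export
logLik.vc_fit <- function(object, ...) object$logLik

#' BLUPs of a fitted random term
#'
#' @param fit A `vc_fit` fitted with the dense solver.
#' @param term Term label.
#' @return A tibble (`level`, `blup`).
#' @export
ranef_blup <- function(fit, term) {
  if (!term %in% names(fit$terms)) abort(paste0("no random term '", term, "'"))
  tm <- fit$terms[[term]]
  f <- as.character(fit$data[[tm$factor]])
  theta <- fit$varcomp$variance[match(term, fit$varcomp$term)]
  Py <- fit$core$Py
  if (is.null(tm$K)) {
    lev <- unique(f)
    Zt_Py <- vapply(lev, function(l) sum(Py[f == l]), numeric(1))
    u <- theta * Zt_Py
  } else {
    lev <- rownames(tm$K)
    Zt_Py <- vapply(lev, function(l) sum(Py[f == l]), numeric(1))
    u <- theta * drop(tm$K %*% Zt_Py)
  }
  tibble::tibble(level = lev, blup = unname(u))
}
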