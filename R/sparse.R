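# Soft-threshold z so that exactly `keep` entries stay nonzero: the
# threshold is the (keep+1)-th largest |z|; ties are broken by variable
# order (earlier variables win). Returns the thresholded vector.
soft_keep <- function(z, keep) {
  p <- length(z)
  if (keep >= p) return(z)
  ord <- order(-abs(z), seq_along(z))
  lam <- abs(z[ord[keep + 1]])
  out <- numeric(p)
  sel <- ord[seq_len(keep)]
  out[sel] <- sign(z[sel]) * pmax(abs(z[sel]) - lam, 0)
  out
}

#' Sparse PCA by SVD with lasso (soft-thresholding) regularization
#'
#' Per component, alternates `u <- Xv / |Xv|` and `v <- S(X'u)` where `S`
#' soft-thresholds so exactly `keep` loadings remain nonzero (the
#' cardinality form of the lasso penalty), to convergence; the loading is
#' normalised and the component deflated from `X` by its rank-one fit.
#' With `keep` equal to the number of variables this reduces to ordinary
#' SVD-based PCA.
#'
#' @param X Matrix or data frame, observations in rows; column-centered
#'   internally unless `center = FALSE`.
#' @param ncomp Number of sparse components (default 2).
#' @param keep Number of nonzero loadings per component (default 50).
#' @param center,scale Column centering / unit-variance scaling.
#' @param max_iter,tol Alternation control.
#' @return A `sparse_fit`: `loadings` (variable x component, unit columns,
#'   at most `keep` nonzeros each), `scores` (observation x component),
#'   `d` (component singular values), `method = "spca"`.
#' @export
spca <- function(X, ncomp = 2, keep = 50, center = TRUE, scale = FALSE,
                 max_iter = 500, tol = 1e-9) {
  X <- as_numeric_matrix(X)
  p <- ncol(X)
  if (keep > p) abort("`keep` exceeds the number of variables")
  if (center) X <- sweep(X, 2, colMeans(X))
  if (scale) {
    sds <- apply(X, 2, sd)
    if (any(sds <= 0)) abort("constant column with scale = TRUE")
    X <- sweep(X, 2, sds, "/")
  }
  vars <- colnames(X) %||% paste0("V", seq_len(p))
  V <- matrix(0, p, ncomp, dimnames = list(vars, paste0("Comp", seq_len(ncomp))))
  S <- matrix(0, nrow(X), ncomp, dimnames = list(rownames(X), colnames(V)))
  d <- numeric(ncomp)
  Xd <- X
  for (h in seq_len(ncomp)) {
    sv <- svd(Xd, nu = 1, nv = 1)
    v <- sv$v[, 1]
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      xv <- Xd %*% v
      nu <- sqrt(sum(xv^2))
      if (nu <= 0) break
      u <- xv / nu
      z <- crossprod(Xd, u)[, 1]
      vnew <- soft_keep(z, keep)
      nv <- sqrt(sum(vnew^2))
      if (nv <= 0) { # degenerate threshold: fall back to hard selection
        sel <- order(-abs(z), seq_along(z))[seq_len(keep)]
        vnew <- numeric(p); vnew[sel] <- z[sel]
        nv <- sqrt(sum(vnew^2))
      }
      vnew <- vnew / nv
      if (sqrt(sum((vnew - v)^2)) < tol) { v <- vnew; ok <- TRUE; break }
      v <- vnew
    }
    if (!ok) warn(sprintf("spca component %d: not converged in %d iterations", h, max_iter))
    # sign policy: orient so the largest-|loading| entry is positive
    i <- which.max(abs(v))
    if (v[i] < 0) v <- -v
    s <- Xd %*% v
    dh <- sqrt(sum(s^2))
    u <- if (dh > 0) s / dh else s
    V[, h] <- v
    S[, h] <- s
    d[h] <- dh
    Xd <- Xd - dh * tcrossprod(u, v)
  }
  structure(list(loadings = V, scores = S, d = d,
                 method = "spca", keep = keep, ncomp = ncomp),
            class = "sparse_fit")
}

#' Two-block sparse PLS (canonical mode)
#'
#' Couples a gene block `X` and a metabolite block `Y` sharing observations:
#' per component, the cross-covariance `M = X'Y` is decomposed by
#' SVD-style alternation with soft-thresholding of the X-loading to `keep_x`
#' nonzeros (and optionally the Y-loading to `keep_y`; by default all
#' metabolites are retained). Latent scores are `xi = Xu`, `omega = Yv`;
#' both blocks are deflated by regression on their own latent score
#' (canonical mode — the blocks are co-analyzed, neither predicts the
#' other).
#'
#' @param X,Y Matrices/data frames with the same rows.
#' @param ncomp Number of components (default 2).
#' @param keep_x Nonzero X-loadings per component (default 50).
#' @param keep_y Nonzero Y-loadings per component (default: all).
#' @param center,scale Column centering / scaling of both blocks.
#' @param max_iter,tol Alternation control.
#' @return A `sparse_fit` with `loadings` (X block), `y_loadings`,
#'   `scores` (xi), `y_scores` (omega), `d` (component covariances),
#'   `method = "spls"`.
#' @export
spls <- function(X, Y, ncomp = 2, keep_x = 50, keep_y = NULL,
                 center = TRUE, scale = FALSE, max_iter = 500, tol = 1e-9) {
  X <- as_numeric_matrix(X); Y <- as_numeric_matrix(Y)
  if (nrow(X) != nrow(Y)) abort("X and Y must share rows")
  if (keep_x > ncol(X)) abort("`keep_x` exceeds the number of X variables")
  prep <- function(M) {
    if (center) M <- sweep(M, 2, colMeans(M))
    if (scale) {
      sds <- apply(M, 2, sd)
      sds[sds <= 0] <- 1
      M <- sweep(M, 2, sds, "/")
    }
    M
  }
  X <- prep(X); Y <- prep(Y)
  p <- ncol(X); q <- ncol(Y)
  keep_y <- keep_y %||% q
  xv <- colnames(X) %||% paste0("X", seq_len(p))
  yv <- colnames(Y) %||% paste0("Y", seq_len(q))
  U <- matrix(0, p, ncomp, dimnames = list(xv, paste0("Comp", seq_len(ncomp))))
  V <- matrix(0, q, ncomp, dimnames = list(yv, colnames(U)))
  Xi <- matrix(0, nrow(X), ncomp, dimnames = list(rownames(X), colnames(U)))
  Om <- Xi
  d <- numeric(ncomp)
  Xd <- X; Yd <- Y
  ncomp_eff <- ncomp
  for (h in seq_len(ncomp)) {
    M <- crossprod(Xd, Yd)
    sv <- svd(M, nu = 1, nv = 1)
    if (sv$d[1] <= max(sv$d) * 1e-12 || sv$d[1] == 0) {
      warn(sprintf("spls: cross-covariance rank-deficient; returning %d component(s)", h - 1L))
      ncomp_eff <- h - 1L
      break
    }
    u <- sv$u[, 1]; v <- sv$v[, 1]
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      zu <- M %*% v
      unew <- soft_keep(zu[, 1], keep_x)
      nu_ <- sqrt(sum(unew^2))
      if (nu_ <= 0) {
        sel <- order(-abs(zu), seq_len(p))[seq_len(keep_x)]
        unew <- numeric(p); unew[sel] <- zu[sel]
        nu_ <- sqrt(sum(unew^2))
      }
      unew <- unew / nu_
      zv <- crossprod(M, unew)
      vnew <- if (keep_y < q) soft_keep(zv[, 1], keep_y) else zv[, 1]
      vnew <- vnew / sqrt(sum(vnew^2))
      if (sqrt(sum((unew - u)^2)) + sqrt(sum((vnew - v)^2)) < tol) {
        u <- unew; v <- vnew; ok <- TRUE; break
      }
      u <- unew; v <- vnew
    }
    if (!ok) warn(sprintf("spls component %d: not converged", h))
    # orient jointly: largest-|u| entry positive
    i <- which.max(abs(u))
    if (u[i] < 0) { u <- -u; v <- -v }
    xi <- Xd %*% u
    om <- Yd %*% v
    U[, h] <- u; V[, h] <- v
    Xi[, h] <- xi; Om[, h] <- om
    d[h] <- crossprod(xi, om)[1]
    # canonical-mode deflation: each block on its own latent score
    if (sum(xi^2) > 0) Xd <- Xd - tcrossprod(xi / sum(xi^2), crossprod(Xd, xi))
    if (sum(om^2) > 0) Yd <- Yd - tcrossprod(om / sum(om^2), crossprod(Yd, om))
  }
  keepc <- seq_len(ncomp_eff)
  structure(list(loadings = U[, keepc, drop = FALSE],
                 y_loadings = V[, keepc, drop = FALSE],
                 scores = Xi[, keepc, drop = FALSE],
                 y_scores = Om[, keepc, drop = FALSE],
                 d = d[keepc], method = "spls",
                 keep = keep_x, keep_y = keep_y, ncomp = ncomp_eff),
            class = "sparse_fit")
}

#' @export
print.sparse_fit <- function(x, ...) {
  cat(sprintf("# Sparse %s fit: %d component(s), keep %d; %d variable(s) selected\n",
              toupper(x$method), x$ncomp, x$keep,
              sum(rowSums(abs(x$loadings)) > 0)))
  invisible(x)
}

#' Selected variables of a sparse fit or consolidation
#'
#' @param fit A [spca()], [spls()] or [bootstrap_consolidate()] object.
#' @return Character vector of variables with a nonzero loading in any
#'   component (for consolidations: the retained set).
#' @export
selected_variables <- function(fit) {
  if (inherits(fit, "sparse_consolidation")) return(fit$retained)
  rownames(fit$loadings)[rowSums(abs(fit$loadings)) > 0]
}

#' Bootstrap consolidation of a sparse selection
#'
#' Stabilises sparse PCA/PLS gene selection: observations are resampled
#' with replacement `n_boot` times (stratified by subject when `strata` is
#' given, preserving the paired injected/contralateral design), the sparse
#' fit is recomputed on every resample, and each variable's selection
#' frequency is the share of resamples in which it carries a nonzero
#' loading in any component. Variables at or above `cutoff` are retained,
#' and the final fit is recomputed on the full data restricted to the
#' retained set.
#'
#' @param X Gene matrix (observations x variables).
#' @param Y Optional second block; when given the fit is [spls()],
#'   otherwise [spca()].
#' @param ncomp,keep Components and per-component cardinality of every fit
#'   (defaults 2 and 50).
#' @param n_boot Number of bootstrap resamples (default 50).
#' @param cutoff Minimum selection frequency to retain (default 0.1).
#' @param strata Optional per-observation labels; resampling is done within
#'   each stratum.
#' @param seed Optional RNG seed (scoped to this call).
#' @param count `"any_component"` (default: selected if nonzero in either
#'   component) or `"per_component"` (frequency denominator
#'   `n_boot * ncomp`).
#' @param ... Passed to the underlying fit (e.g. `scale`).
#' @return A `sparse_consolidation`: `selection_freq` tibble (`variable`,
#'   `freq`, `retained`), `retained` character vector, `final_fit` (sparse
#'   fit on the retained set), `params`.
#' @export
bootstrap_consolidate <- function(X, Y = NULL, ncomp = 2, keep = 50,
                                  n_boot = 50, cutoff = 0.1, strata = NULL,
                                  seed = NULL, count = c("any_component", "per_component"),
                                  ...) {
  count <- match.arg(count)
  X <- as_numeric_matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (!is.null(Y)) Y <- as_numeric_matrix(Y)
  if (n_boot < 1) abort("`n_boot` must be at least 1")
  n <- nrow(X)
  idx_pool <- if (is.null(strata)) list(seq_len(n)) else split(seq_len(n), strata)
  fit_once <- function(Xb, Yb) {
    kp <- min(keep, ncol(Xb))
    if (is.null(Yb)) spca(Xb, ncomp = ncomp, keep = kp, ...)
    else spls(Xb, Yb, ncomp = ncomp, keep_x = kp, ...)
  }
  counts <- numeric(ncol(X))
  hits <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      for (try in 1:20) {
        idx <- unlist(lapply(idx_pool, function(ii) ii[sample.int(length(ii), length(ii), replace = TRUE)]),
                      use.names = FALSE)
        Xb <- X[idx, , drop = FALSE]
        if (any(apply(Xb, 2, var) > 0)) break
      }
      fb <- suppressWarnings(fit_once(Xb, if (!is.null(Y)) Y[idx, , drop = FALSE]))
      nz <- abs(fb$loadings) > 0
      if (count == "any_component") {
        counts <- counts + (rowSums(nz) > 0)
      } else {
        counts <- counts + rowSums(nz)
      }
      hits <- hits + 1L
    }
  })
  denom <- if (count == "any_component") n_boot else n_boot * ncomp
  freq <- unname(counts / denom)
  # retained = ever-selected variables at or above the frequency cutoff
  retained <- colnames(X)[freq >= cutoff & freq > 0]
  final_fit <- if (length(retained)) {
    suppressWarnings(fit_once(X[, retained, drop = FALSE], Y))
  } else {
    warn("no variable reaches the selection-frequency cutoff")
    NULL
  }
  sel <- tibble::tibble(variable = colnames(X), freq = freq,
                        retained = freq >= cutoff)
  structure(list(selection_freq = sel, retained = retained,
                 final_fit = final_fit,
                 params = list(ncomp = ncomp, keep = keep, n_boot = n_boot,
                               cutoff = cutoff, seed = seed, count = count,
                               method = if (is.null(Y)) "spca" else "spls")),
            class = "sparse_consolidation")
}

#' @export
print.sparse_consolidation <- function(x, ...) {
  cat(sprintf("# Bootstrap-consolidated %s selection: %d/%d variables retained (cutoff %.2g, %d resamples)\n",
              toupper(x$params$method), length(x$retained),
              nrow(x$selection_freq), x$params$cutoff, x$params$n_boot))
  invisible(x)
}

#' @export
tidy.sparse_consolidation <- function(x, ...) x$selection_freq

#' @export
glance.sparse_consolidation <- function(x, ...) {
  tibble::tibble(
    n_variables = nrow(x$selection_freq),
    n_retained = length(x$retained),
    n_boot = x$params$n_boot,
    cutoff = x$params$cutoff,
    method = x$params$method
  )
}

#' @export
tidy.sparse_fit <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "variable") |>
    tidyr::pivot_longer(-"variable", names_to = "component",
                        values_to = "loading") |>
    dplyr::filter(.data$loading != 0)
}
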