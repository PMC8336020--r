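#' Regularized iterative PCA imputation
#'
#' Completes a matrix with missing entries by the regularized iterative PCA
#' (EM-PCA with shrinkage) algorithm: missing cells are initialised with
#' column means, then the algorithm alternates (1) column-centering of the
#' completed matrix, (2) truncated SVD at `ncomp`, (3) reconstruction with
#' shrunken singular values `d -> (d^2 - sigma2) / d`, where `sigma2` is the
#' mean of the trailing (residual) eigenvalues, and (4) restoration of the
#' observed entries, until the imputed cells change by less than `tol`
#' (root-mean-square). The shrinkage prevents overfitting the missing cells
#' when the signal-to-noise ratio is low. Observed entries are never
#' modified.
#'
#' @param X Numeric matrix (or data frame) with `NA`s to impute.
#' @param ncomp Number of components of the underlying signal (default 2);
#'   `ncomp = 0` returns the column-mean fill.
#' @param max_iter,tol Iteration cap and convergence tolerance on the change
#'   in imputed entries.
#' @return List of class `rpca_impute`: `completed` matrix, `n_iter`,
#'   `converged`, `ncomp`, `sigma2` (residual variance estimate at the last
#'   iteration).
#' @examples
#' X <- outer(1:6, c(2, 1, 3)) + 0
#' X[2, 1] <- NA
#' impute_regularized_pca(X, ncomp = 1)$completed[2, 1]
#' @export
impute_regularized_pca <- function(X, ncomp = 2, max_iter = 1000, tol = 1e-8) {
  X <- as_numeric_matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (ncomp >= min(n, p)) abort("`ncomp` must be smaller than both dimensions")
  miss <- is.na(X)
  if (any(rowSums(!miss) == 0)) abort("a row has no observed entry")
  if (any(colSums(!miss) == 0)) abort("a column has no observed entry")
  if (!any(miss)) {
    return(structure(list(completed = X, n_iter = 0L, converged = TRUE,
                          ncomp = ncomp, sigma2 = 0), class = "rpca_impute"))
  }
  mu0 <- colMeans(X, na.rm = TRUE)
  comp <- X
  comp[miss] <- matrix(mu0, n, p, byrow = TRUE)[miss]
  if (ncomp == 0) {
    return(structure(list(completed = comp, n_iter = 0L, converged = TRUE,
                          ncomp = 0L, sigma2 = mean((X - comp)^2, na.rm = TRUE)),
                     class = "rpca_impute"))
  }
  sigma2 <- 0
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    mu <- colMeans(comp)
    Xc <- sweep(comp, 2, mu)
    sv <- svd(Xc)
    ev <- sv$d^2
    r <- sum(ev > max(ev) * 1e-12)
    sigma2 <- if (r > ncomp) mean(ev[(ncomp + 1):r]) else 0
    ds <- pmax((sv$d[seq_len(ncomp)]^2 - sigma2) / sv$d[seq_len(ncomp)], 0)
    rec <- sv$u[, seq_len(ncomp), drop = FALSE] %*%
      (ds * t(sv$v[, seq_len(ncomp), drop = FALSE]))
    rec <- sweep(rec, 2, mu, "+")
    delta <- sqrt(mean((rec[miss] - comp[miss])^2))
    comp[miss] <- rec[miss]
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) {
      warn("regularized iterative PCA did not converge")
      break
    }
  }
  structure(list(completed = comp, n_iter = it, converged = converged,
                 ncomp = as.integer(ncomp), sigma2 = sigma2),
            class = "rpca_impute")
}

#' @export
print.rpca_impute <- function(x, ...) {
  cat(sprintf("# Regularized iterative PCA imputation: ncomp %d, %d iteration(s), %s\n",
              x$ncomp, x$n_iter, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Impute the metabolite columns of a metabolite table
#'
#' Convenience wrapper applying [impute_regularized_pca()] to the metabolite
#' block of a table (e.g. after CRLB filtering).
#'
#' @inheritParams impute_regularized_pca
#' @param table A [metabolite_table()].
#' @return The table with missing metabolite entries completed.
#' @export
impute_metabolites <- function(table, ncomp = 2, max_iter = 1000, tol = 1e-8) {
  vals <- metab_values(table)
  res <- impute_regularized_pca(vals, ncomp = ncomp, max_iter = max_iter, tol = tol)
  out <- metab_replace(table, res$completed)
  attr(out, "imputation") <- res[c("n_iter", "converged", "ncomp", "sigma2")]
  out
}
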