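#' Build a statistical triplet
#'
#' Every ordination in the package operates on a statistical triplet: a data
#' matrix `X` together with a diagonal row-weight metric (weights summing
#' to 1) and a diagonal column metric. Centering and unit-variance scaling
#' (both row-weighted) are applied at construction; metabolite tables are
#' scaled by default because metabolites live on heterogeneous scales.
#'
#' @param x Numeric matrix, data frame, or [metabolite_table()] (whose
#'   metabolite columns are used).
#' @param row_w Non-negative row weights (normalised to sum 1; default
#'   uniform).
#' @param col_w Positive column weights (default 1).
#' @param center,scale Row-weighted centering / unit-variance scaling.
#' @return A `triplet`: list with centered/scaled `X`, `row_w`, `col_w`, and
#'   the centering (`means`) and scaling (`sds`) vectors applied.
#' @export
as_triplet <- function(x, row_w = NULL, col_w = NULL,
                       center = TRUE, scale = FALSE) {
  X <- if (inherits(x, "metab_tbl")) metab_values(x) else as_numeric_matrix(x)
  if (anyNA(X)) abort("triplet input must be complete; impute first")
  n <- nrow(X); p <- ncol(X)
  row_w <- row_w %||% rep(1 / n, n)
  if (length(row_w) != n || any(row_w < 0)) abort("invalid row weights")
  row_w <- row_w / sum(row_w)
  col_w <- col_w %||% rep(1, p)
  if (length(col_w) != p || any(col_w <= 0)) abort("invalid column weights")
  means <- rep(0, p); sds <- rep(1, p)
  if (center) {
    means <- wcolmeans(X, row_w)
    X <- sweep(X, 2, means)
  }
  if (scale) {
    sds <- sqrt(wcolmeans(X^2, row_w))
    zero <- sds < .Machine$double.eps^0.5
    if (any(zero)) {
      abort(paste("constant column(s) cannot be scaled:",
                  toString(colnames(X)[zero] %||% which(zero))))
    }
    X <- sweep(X, 2, sds, "/")
  }
  structure(list(X = X, row_w = row_w, col_w = col_w,
                 means = means, sds = sds),
            class = "triplet")
}

#' @export
print.triplet <- function(x, ...) {
  cat(sprintf("# Statistical triplet: %d x %d, total inertia %.4g\n",
              nrow(x$X), ncol(x$X), total_inertia(x)))
  invisible(x)
}

#' Total inertia of a triplet
#'
#' Sum of column-weighted, row-weighted squared values — the total variance
#' the ordination decomposes.
#'
#' @param t A [as_triplet()] object.
#' @return Scalar inertia.
#' @export
total_inertia <- function(t) {
  sum(t$col_w * colSums(t$row_w * t$X^2))
}

#' PCA of a statistical triplet
#'
#' Generalized SVD of the triplet's matrix under its row and column metrics.
#' Axis orientation follows a fixed sign policy: each axis is flipped so
#' that its largest-magnitude loading is positive, making results
#' reproducible where figure orientation is arbitrary.
#'
#' @param t A [as_triplet()].
#' @param ncomp Number of components to return (default: full rank).
#' @return An `ordination`: `eigenvalues` (all, non-increasing, summing to
#'   the total inertia), `row_coords` (observation scores), `col_coords`
#'   (variable loadings, unit-norm in the column metric), `rank`.
#' @export
pca_triplet <- function(t, ncomp = NULL) {
  Xs <- sqrt(t$row_w) * sweep(t$X, 2, sqrt(t$col_w), "*")
  sv <- svd(Xs)
  ev <- sv$d^2
  rank <- sum(sv$d > max(sv$d, 0) * 1e-9)
  ncomp <- min(ncomp %||% rank, rank)
  A <- sweep(sv$v[, seq_len(ncomp), drop = FALSE], 1, sqrt(t$col_w), "/")
  A <- apply_sign_policy(A)
  scores <- t$X %*% (t$col_w * A)
  rownames(A) <- colnames(t$X)
  colnames(A) <- paste0("Axis", seq_len(ncomp))
  dimnames(scores) <- list(rownames(t$X), colnames(A))
  structure(list(eigenvalues = ev, row_coords = scores, col_coords = A,
                 rank = rank, ncomp = ncomp, total_inertia = total_inertia(t)),
            class = "ordination")
}

# Flip each column so its largest-|value| entry is positive.
apply_sign_policy <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("# Ordination: rank %d, first eigenvalues %s\n", x$rank,
              toString(signif(head(x$eigenvalues, 3), 4))))
  invisible(x)
}

#' Within-group (within-class) centering
#'
#' Subtracts the row-weighted group mean from each observation, removing the
#' effect of a nuisance grouping (e.g. the patient of origin of each
#' xenograft) before ordination. PCA of the centered triplet is the
#' within-group analysis (WCA).
#'
#' @param t A [as_triplet()].
#' @param groups Per-observation group labels.
#' @return A triplet of the within-group-centered matrix (same metrics).
#' @export
within_group_center <- function(t, groups) {
  groups <- as.factor(groups)
  if (length(groups) != nrow(t$X)) abort("one group label per observation required")
  gw <- as.numeric(rowsum(t$row_w, groups))
  gmean <- rowsum(t$row_w * t$X, groups) / gw
  Xw <- t$X - gmean[as.integer(groups), , drop = FALSE]
  dimnames(Xw) <- dimnames(t$X)
  out <- t
  out$X <- Xw
  out
}

# Between-group inertia of a (centered) triplet under a grouping.
between_group_inertia <- function(t, groups) {
  groups <- as.factor(groups)
  gw <- as.numeric(rowsum(t$row_w, groups))
  gmean <- rowsum(t$row_w * t$X, groups) / gw
  sum(t$col_w * colSums(gw * gmean^2))
}

#' Monte-Carlo test of the between-group inertia percentage
#'
#' The statistic is the share of total inertia carried by group means
#' (between-group inertia / total inertia). Its null distribution is built
#' by permuting the group labels; the p-value is
#' `(1 + #{perm >= obs}) / (n_perm + 1)`.
#'
#' @param t A [as_triplet()].
#' @param groups Per-observation group labels (at least 2 groups).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional RNG seed (scoped to this call).
#' @return Tibble with `percent_between` (in \[0,1\]), `p_value`, `n_perm`.
#' @export
between_group_inertia_test <- function(t, groups, n_perm = 999, seed = NULL) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) abort("need at least 2 groups")
  tot <- total_inertia(t)
  if (tot <= 0) {
    return(tibble::tibble(percent_between = 0, p_value = 1, n_perm = n_perm))
  }
  obs <- between_group_inertia(t, groups) / tot
  g <- as.integer(groups)
  perm_stats <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    between_group_inertia(t, g[sample.int(length(g))])
  }, numeric(1))) / tot
  p <- (1 + sum(perm_stats >= obs - 1e-12)) / (n_perm + 1)
  tibble::tibble(percent_between = obs, p_value = p, n_perm = n_perm)
}
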