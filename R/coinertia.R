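#' RV coefficient between two multivariate configurations
#'
#' Vectorial correlation between two column-centered matrices sharing rows:
#' `RV = tr(XX'YY') / sqrt(tr((XX')^2) tr((YY')^2))`, in \[0, 1\] for
#' centered data, 1 iff the two configurations are homothetic.
#'
#' @param X,Y Numeric matrices/data frames with the same rows; columns are
#'   centered internally.
#' @return Scalar RV.
#' @export
rv_coefficient <- function(X, Y) {
  X <- scale(as_numeric_matrix(X), scale = FALSE)
  Y <- scale(as_numeric_matrix(Y), scale = FALSE)
  if (nrow(X) != nrow(Y)) abort("X and Y must share rows")
  A <- tcrossprod(X); B <- tcrossprod(Y)
  da <- sum(A^2); db <- sum(B^2)
  if (da <= 0 || db <= 0) abort("zero-inertia block")
  sum(A * B) / sqrt(da * db)
}

#' Permutation test of the RV coefficient
#'
#' Permutes the rows of one block `n_perm` times and reports
#' `p = (1 + #{RV_perm >= RV_obs}) / (n_perm + 1)`.
#'
#' @inheritParams rv_coefficient
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional RNG seed (scoped to this call).
#' @param permute Which block's rows to permute (`"Y"`, the default — in
#'   practice the larger gene block; statistically symmetric).
#' @return Tibble with `rv`, `p_value`, `n_perm`.
#' @export
rv_permutation_test <- function(X, Y, n_perm = 999, seed = NULL,
                                permute = c("Y", "X")) {
  permute <- match.arg(permute)
  X <- scale(as_numeric_matrix(X), scale = FALSE)
  Y <- scale(as_numeric_matrix(Y), scale = FALSE)
  if (nrow(X) != nrow(Y)) abort("X and Y must share rows")
  A <- tcrossprod(X); B <- tcrossprod(Y)
  da <- sum(A^2); db <- sum(B^2)
  if (da <= 0 || db <= 0) abort("zero-inertia block")
  denom <- sqrt(da * db)
  obs <- sum(A * B) / denom
  P <- if (permute == "Y") B else A
  Q <- if (permute == "Y") A else B
  n <- nrow(A)
  stats <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    s <- sample.int(n)
    sum(P[s, s] * Q)
  }, numeric(1))) / denom
  p <- (1 + sum(stats >= obs - 1e-12)) / (n_perm + 1)
  tibble::tibble(rv = obs, p_value = p, n_perm = n_perm)
}

#' Coinertia analysis of two triplets sharing observations
#'
#' Couples a metabolite triplet and an expression triplet measured on the
#' same samples: the row-weighted cross table `Z = Y' D X` is decomposed by
#' SVD under the column metrics, yielding paired co-loading vectors that
#' maximise the covariance between block projections. Row scores place every
#' sample on matched metabolite and expression axes; the RV coefficient
#' summarises the global co-structure.
#'
#' @param tx,ty [as_triplet()] objects (or coercibles) with the same rows
#'   and row weights; `tx` is the X block (e.g. metabolites), `ty` the Y
#'   block (e.g. genes).
#' @param ncomp Number of coinertia axes (default 2).
#' @return A `coinertia` object: `singular_values` (all, non-increasing;
#'   their squares sum to the total coinertia), `x_loadings`, `y_loadings`,
#'   `x_row_scores`, `y_row_scores`, `rv`, `cross_table` (Y-variable by
#'   X-variable), `total_coinertia`.
#' @export
coinertia_fit <- function(tx, ty, ncomp = 2) {
  if (!inherits(tx, "triplet")) tx <- as_triplet(tx)
  if (!inherits(ty, "triplet")) ty <- as_triplet(ty)
  if (nrow(tx$X) != nrow(ty$X)) abort("blocks must share rows")
  if (max(abs(tx$row_w - ty$row_w)) > 1e-10) abort("blocks must share row weights")
  w <- tx$row_w
  Xs <- sweep(tx$X, 2, sqrt(tx$col_w), "*")
  Ys <- sweep(ty$X, 2, sqrt(ty$col_w), "*")
  Z <- crossprod(Ys, w * Xs)   # q x p, metric-standardized
  sv <- svd(Z)
  ncomp <- min(ncomp, sum(sv$d > max(sv$d, 0) * 1e-12))
  ax <- seq_len(ncomp)
  B <- sweep(sv$u[, ax, drop = FALSE], 1, sqrt(ty$col_w), "/")
  A <- sweep(sv$v[, ax, drop = FALSE], 1, sqrt(tx$col_w), "/")
  # joint sign policy: orient by the X block's largest loading
  for (j in ax) {
    i <- which.max(abs(A[, j]))
    if (A[i, j] < 0) { A[, j] <- -A[, j]; B[, j] <- -B[, j] }
  }
  dimnames(A) <- list(colnames(tx$X), paste0("Axis", ax))
  dimnames(B) <- list(colnames(ty$X), paste0("Axis", ax))
  xs <- tx$X %*% (tx$col_w * A)
  ys <- ty$X %*% (ty$col_w * B)
  cross <- crossprod(ty$X, w * tx$X)
  structure(list(singular_values = sv$d,
                 x_loadings = A, y_loadings = B,
                 x_row_scores = xs, y_row_scores = ys,
                 rv = rv_coefficient(sqrt(w) * Xs, sqrt(w) * Ys),
                 cross_table = cross,
                 total_coinertia = sum(Z^2), ncomp = ncomp),
            class = "coinertia")
}

#' @export
print.coinertia <- function(x, ...) {
  cat(sprintf("# Coinertia: %d axes kept, RV = %.3f, total coinertia %.4g\n",
              x$ncomp, x$rv, x$total_coinertia))
  invisible(x)
}

#' Tidy coinertia results
#'
#' @param x A [coinertia_fit()] object.
#' @param what `"scores"` (paired per-sample axis-1..k scores of both
#'   blocks), `"loadings"` (both blocks, long), or `"cross_table"` (long
#'   Y-variable by X-variable co-inertia entries).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.coinertia <- function(x, what = c("scores", "loadings", "cross_table"), ...) {
  what <- match.arg(what)
  if (what == "scores") {
    xs <- tibble::as_tibble(x$x_row_scores)
    names(xs) <- paste0("x_", names(xs))
    ys <- tibble::as_tibble(x$y_row_scores)
    names(ys) <- paste0("y_", names(ys))
    return(dplyr::bind_cols(tibble::tibble(row = seq_len(nrow(xs))), xs, ys))
  }
  if (what == "loadings") {
    lx <- tibble::as_tibble(x$x_loadings, rownames = "variable")
    lx$block <- "X"
    ly <- tibble::as_tibble(x$y_loadings, rownames = "variable")
    ly$block <- "Y"
    return(dplyr::bind_rows(lx, ly))
  }
  tibble::as_tibble(x$cross_table, rownames = "y_variable") |>
    tidyr::pivot_longer(-"y_variable", names_to = "x_variable",
                        values_to = "coinertia")
}

#' @export
glance.coinertia <- function(x, ...) {
  d2 <- x$singular_values^2
  tibble::tibble(rv = x$rv,
                 total_coinertia = x$total_coinertia,
                 axis1_share = d2[1] / sum(d2),
                 ncomp = x$ncomp)
}

#' Variation partitioning of a response among explanatory sets
#'
#' Decomposes the redundancy-analysis R-squared of a (possibly
#' multivariate) response into unique and shared "Venn" fractions over 2 or
#' 3 named sets of explanatory variables, by inclusion-exclusion over the
#' R-squared of every subset of sets. Factors are expanded to indicator
#' columns; rank-deficient designs are fit by pseudoinverse (with a
#' warning). Unadjusted fractions sum, with the residual, exactly to 1.
#'
#' @param response Numeric vector, matrix, or data frame (centered
#'   internally).
#' @param explanatory Named list of 2 or 3 explanatory sets, each a data
#'   frame / matrix / vector.
#' @param adjust Use Ezekiel-adjusted R-squared (default `FALSE`; adjusted
#'   fractions can be slightly negative).
#' @return A `varpart_result`: tibble `fractions` (`fraction`, `value`) with
#'   one row per Venn region plus `residual`, and `combined` (the full-model
#'   R-squared).
#' @export
variation_partition <- function(response, explanatory, adjust = FALSE) {
  Y <- scale(as_numeric_matrix(response), scale = FALSE)
  if (is.null(names(explanatory)) || any(names(explanatory) == "")) {
    abort("`explanatory` must be a named list")
  }
  m <- length(explanatory)
  if (m < 2 || m > 3) abort("2 or 3 explanatory sets supported")
  mats <- lapply(explanatory, expand_predictors)
  n <- nrow(Y)
  ssy <- sum(Y^2)
  if (ssy <= 0) abort("response has zero variance")
  r2 <- function(sets) {
    if (!length(sets)) return(0)
    X <- do.call(cbind, mats[sets])
    X <- scale(X, scale = FALSE)
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    if (sum(pos) < ncol(X)) warn("collinear predictors: least squares via pseudoinverse")
    U <- sv$u[, pos, drop = FALSE]
    fit <- U %*% crossprod(U, Y)
    raw <- sum(fit^2) / ssy
    if (adjust) 1 - (1 - raw) * (n - 1) / (n - sum(pos) - 1) else raw
  }
  nm <- names(explanatory)
  if (m == 2) {
    rA <- r2(nm[1]); rB <- r2(nm[2]); rAB <- r2(nm)
    fr <- c(rAB - rB, rA + rB - rAB, rAB - rA)
    names(fr) <- c(nm[1], paste(nm[1], nm[2], sep = "&"), nm[2])
    resid <- 1 - rAB
    combined <- rAB
  } else {
    rA <- r2(nm[1]); rB <- r2(nm[2]); rC <- r2(nm[3])
    rAB <- r2(nm[1:2]); rAC <- r2(nm[c(1, 3)]); rBC <- r2(nm[2:3])
    rABC <- r2(nm)
    # unique, pairwise-shared and triple-shared fractions (inclusion-exclusion)
    a <- rABC - rBC
    b <- rABC - rAC
    c_ <- rABC - rAB
    ab <- rAC + rBC - rC - rABC
    ac <- rAB + rBC - rB - rABC
    bc <- rAB + rAC - rA - rABC
    abc <- rA + rB + rC - rAB - rAC - rBC + rABC
    fr <- c(a, b, c_, ab, ac, bc, abc)
    names(fr) <- c(nm,
                   paste(nm[1], nm[2], sep = "&"),
                   paste(nm[1], nm[3], sep = "&"),
                   paste(nm[2], nm[3], sep = "&"),
                   paste(nm, collapse = "&"))
    resid <- 1 - rABC
    combined <- rABC
  }
  structure(list(
    fractions = tibble::tibble(fraction = c(names(fr), "residual"),
                               value = c(unname(fr), resid)),
    combined = combined, adjust = adjust
  ), class = "varpart_result")
}

expand_predictors <- function(x) {
  df <- as.data.frame(x)
  mm <- model.matrix(~ . - 1, data = df)
  storage.mode(mm) <- "double"
  mm
}

#' @export
print.varpart_result <- function(x, ...) {
  cat(sprintf("# Variation partitioning (%s R2): combined %.3f\n",
              if (x$adjust) "adjusted" else "unadjusted", x$combined))
  print(x$fractions)
  invisible(x)
}

#' @export
tidy.varpart_result <- function(x, ...) x$fractions

#' @export
glance.varpart_result <- function(x, ...) {
  tibble::tibble(combined = x$combined,
                 residual = x$fractions$value[x$fractions$fraction == "residual"],
                 adjusted = x$adjust)
}

#' Consensus k-means clustering
#'
#' Runs k-means `n_rep` times from distinct k-means++ initialisations, forms
#' the consensus matrix of pairwise co-assignment frequencies, and cuts the
#' average-linkage hierarchy of `1 - consensus` into `k` final clusters.
#'
#' @param X Item-by-feature matrix (items are clustered).
#' @param k Number of clusters (default 3).
#' @param n_rep Number of k-means repetitions (default 100).
#' @param seed Optional RNG seed (scoped to this call).
#' @return A `consensus_clust`: `labels` (named integer vector),
#'   `consensus` (symmetric item-by-item co-assignment matrix), `k`,
#'   `n_rep`.
#' @export
consensus_kmeans <- function(X, k = 3, n_rep = 100, seed = NULL) {
  X <- as_numeric_matrix(X)
  n <- nrow(X)
  if (k > n) abort("`k` exceeds the number of items")
  if (k == 1) {
    lab <- setNames(rep(1L, n), rownames(X))
    return(structure(list(labels = lab,
                          consensus = matrix(1, n, n, dimnames = list(rownames(X), rownames(X))),
                          k = 1L, n_rep = n_rep), class = "consensus_clust"))
  }
  co <- matrix(0, n, n)
  with_seed(seed, {
    for (r in seq_len(n_rep)) {
      centers <- kmeanspp_centers(X, k)
      cl <- suppressWarnings(kmeans(X, centers = centers, iter.max = 50))$cluster
      co <- co + outer(cl, cl, `==`)
    }
  })
  consensus <- co / n_rep
  dimnames(consensus) <- list(rownames(X), rownames(X))
  hc <- hclust(as.dist(1 - consensus), method = "average")
  labels <- cutree(hc, k = k)
  structure(list(labels = labels, consensus = consensus, k = as.integer(k),
                 n_rep = n_rep, hclust = hc),
            class = "consensus_clust")
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance to the nearest chosen center.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(X, 2, X[idx[1], ])^2)
  for (j in seq_len(k - 1)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx[j + 1] <- sample.int(n, 1, prob = probs)
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx[j + 1], ])^2))
  }
  X[idx, , drop = FALSE] + matrix(rnorm(k * ncol(X), 0, 1e-10), k)
}

#' @export
print.consensus_clust <- function(x, ...) {
  cat(sprintf("# Consensus k-means: k = %d over %d repetitions; cluster sizes %s\n",
              x$k, x$n_rep, toString(table(x$labels))))
  invisible(x)
}

#' @export
tidy.consensus_clust <- function(x, ...) {
  tibble::tibble(item = names(x$labels) %||% as.character(seq_along(x$labels)),
                 cluster = unname(x$labels))
}

#' Ward-linkage leaf orders for heatmap display
#'
#' Euclidean-distance, Ward-linkage dendrogram leaf orders for the rows and
#' columns of a matrix — the standard ordering for expression/co-inertia
#' heatmaps.
#'
#' @param X Numeric matrix.
#' @return List with integer vectors `rows` and `cols` (permutations).
#' @export
ward_heatmap_order <- function(X) {
  X <- as_numeric_matrix(X)
  ord <- function(M) {
    if (nrow(M) < 3) return(seq_len(nrow(M)))
    hclust(dist(M), method = "ward.D2")$order
  }
  list(rows = ord(X), cols = ord(t(X)))
}
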