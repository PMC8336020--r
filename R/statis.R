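#' STATIS: compromise analysis of K tables sharing variables
#'
#' STATIS analyzes several data tables measured on the same variables (here:
#' one metabolite table per mouse, rows = scans; or one per patient, rows =
#' voxels). Each table k is summarised by its variable-space inertia
#' operator `C_k = X_k' D_k X_k` (Frobenius-normalised so no table dominates
#' by scale). The *interstructure* is the matrix of RV coefficients between
#' operators; its first eigenvector (non-negative by Perron-Frobenius) gives
#' the table weights `alpha`. The *compromise* `C = sum alpha_k C_k` is
#' eigen-decomposed into consensus metabolite loadings, and the
#' *intrastructure* projects every table's rows onto the compromise axes,
#' putting all mice (or all voxels of all patients) on one common axis
#' system.
#'
#' @param tables List of [as_triplet()] objects (or objects coercible via
#'   `as_triplet`) with identical ordered variables.
#' @param ncomp Number of compromise axes to keep (default 2).
#' @param center,scale Passed to `as_triplet` for inputs that are not yet
#'   triplets.
#' @return A `statis` object: `rv_matrix` (K x K interstructure),
#'   `table_weights` (sum 1), `compromise_eigenvalues`,
#'   `compromise_loadings` (variable by axis), `per_table_row_coords` (list
#'   of row-score matrices), `grand_mean`, `variables`, `tables`.
#' @export
statis_fit <- function(tables, ncomp = 2, center = TRUE, scale = FALSE) {
  if (length(tables) < 2) abort("STATIS needs at least 2 tables")
  tables <- lapply(tables, function(x) {
    if (inherits(x, "triplet")) x else as_triplet(x, center = center, scale = scale)
  })
  vars <- lapply(tables, function(t) colnames(t$X))
  if (is.null(vars[[1]])) {
    p <- vapply(tables, function(t) ncol(t$X), integer(1))
    if (length(unique(p)) > 1) abort("tables differ in variable count")
    variables <- paste0("V", seq_len(p[1]))
  } else {
    ok <- vapply(vars, identical, logical(1), y = vars[[1]])
    if (!all(ok)) {
      bad <- which(!ok)[1]
      abort(paste0("table ", bad, " variables differ from table 1: ",
                   toString(union(setdiff(vars[[bad]], vars[[1]]),
                                  setdiff(vars[[1]], vars[[bad]])))))
    }
    variables <- vars[[1]]
  }
  ops <- lapply(tables, function(t) {
    Xs <- sweep(t$X, 2, sqrt(t$col_w), "*")
    C <- crossprod(sqrt(t$row_w) * Xs)
    nf <- sqrt(sum(C^2))
    if (nf <= 0) abort("a table has zero inertia")
    C / nf
  })
  K <- length(ops)
  rv <- diag(1, K)
  for (j in seq_len(K)) for (k in seq_len(K)) {
    if (k > j) rv[j, k] <- rv[k, j] <- sum(ops[[j]] * ops[[k]])
  }
  # leading eigenvector of the (non-negative) RV matrix by power iteration
  # from the uniform start: non-negative by Perron-Frobenius, and the
  # uniform vector is returned when tables are mutually orthogonal (the
  # degenerate case where the leading eigenspace is not unique)
  a <- rep(1 / sqrt(K), K)
  for (i in 1:200) {
    a_new <- as.numeric(rv %*% a)
    a_new <- a_new / sqrt(sum(a_new^2))
    if (max(abs(a_new - a)) < 1e-12) { a <- a_new; break }
    a <- a_new
  }
  a <- pmax(a, 0)
  alpha <- a / sum(a)
  C <- Reduce(`+`, Map(`*`, ops, alpha))
  ec <- eigen(C, symmetric = TRUE)
  ncomp <- min(ncomp, sum(ec$values > max(ec$values) * 1e-9))
  V <- apply_sign_policy(ec$vectors[, seq_len(ncomp), drop = FALSE])
  # back to original variable scale under the (shared) column metric
  col_w <- tables[[1]]$col_w
  A <- sweep(V, 1, sqrt(col_w), "/")
  rownames(A) <- variables
  colnames(A) <- paste0("Axis", seq_len(ncomp))
  coords <- lapply(tables, function(t) {
    s <- t$X %*% (col_w * A)
    dimnames(s) <- list(rownames(t$X), colnames(A))
    s
  })
  centers <- vapply(tables, function(t) t$means, numeric(length(variables)))
  grand_mean <- rowMeans(matrix(centers, ncol = K))
  names(grand_mean) <- variables
  structure(list(
    rv_matrix = rv, table_weights = alpha,
    compromise_eigenvalues = ec$values,
    compromise_loadings = A,
    per_table_row_coords = coords,
    grand_mean = grand_mean, variables = variables,
    tables = tables, ncomp = ncomp,
    scale = scale, center = center
  ), class = "statis")
}

#' @export
print.statis <- function(x, ...) {
  cat(sprintf("# STATIS compromise of %d tables (%d variables, %d axes)\n",
              length(x$tables), length(x$variables), x$ncomp))
  cat("  table weights:", toString(signif(x$table_weights, 3)), "\n")
  invisible(x)
}

#' Orient the first compromise axis as a tumor axis
#'
#' The compromise axes have arbitrary sign. For metabolite data the field
#' convention is that high axis-1 values mean "more tumoral": N-acetyl
#' aspartate (NAA), the canonical neuronal/normal-brain marker, decreases
#' with tumor burden, so axis 1 is flipped (loadings and all row scores)
#' until the marker's loading is negative.
#'
#' @param res A [statis_fit()] object.
#' @param marker Variable whose axis-1 loading must be negative (default
#'   `"NAA"`); silently left unchanged when absent.
#' @param axis Axis to orient (default 1).
#' @return The (possibly flipped) `statis` object.
#' @export
orient_tumor_axis <- function(res, marker = "NAA", axis = 1) {
  if (!marker %in% res$variables) return(res)
  if (res$compromise_loadings[marker, axis] > 0) {
    res$compromise_loadings[, axis] <- -res$compromise_loadings[, axis]
    res$per_table_row_coords <- lapply(res$per_table_row_coords, function(s) {
      s[, axis] <- -s[, axis]
      s
    })
  }
  res
}

#' Project observations onto STATIS compromise axes
#'
#' Scores new (or fitted) observations on the compromise axes: the table is
#' centered (by its own column means, by the fit's grand mean, or not at
#' all) and multiplied by the compromise loadings under the column metric.
#' Used e.g. to score held-out contralateral series on axes fitted to all
#' measurements.
#'
#' @param res A [statis_fit()] object.
#' @param table Matrix, data frame, [metabolite_table()], or triplet with
#'   the fitted variables.
#' @param axes Which axes to return (default all fitted).
#' @param center `"table"` (own column means; matches the fitted tables'
#'   coordinates), `"grand"` (the fit's grand mean; an observation equal to
#'   it scores 0), or `"none"`.
#' @return Matrix of per-observation scores.
#' @export
project_rows <- function(res, table, axes = NULL,
                         center = c("table", "grand", "none")) {
  center <- match.arg(center)
  X <- if (inherits(table, "triplet")) {
    table$X
  } else if (inherits(table, "metab_tbl")) {
    metab_values(table)
  } else {
    as_numeric_matrix(table)
  }
  if (ncol(X) != length(res$variables)) {
    abort(sprintf("variable mismatch: table has %d variables, fit has %d",
                  ncol(X), length(res$variables)))
  }
  if (!is.null(colnames(X)) && !identical(colnames(X), res$variables)) {
    missing_v <- setdiff(res$variables, colnames(X))
    if (length(missing_v)) abort(paste("variables absent:", toString(missing_v)))
    X <- X[, res$variables, drop = FALSE]
  }
  if (!inherits(table, "triplet")) {
    if (center == "table") {
      X <- sweep(X, 2, colMeans(X))
    } else if (center == "grand") {
      X <- sweep(X, 2, res$grand_mean)
    }
    if (isTRUE(res$scale)) {
      # apply the average fitted scaling so new tables are comparable
      sds <- rowMeans(vapply(res$tables, function(t) t$sds,
                             numeric(length(res$variables))))
      X <- sweep(X, 2, sds, "/")
    }
  }
  axes <- axes %||% seq_len(res$ncomp)
  A <- res$compromise_loadings[, axes, drop = FALSE]
  X %*% (res$tables[[1]]$col_w * A)
}

#' Tidy STATIS results
#'
#' @param x A [statis_fit()] object.
#' @param what `"scores"` (per-table row coordinates, long),
#'   `"loadings"` (variable loadings), or `"weights"` (table weights).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.statis <- function(x, what = c("scores", "loadings", "weights"), ...) {
  what <- match.arg(what)
  if (what == "loadings") {
    out <- tibble::as_tibble(x$compromise_loadings, rownames = "variable")
  } else if (what == "weights") {
    out <- tibble::tibble(table = seq_along(x$table_weights),
                          weight = x$table_weights)
  } else {
    out <- purrr::imap_dfr(x$per_table_row_coords, function(s, i) {
      dplyr::mutate(tibble::as_tibble(s), table = i,
                    row = seq_len(nrow(s)), .before = 1)
    })
  }
  out
}

#' @export
glance.statis <- function(x, ...) {
  ev <- x$compromise_eigenvalues
  tibble::tibble(
    n_tables = length(x$tables),
    n_variables = length(x$variables),
    axis1_share = ev[1] / sum(pmax(ev, 0)),
    axis2_share = if (length(ev) > 1) ev[2] / sum(pmax(ev, 0)) else NA_real_,
    min_rv = min(x$rv_matrix),
    ncomp = x$ncomp
  )
}
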