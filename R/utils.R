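# Internal helpers shared across modules.

# Known metadata column names for metabolite tables; everything else is
# treated as a metabolite value column.
.meta_cols <- c(
  "subject", "mouse", "side", "time_days",
  "voxel_row", "voxel_col", "sample", "patient"
)

#' Metabolite columns of a metabolite table
#'
#' @param x A metabolite table (tibble): metadata columns first, then one
#'   numeric column per metabolite.
#' @return Character vector of metabolite column names.
#' @export
metabolite_names <- function(x) {
  mets <- attr(x, "metabolites")
  if (!is.null(mets)) return(intersect(mets, names(x)))
  setdiff(names(x), .meta_cols)
}

# Extract the numeric value matrix of a metabolite table.
metab_values <- function(x) {
  mets <- metabolite_names(x)
  m <- as.matrix(x[, mets, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

# Replace metabolite columns of `x` with the columns of matrix `m`
# (may have fewer columns than before).
metab_replace <- function(x, m) {
  meta <- x[, intersect(names(x), .meta_cols), drop = FALSE]
  out <- dplyr::bind_cols(meta, tibble::as_tibble(m))
  attr(out, "crlb") <- attr(x, "crlb")
  attr(out, "metabolites") <- colnames(m)
  class(out) <- class(x)
  out
}

# Seed scoping: run `expr` under `seed` (if non-NULL) without disturbing
# the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a 32-bit child seed from a master seed and a stream index.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 1009L + as.integer(stream) * 9973L) %% 2147483629L
}

# Weighted column means (weights sum to 1).
wcolmeans <- function(X, w) as.numeric(crossprod(w, X))

stopifnot_matrix <- function(X, arg = "X") {
  if (!is.matrix(X) || !is.numeric(X)) {
    abort(paste0("`", arg, "` must be a numeric matrix"))
  }
}

as_numeric_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[vapply(x, is.numeric, logical(1))])
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1)
  storage.mode(x) <- "double"
  x
}
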