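#' Build a mixed-species count matrix
#'
#' Container for gene-by-sample raw RNA-seq counts from xenograft tissue in
#' which reads have already been classified by species of origin. Each gene
#' carries a label in `human`, `mouse`, `ambiguous`; each sample carries
#' metadata (subject of origin, tissue type, ...).
#'
#' @param counts Non-negative integer gene-by-sample matrix with rownames
#'   (gene ids) and colnames (sample ids), or a data frame with columns
#'   `gene_id`, `species`, then one column per sample.
#' @param species Per-gene label in `human`/`mouse`/`ambiguous` (ignored when
#'   `counts` is a data frame carrying it).
#' @param sample_meta Optional tibble of per-sample metadata with a `sample`
#'   column matching `colnames(counts)`; typical columns are `subject` and
#'   `type` (one of `injected`, `contralateral`, `human_tumor`, `mock_brain`).
#' @return A `count_mat` object: list of `counts`, `species`, `samples`
#'   (metadata tibble including `lib_size`).
#' @export
count_matrix <- function(counts, species = NULL, sample_meta = NULL) {
  if (is.data.frame(counts)) {
    df <- counts
    if (!all(c("gene_id", "species") %in% names(df))) {
      abort("data-frame input needs `gene_id` and `species` columns")
    }
    species <- df$species
    counts <- as.matrix(df[, setdiff(names(df), c("gene_id", "species")), drop = FALSE])
    rownames(counts) <- df$gene_id
  }
  stopifnot_matrix(counts, "counts")
  if (nrow(counts) > 0 && is.null(rownames(counts))) {
    abort("`counts` needs gene ids as rownames")
  }
  if (anyDuplicated(rownames(counts))) abort("gene ids must be unique")
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be non-negative integers")
  }
  if (is.null(species)) species <- rep("human", nrow(counts))
  species <- as.character(species)
  if (length(species) != nrow(counts)) abort("one species label per gene required")
  bad <- setdiff(unique(species), c("human", "mouse", "ambiguous"))
  if (length(bad)) abort(paste("unknown species labels:", toString(bad)))
  samples <- tibble::tibble(sample = colnames(counts) %||%
                              paste0("S", seq_len(ncol(counts))))
  if (!is.null(sample_meta)) {
    sample_meta <- tibble::as_tibble(sample_meta)
    if (!"sample" %in% names(sample_meta)) abort("`sample_meta` needs a `sample` column")
    samples <- dplyr::left_join(samples, sample_meta, by = "sample")
  }
  samples$lib_size <- as.numeric(colSums(counts))
  structure(list(counts = counts, species = species, samples = samples),
            class = "count_mat")
}

#' @export
print.count_mat <- function(x, ...) {
  tab <- table(factor(x$species, c("human", "mouse", "ambiguous")))
  cat(sprintf("# Count matrix: %d genes x %d samples (human %d, mouse %d, ambiguous %d)\n",
              nrow(x$counts), ncol(x$counts), tab[1], tab[2], tab[3]))
  invisible(x)
}

#' @export
dim.count_mat <- function(x) dim(x$counts)

#' Tidy a count matrix into long form
#'
#' @param x A [count_matrix()].
#' @param ... Unused.
#' @return Tibble with columns `gene_id`, `species`, `sample`, `count`.
#' @export
tidy.count_mat <- function(x, ...) {
  tibble::tibble(
    gene_id = rep(rownames(x$counts), ncol(x$counts)),
    species = rep(x$species, ncol(x$counts)),
    sample = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.vector(x$counts)
  )
}

#' Read a count table (and sidecar sample metadata) from TSV
#'
#' The count TSV has columns `gene_id`, `species`, then one column per
#' sample; the optional sidecar TSV has a `sample` column plus metadata.
#'
#' @param file Count TSV path.
#' @param sample_file Optional sample-metadata TSV path.
#' @return A [count_matrix()].
#' @export
read_counts <- function(file, sample_file = NULL) {
  df <- readr::read_tsv(file, show_col_types = FALSE, progress = FALSE)
  meta <- if (!is.null(sample_file)) {
    readr::read_tsv(sample_file, show_col_types = FALSE, progress = FALSE)
  }
  count_matrix(df, sample_meta = meta)
}

#' Write a count matrix to TSV
#'
#' @param x A [count_matrix()].
#' @param file Count TSV path; sample metadata goes to `<stem>.samples.tsv`.
#' @return `x`, invisibly.
#' @export
write_counts <- function(x, file) {
  df <- dplyr::bind_cols(
    tibble::tibble(gene_id = rownames(x$counts), species = x$species),
    tibble::as_tibble(x$counts)
  )
  readr::write_tsv(df, file, progress = FALSE)
  readr::write_tsv(x$samples, sub("(\\.tsv)$", ".samples\\1", file),
                   progress = FALSE)
  invisible(x)
}

#' TMM scaling factors
#'
#' Trimmed-mean-of-M-values between-sample normalization factors
#' (Robinson & Oshlack), computed via edgeR: the reference sample is the one
#' whose 75th-percentile count fraction is closest to the mean; per-gene
#' log-ratios M and average log-abundances A are doubly trimmed
#' (`trim_m` on M, `trim_a` on A) and combined by a weighted mean with
#' inverse asymptotic (binomial) variance weights; factors are rescaled to
#' geometric mean 1.
#'
#' @param counts A [count_matrix()] or a counts matrix.
#' @param trim_m,trim_a Trim fractions for log-ratios and log-abundances.
#' @return Named numeric vector of positive per-sample factors.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  m <- if (inherits(counts, "count_mat")) counts$counts else counts
  if (ncol(m) < 2) abort("TMM needs at least 2 samples")
  if (any(colSums(m) <= 0)) abort("every sample needs positive total counts")
  f <- edgeR::calcNormFactors(m, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  if (any(!is.finite(f))) abort("TMM failed: sample shares no positive genes with the reference")
  setNames(as.numeric(f), colnames(m))
}

#' Log-CPM normalization
#'
#' `log2((count + pseudocount) / (lib_size * factor) * 1e6)`: counts scaled
#' to effective library size (library size times TMM factor), per million,
#' log2 with a pseudocount guarding zeros.
#'
#' @param counts A [count_matrix()] or counts matrix.
#' @param factors Per-sample positive scaling factors (default: all 1).
#' @param pseudocount Added to every count before the log (default 0.5).
#' @return Object of class `norm_expr`: list with `values` (gene-by-sample
#'   log2-CPM matrix), `norm_factors`, `offset` (the pseudocount), and the
#'   sample metadata when available.
#' @export
log_normalize <- function(counts, factors = NULL, pseudocount = 0.5) {
  m <- if (inherits(counts, "count_mat")) counts$counts else counts
  lib <- colSums(m)
  if (is.null(factors)) factors <- rep(1, ncol(m))
  if (length(factors) != ncol(m) || any(factors <= 0)) {
    abort("`factors` must be positive, one per sample")
  }
  eff <- lib * factors
  if (any(eff <= 0)) abort("non-positive effective library size")
  vals <- log2(sweep(m + pseudocount, 2, eff, "/") * 1e6)
  structure(list(values = vals, norm_factors = factors, offset = pseudocount,
                 samples = if (inherits(counts, "count_mat")) counts$samples,
                 species = if (inherits(counts, "count_mat")) counts$species),
            class = "norm_expr")
}

#' @export
print.norm_expr <- function(x, ...) {
  cat(sprintf("# Normalized expression (log2-CPM): %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Remove low-count and ambiguous genes
#'
#' Keeps genes reaching `min_cpm` counts-per-million in at least
#' `min_fraction_samples` of the samples; genes labelled `ambiguous` by the
#' read classifier are always dropped.
#'
#' @param counts A [count_matrix()].
#' @param min_cpm CPM threshold (default 1).
#' @param min_fraction_samples Fraction of samples that must reach it
#'   (default 0.25).
#' @return A filtered [count_matrix()].
#' @export
filter_low_counts <- function(counts, min_cpm = 1, min_fraction_samples = 0.25) {
  if (min_cpm < 0 || min_fraction_samples < 0 || min_fraction_samples > 1) {
    abort("thresholds out of range")
  }
  cpm <- sweep(counts$counts, 2, colSums(counts$counts), "/") * 1e6
  ok_expr <- rowMeans(cpm >= min_cpm) >= min_fraction_samples
  keep <- ok_expr & counts$species != "ambiguous"
  if (!any(keep)) abort("no genes survive the low-count filter; relax `min_cpm`")
  count_matrix(counts$counts[keep, , drop = FALSE], counts$species[keep],
               counts$samples[setdiff(names(counts$samples), "lib_size")])
}

#' Split a mixed-species count matrix by species
#'
#' @param counts A [count_matrix()].
#' @return List with `human` and `mouse` count matrices (ambiguous genes
#'   dropped, sample metadata preserved) and `fraction_human_reads`, the
#'   per-sample human total over human + mouse total.
#' @export
partition_species <- function(counts) {
  meta <- counts$samples[setdiff(names(counts$samples), "lib_size")]
  pick <- function(sp) {
    keep <- counts$species == sp
    count_matrix(counts$counts[keep, , drop = FALSE],
                 counts$species[keep], meta)
  }
  human <- pick("human")
  mouse <- pick("mouse")
  ht <- colSums(human$counts)
  mt <- colSums(mouse$counts)
  frac <- ht / (ht + mt)
  human$samples$fraction_human_reads <- frac
  mouse$samples$fraction_human_reads <- frac
  list(human = human, mouse = mouse,
       fraction_human_reads = setNames(frac, counts$samples$sample))
}

#' Drop samples with too few reads
#'
#' Applied to the mouse partition: samples whose total is strictly below
#' `min_reads` (default one million) are excluded, and the exclusions are
#' reported.
#'
#' @param counts A [count_matrix()] (typically the mouse partition).
#' @param min_reads Minimum total read count per sample (default `1e6`).
#' @return A [count_matrix()] without the low-coverage samples.
#' @export
exclude_low_read_samples <- function(counts, min_reads = 1e6) {
  tot <- colSums(counts$counts)
  drop <- tot < min_reads
  if (any(drop)) {
    inform(sprintf("excluding %d sample(s) with < %g reads: %s",
                   sum(drop), min_reads,
                   toString(colnames(counts$counts)[drop])))
  }
  count_matrix(counts$counts[, !drop, drop = FALSE], counts$species,
               counts$samples[!drop, setdiff(names(counts$samples), "lib_size")])
}
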