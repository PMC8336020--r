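#' Build a metabolite table
#'
#' A metabolite table is a tibble with one row per observation (one MRS scan
#' of one voxel or one hemisphere at one timepoint) carrying metadata columns
#' (any of `subject`, `mouse`, `side`, `time_days`, `voxel_row`, `voxel_col`,
#' `sample`) followed by one numeric column per metabolite. An optional
#' parallel matrix of Cramer-Rao lower bounds (CRLB, in percent) of the same
#' observation-by-metabolite shape is attached as the `"crlb"` attribute and
#' drives quality filtering.
#'
#' @param data Data frame of metadata plus metabolite columns.
#' @param crlb Optional data frame or matrix of CRLB percentages, one column
#'   per metabolite column of `data`, same row count.
#' @param metabolites Character vector naming the metabolite columns; by
#'   default every column not recognised as metadata.
#' @return A `metab_tbl`: a tibble with attributes `metabolites` and `crlb`.
#' @examples
#' tb <- metabolite_table(
#'   data.frame(subject = "P1", side = "injected", time_days = 42,
#'              NAA = 8, Cr = 4, PCr = 4),
#'   crlb = data.frame(NAA = 5, Cr = 4, PCr = 6)
#' )
#' metabolite_names(tb)
#' @export
metabolite_table <- function(data, crlb = NULL, metabolites = NULL) {
  out <- tibble::as_tibble(data)
  if (is.null(metabolites)) metabolites <- setdiff(names(out), .meta_cols)
  if (anyDuplicated(metabolites)) abort("metabolite names must be unique")
  bad <- metabolites[!vapply(out[metabolites], is.numeric, logical(1))]
  if (length(bad)) abort(paste("non-numeric metabolite columns:", toString(bad)))
  if ("time_days" %in% names(out) && any(out$time_days < 0, na.rm = TRUE)) {
    abort("`time_days` must be non-negative")
  }
  if (!is.null(crlb)) {
    crlb <- as.matrix(as.data.frame(crlb)[, metabolites, drop = FALSE])
    if (nrow(crlb) != nrow(out)) abort("`crlb` must have one row per observation")
    storage.mode(crlb) <- "double"
  }
  attr(out, "metabolites") <- metabolites
  attr(out, "crlb") <- crlb
  class(out) <- c("metab_tbl", class(out))
  out
}

#' Read a metabolite table from TSV/CSV
#'
#' Expects observations in rows: metadata columns (`subject`, `side`,
#' `time_days` or `voxel_row`/`voxel_col`, ...) followed by metabolite
#' columns. If a sibling file `<stem>.crlb.<ext>` exists (or `crlb_file` is
#' given) it is read as the parallel CRLB matrix.
#'
#' @param file Path to a delimited file (delimiter sniffed from extension).
#' @param crlb_file Optional explicit path to the CRLB table.
#' @return A [metabolite_table()].
#' @export
read_metabolite_table <- function(file, crlb_file = NULL) {
  read_fun <- if (grepl("\\.csv$", file)) readr::read_csv else readr::read_tsv
  data <- read_fun(file, show_col_types = FALSE, progress = FALSE)
  if (is.null(crlb_file)) {
    guess <- sub("(\\.[ct]sv)$", ".crlb\\1", file)
    if (guess != file && file.exists(guess)) crlb_file <- guess
  }
  crlb <- NULL
  if (!is.null(crlb_file)) {
    crlb_raw <- read_fun(crlb_file, show_col_types = FALSE, progress = FALSE)
    mets <- setdiff(names(data), .meta_cols)
    crlb <- crlb_raw[, mets, drop = FALSE]
  }
  metabolite_table(data, crlb = crlb)
}

#' Write a metabolite table (and its CRLB matrix) to TSV
#'
#' @param x A [metabolite_table()].
#' @param file Output path; the CRLB matrix, if present, goes to
#'   `<stem>.crlb.tsv`.
#' @return `x`, invisibly.
#' @export
write_metabolite_table <- function(x, file) {
  readr::write_tsv(tibble::as_tibble(as.data.frame(x)), file, progress = FALSE)
  crlb <- attr(x, "crlb")
  if (!is.null(crlb)) {
    readr::write_tsv(tibble::as_tibble(as.data.frame(crlb)),
                     sub("(\\.[ct]sv)$", ".crlb\\1", file), progress = FALSE)
  }
  invisible(x)
}

#' Exclude poorly quantified entries by CRLB
#'
#' LCModel reports a Cramer-Rao lower bound for every fitted metabolite;
#' large CRLB means unreliable quantification. Entries with CRLB strictly
#' above `threshold_percent` are set to `NA` (mode `"exclude_entry"`, the
#' per-scan rule used for mouse spectra with threshold 40), or whole
#' metabolites are dropped when any of their entries exceeds the threshold
#' (mode `"exclude_metabolite"`, the patient-table rule at threshold 50).
#' Retained values are never altered.
#'
#' @param table A [metabolite_table()] with a CRLB attribute.
#' @param threshold_percent Positive CRLB threshold in percent; strictly
#'   greater values are excluded.
#' @param mode `"exclude_entry"` or `"exclude_metabolite"`.
#' @return A new metabolite table with exclusions applied as `NA` (or columns
#'   dropped); metadata untouched.
#' @export
filter_by_crlb <- function(table, threshold_percent,
                           mode = c("exclude_entry", "exclude_metabolite")) {
  mode <- match.arg(mode)
  crlb <- attr(table, "crlb")
  if (is.null(crlb)) abort("CRLB filter inapplicable: table has no CRLB matrix")
  if (!is.numeric(threshold_percent) || threshold_percent <= 0) {
    abort("`threshold_percent` must be positive")
  }
  vals <- metab_values(table)
  bad <- !is.na(crlb) & crlb > threshold_percent
  if (mode == "exclude_entry") {
    vals[bad] <- NA_real_
    out <- metab_replace(table, vals)
    attr(out, "crlb") <- crlb
  } else {
    keep <- colSums(bad) == 0
    out <- metab_replace(table, vals[, keep, drop = FALSE])
    attr(out, "crlb") <- crlb[, keep, drop = FALSE]
  }
  out
}

#' Express metabolites as ratios to a reference pool
#'
#' Divides every metabolite by the per-observation sum of the reference
#' components — canonically total creatine, tCr = Cr + PCr — the internal
#' reference used for in vivo MRS when water scaling is unavailable.
#' Observations whose reference sum is zero or missing get all-missing
#' ratios, with a warning reporting how many.
#'
#' @param table A [metabolite_table()].
#' @param reference_components Metabolite names summed into the reference
#'   (default `c("Cr", "PCr")`).
#' @param drop_reference Drop the reference metabolites from the output
#'   (default `TRUE`); keep them (as ratios) to mirror figure axes that show
#'   all measured metabolites.
#' @return A metabolite table of ratios.
#' @export
ratio_to_reference <- function(table, reference_components = c("Cr", "PCr"),
                               drop_reference = TRUE) {
  mets <- metabolite_names(table)
  missing_ref <- setdiff(reference_components, mets)
  if (length(missing_ref)) {
    abort(paste("reference components absent:", toString(missing_ref)))
  }
  vals <- metab_values(table)
  ref <- rowSums(vals[, reference_components, drop = FALSE])
  bad <- !is.finite(ref) | ref <= 0
  ref[bad] <- NA_real_
  out_vals <- vals / ref
  if (any(bad)) {
    warn(sprintf("%d observation(s) with zero/missing reference: ratios set missing",
                 sum(bad)))
  }
  if (drop_reference) {
    out_vals <- out_vals[, setdiff(mets, reference_components), drop = FALSE]
  }
  out <- metab_replace(table, out_vals)
  crlb <- attr(table, "crlb")
  if (!is.null(crlb)) attr(out, "crlb") <- crlb[, colnames(out_vals), drop = FALSE]
  out
}

#' @export
print.metab_tbl <- function(x, ...) {
  mets <- metabolite_names(x)
  cat(sprintf("# Metabolite table: %d observations x %d metabolites%s\n",
              nrow(x), length(mets),
              if (is.null(attr(x, "crlb"))) "" else " (with CRLB)"))
  NextMethod()
}
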