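#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param file Path to a `.gmt` file.
#' @return Named list of character vectors (one per gene set).
#' @export
read_gmt <- function(file) {
  fgsea::gmtPathways(file)
}

#' Map mixed-species gene symbols to human symbols
#'
#' Mouse symbols are translated through a two-column homolog table; human
#' symbols pass through unchanged; unmapped mouse symbols are dropped (with
#' a count reported). When a mouse gene and its human homolog are both
#' present, they collapse to a single output symbol carrying both species
#' flags.
#'
#' @param genes Tibble/data frame with columns `gene` and `species`
#'   (`human`/`mouse`), or a character vector (assumed human).
#' @param mapping Two-column data frame of mouse symbol, human symbol (in
#'   that order, any column names).
#' @return Tibble with `human_gene`, `from_human`, `from_mouse`.
#' @export
map_homologs <- function(genes, mapping = NULL) {
  if (is.character(genes)) {
    genes <- tibble::tibble(gene = genes, species = "human")
  }
  genes <- tibble::as_tibble(genes)
  if (!all(c("gene", "species") %in% names(genes))) {
    abort("`genes` needs `gene` and `species` columns")
  }
  has_mouse <- any(genes$species == "mouse")
  if (has_mouse && (is.null(mapping) || nrow(mapping) == 0)) {
    abort("mouse genes present but the homolog mapping is empty")
  }
  hum <- dplyr::filter(genes, .data$species == "human") |>
    dplyr::transmute(human_gene = .data$gene, from_human = TRUE, from_mouse = FALSE)
  mou <- dplyr::filter(genes, .data$species == "mouse")
  if (nrow(mou)) {
    map <- tibble::as_tibble(as.data.frame(mapping)[, 1:2])
    names(map) <- c("mouse_gene", "human_gene")
    mou2 <- dplyr::inner_join(mou, map, by = c(gene = "mouse_gene"),
                              relationship = "many-to-many")
    n_drop <- length(setdiff(mou$gene, map$mouse_gene))
    if (n_drop) inform(sprintf("%d mouse symbol(s) without homolog dropped", n_drop))
    mou <- dplyr::transmute(mou2, human_gene = .data$human_gene,
                            from_human = FALSE, from_mouse = TRUE)
  } else {
    mou <- hum[0, ]
  }
  dplyr::bind_rows(hum, mou) |>
    dplyr::summarise(from_human = any(.data$from_human),
                     from_mouse = any(.data$from_mouse),
                     .by = "human_gene")
}

#' Hypergeometric gene-set enrichment with Bonferroni control
#'
#' For each gene set, tests over-representation of the selected genes in
#' the set within the chosen universe by the upper-tail hypergeometric
#' probability `P(overlap >= x)` with universe size `N`, set size `K`
#' (after intersection with the universe) and selection size `n`. Sets with
#' no overlap are excluded from testing, and the Bonferroni divisor is the
#' number of sets actually tested. Sets with adjusted p at or below `alpha`
#' are flagged significant.
#'
#' @param selected Character vector of selected genes (must lie in
#'   `universe`).
#' @param universe Character vector: all genes that entered the analysis.
#' @param collections Named list of gene sets (see [read_gmt()]) or a GMT
#'   path.
#' @param alpha Significance threshold on the adjusted p (default 0.1).
#' @param species Optional named character vector (or tibble from
#'   [map_homologs()]) giving each gene's species of origin, used to report
#'   the human fraction of each overlap.
#' @param adjust `"bonferroni"` (default) or `"BH"`.
#' @param min_overlap Minimum overlap for a set to be tested (default 1).
#' @return Tibble with one row per tested set: `set_name`, `N`, `K`, `n`,
#'   `x`, `p`, `p_adj`, `significant`, `gene_ratio`, `fraction_human`,
#'   `overlapping_genes` (list column).
#' @export
hypergeom_enrichment <- function(selected, universe, collections, alpha = 0.1,
                                 species = NULL,
                                 adjust = c("bonferroni", "BH"),
                                 min_overlap = 1) {
  adjust <- match.arg(adjust)
  if (is.character(collections) && length(collections) == 1 &&
      file.exists(collections)) {
    collections <- read_gmt(collections)
  }
  selected <- unique(selected)
  universe <- unique(universe)
  stray <- setdiff(selected, universe)
  if (length(stray)) {
    abort(paste("selected genes outside the universe:", toString(head(stray, 10))))
  }
  N <- length(universe)
  n <- length(selected)
  rows <- purrr::imap(collections, function(set, nm) {
    set_u <- intersect(unique(set), universe)
    K <- length(set_u)
    ov <- intersect(selected, set_u)
    x <- length(ov)
    if (K == 0 || x < min_overlap) return(NULL)
    tibble::tibble(set_name = nm, N = N, K = K, n = n, x = x,
                   p = phyper(x - 1, K, N - K, n, lower.tail = FALSE),
                   gene_ratio = x / n,
                   fraction_human = fraction_human(ov, species),
                   overlapping_genes = list(ov))
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(out)
  m <- nrow(out)
  out$p_adj <- if (adjust == "bonferroni") pmin(1, out$p * m) else p.adjust(out$p, "BH")
  out$significant <- out$p_adj <= alpha
  dplyr::arrange(
    dplyr::relocate(out, "p_adj", "significant", .after = "p"),
    .data$p
  )
}

fraction_human <- function(genes, species) {
  if (is.null(species) || !length(genes)) return(NA_real_)
  if (is.data.frame(species)) {
    hum <- species$human_gene[species$from_human]
    return(mean(genes %in% hum))
  }
  mean(species[genes] == "human")
}
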