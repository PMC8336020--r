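# End-to-end workflow drivers. Each takes a config list (defaults filled by
# the corresponding *_config() helper), runs the stages in order with
# stage-level logging, optionally writes every artifact (plus a manifest)
# to `out_dir`, and returns a report object of tibbles. A single master
# seed drives every stochastic stage through derived child seeds, so a
# rerun with the same config is bit-identical.

fill_config <- function(config, defaults) {
  utils::modifyList(defaults, config %||% list())
}

stage_log <- function(log, stage, n_in, n_out, note = "") {
  dplyr::bind_rows(log, tibble::tibble(stage = stage, n_in = n_in,
                                       n_out = n_out, note = note))
}

write_report <- function(tables, out_dir, config, log) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables)) {
    readr::write_tsv(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                     progress = FALSE)
  }
  manifest <- tibble::tibble(
    artifact = names(tables),
    rows = vapply(tables, nrow, integer(1)),
    hash = vapply(tables, rlang::hash, character(1))
  )
  manifest$config_hash <- rlang::hash(config)
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"), progress = FALSE)
  readr::write_tsv(log, file.path(out_dir, "stages.tsv"), progress = FALSE)
  invisible(NULL)
}

#' Default configuration for the trajectory workflow
#'
#' @param seed Master seed.
#' @param ... Overrides of any default field.
#' @return Config list.
#' @export
trajectory_config <- function(seed = 1, ...) {
  utils::modifyList(list(
    seed = seed,
    crlb_max = 40,
    reference = c("Cr", "PCr"),
    drop_reference = FALSE,
    impute_ncomp = 2,
    statis_ncomp = 2,
    scale = TRUE,
    mvs_crlb_max = 50,
    mvs_patients = list(
      list(subject = "P1", tumor_center = c(2, 2), tumor_radius = 1.5),
      list(subject = "P12", tumor_center = c(4, 4), tumor_radius = 1.2),
      list(subject = "P14", tumor_center = c(3, 2), tumor_radius = 1.8)
    ),
    longitudinal = list(),
    out_dir = NULL
  ), list(...))
}

#' Trajectory workflow: STATIS of longitudinal and multi-voxel MRS
#'
#' CRLB filter, tCr ratio, regularized-PCA imputation, then STATIS with one
#' table per mouse (longitudinal scans) giving per-observation axis-1
#' tumor-axis scores and metabolite loadings; the same machinery runs on
#' per-patient multi-voxel grids, and the two analyses' axis-1 loadings are
#' correlated (Spearman) over the common metabolites.
#'
#' @param config See [trajectory_config()]; `config$data` may carry a
#'   pre-built longitudinal table (`data$longitudinal`, with truth in
#'   `data$longitudinal_truth`) to analyze instead of simulating.
#' @return A `trajectory_report`: `scores`, `loadings`, `mvs_scores`,
#'   `mvs_loadings`, `loading_correlation`, `truth`, `stage_log`.
#' @export
run_trajectory_analysis <- function(config = trajectory_config()) {
  cfg <- fill_config(config, trajectory_config())
  log <- tibble::tibble()
  # -- longitudinal arm -------------------------------------------------
  if (!is.null(cfg$data$longitudinal)) {
    tab <- cfg$data$longitudinal
    truth <- cfg$data$longitudinal_truth
  } else {
    sim <- do.call(simulate_longitudinal,
                   utils::modifyList(cfg$longitudinal,
                                     list(seed = child_seed(cfg$seed, 1))))
    tab <- sim$table; truth <- sim$truth
  }
  n0 <- nrow(tab)
  tab <- filter_by_crlb(tab, cfg$crlb_max, mode = "exclude_entry")
  log <- stage_log(log, "crlb_filter", n0, nrow(tab),
                   sprintf("threshold %g%%", cfg$crlb_max))
  tab <- ratio_to_reference(tab, cfg$reference,
                            drop_reference = cfg$drop_reference)
  log <- stage_log(log, "tcr_ratio", nrow(tab), nrow(tab),
                   toString(cfg$reference))
  tab <- impute_metabolites(tab, ncomp = cfg$impute_ncomp)
  log <- stage_log(log, "imputation", nrow(tab), nrow(tab),
                   sprintf("ncomp %d", cfg$impute_ncomp))
  mets <- metabolite_names(tab)
  tabs <- split(tibble::as_tibble(as.data.frame(tab)), tab$mouse)
  triplets <- lapply(tabs, function(d) {
    as_triplet(as.matrix(d[, mets]), scale = cfg$scale)
  })
  fit <- orient_tumor_axis(statis_fit(triplets, ncomp = cfg$statis_ncomp))
  scores <- purrr::imap_dfr(fit$per_table_row_coords, function(s, nm) {
    dplyr::bind_cols(tabs[[nm]][, intersect(names(tabs[[nm]]), .meta_cols)],
                     tibble::as_tibble(s))
  })
  loadings <- tidy(fit, "loadings")
  log <- stage_log(log, "statis", nrow(scores), nrow(loadings),
                   sprintf("%d tables", length(triplets)))
  # -- multi-voxel arm --------------------------------------------------
  mvs_tabs <- list()
  for (i in seq_along(cfg$mvs_patients)) {
    p <- cfg$mvs_patients[[i]]
    simv <- do.call(simulate_mvs,
                    utils::modifyList(p, list(seed = child_seed(cfg$seed, 10 + i))))
    tv <- filter_by_crlb(simv$table, cfg$mvs_crlb_max, mode = "exclude_entry")
    tv <- filter_missing_metabolites(tv, 0.5)
    mvs_tabs[[p$subject]] <- tv
  }
  common_mets <- Reduce(intersect, lapply(mvs_tabs, metabolite_names))
  mvs_trip <- lapply(mvs_tabs, function(tv) {
    v <- impute_regularized_pca(metab_values(tv)[, common_mets, drop = FALSE],
                                ncomp = cfg$impute_ncomp)$completed
    as_triplet(v, scale = cfg$scale)
  })
  mvs_fit <- orient_tumor_axis(statis_fit(mvs_trip, ncomp = cfg$statis_ncomp))
  mvs_scores <- purrr::imap_dfr(mvs_fit$per_table_row_coords, function(s, nm) {
    dplyr::bind_cols(mvs_tabs[[nm]][, intersect(names(mvs_tabs[[nm]]), .meta_cols)],
                     tibble::as_tibble(s))
  })
  mvs_loadings <- tidy(mvs_fit, "loadings")
  log <- stage_log(log, "mvs_statis", nrow(mvs_scores), nrow(mvs_loadings),
                   sprintf("%d patients", length(mvs_tabs)))
  # -- cross-domain loading correlation (common metabolites) ------------
  shared <- intersect(loadings$variable, mvs_loadings$variable)
  ct <- suppressWarnings(cor.test(
    loadings$Axis1[match(shared, loadings$variable)],
    mvs_loadings$Axis1[match(shared, mvs_loadings$variable)],
    method = "spearman"))
  loading_correlation <- tibble::tibble(
    n_common = length(shared), spearman = unname(ct$estimate),
    p_value = ct$p.value)
  log <- stage_log(log, "cross_correlation", length(shared), 1,
                   sprintf("rho %.3f", loading_correlation$spearman))
  report <- structure(list(
    scores = scores, loadings = loadings,
    mvs_scores = mvs_scores, mvs_loadings = mvs_loadings,
    loading_correlation = loading_correlation,
    truth = truth, statis = fit, mvs_statis = mvs_fit,
    stage_log = log, config = cfg
  ), class = "trajectory_report")
  write_report(list(scores = scores, loadings = loadings,
                    mvs_scores = mvs_scores, mvs_loadings = mvs_loadings,
                    loading_correlation = loading_correlation),
               cfg$out_dir, cfg, log)
  report
}

#' @export
print.trajectory_report <- function(x, ...) {
  cat("# Trajectory workflow report\n")
  cat(sprintf("  %d scored observations, %d metabolite loadings\n",
              nrow(x$scores), nrow(x$loadings)))
  cat(sprintf("  cross-domain loading Spearman: %.3f (n = %d)\n",
              x$loading_correlation$spearman, x$loading_correlation$n_common))
  invisible(x)
}

#' Default configuration for the integration workflow
#'
#' @inheritParams trajectory_config
#' @return Config list.
#' @export
integration_config <- function(seed = 1, ...) {
  utils::modifyList(list(
    seed = seed,
    crlb_max = 40,
    reference = c("Cr", "PCr"),
    drop_reference = FALSE,
    impute_ncomp = 2,
    min_cpm = 1, min_fraction_samples = 0.25,
    keep = 50, ncomp = 2, n_boot = 50, cutoff = 0.1,
    n_perm = 999,
    alpha = 0.1,
    longitudinal = list(),
    counts = list(),
    out_dir = NULL
  ), list(...))
}

#' Integration workflow: WCA, sparse PLS, coinertia, enrichment
#'
#' Links end-stage metabolite profiles (last scan of each mouse, both
#' sides) to expression: TMM/log-CPM normalization, within-group centering
#' of expression by subject (removing tumor-origin effects), sparse PLS
#' gene selection consolidated by bootstrap, coinertia of the metabolite
#' block with the retained genes, RV coefficient with permutation test, and
#' hypergeometric enrichment of the retained set.
#'
#' @param config See [integration_config()]; `config$data` may carry
#'   `metabolites` (last-scan table), `counts` (a [count_matrix()]),
#'   `truth`, and `gene_sets`.
#' @return An `integration_report`: `selection`, `retained`, `coinertia`
#'   (fit), `rv_test`, `enrichment`, `sensitivity`, `truth`, `stage_log`.
#' @export
run_integration_analysis <- function(config = integration_config()) {
  cfg <- fill_config(config, integration_config())
  log <- tibble::tibble()
  # -- inputs -----------------------------------------------------------
  if (!is.null(cfg$data$metabolites)) {
    last <- cfg$data$metabolites
    truth_m <- cfg$data$truth
  } else {
    sim <- do.call(simulate_longitudinal,
                   utils::modifyList(cfg$longitudinal,
                                     list(seed = child_seed(cfg$seed, 1))))
    tab <- sim$table; truth_m <- sim$truth
    last <- dplyr::slice_max(tibble::as_tibble(as.data.frame(tab)),
                             .data$time_days, n = 1,
                             by = c("subject", "mouse", "side"))
    keep_rows <- match(paste(last$mouse, last$side, last$time_days),
                       paste(tab$mouse, tab$side, tab$time_days))
    last <- metabolite_table(last, crlb = attr(tab, "crlb")[keep_rows, , drop = FALSE])
  }
  last <- filter_by_crlb(last, cfg$crlb_max)
  last <- ratio_to_reference(last, cfg$reference, drop_reference = cfg$drop_reference)
  # metabolites mostly lost to the CRLB rule carry no usable information
  last <- filter_missing_metabolites(last, 0.5)
  last <- impute_metabolites(last, ncomp = cfg$impute_ncomp)
  log <- stage_log(log, "metabolite_prep", nrow(last), nrow(last), "")
  samples <- paste0(last$mouse, "_", substr(last$side, 1, 4))
  if (!is.null(cfg$data$counts)) {
    cm <- cfg$data$counts
    truth_c <- cfg$data$truth_counts %||% cfg$data$truth
  } else {
    bt <- truth_m$burden
    key <- paste(bt$mouse, bt$side, bt$time_days)
    lk <- paste(last$mouse, last$side, last$time_days)
    burden <- bt$burden[match(lk, key)]
    simc <- do.call(simulate_coupled_counts,
                    utils::modifyList(cfg$counts, list(
                      scores = burden, subjects = last$subject,
                      types = last$side, sample_ids = samples,
                      seed = child_seed(cfg$seed, 2))))
    cm <- simc$counts; truth_c <- simc$truth
  }
  # -- expression prep --------------------------------------------------
  n_g0 <- nrow(cm$counts)
  cm <- filter_low_counts(cm, cfg$min_cpm, cfg$min_fraction_samples)
  log <- stage_log(log, "count_filter", n_g0, nrow(cm$counts), "low counts + ambiguous")
  fac <- tmm_factors(cm)
  expr <- log_normalize(cm, fac)
  E <- t(expr$values)   # samples x genes
  if (!setequal(rownames(E), samples)) {
    abort(paste("sample mismatch between blocks:",
                toString(union(setdiff(rownames(E), samples),
                               setdiff(samples, rownames(E))))))
  }
  E <- E[samples, , drop = FALSE]
  tE <- within_group_center(as_triplet(E), last$subject)
  log <- stage_log(log, "wca", nrow(E), nrow(E), "subject effects removed")
  # -- sparse PLS + bootstrap ------------------------------------------
  M <- metab_values(last)
  sel <- bootstrap_consolidate(tE$X, M, ncomp = cfg$ncomp, keep = cfg$keep,
                               n_boot = cfg$n_boot, cutoff = cfg$cutoff,
                               strata = last$subject,
                               seed = child_seed(cfg$seed, 3))
  log <- stage_log(log, "spls_bootstrap", ncol(tE$X), length(sel$retained),
                   sprintf("cutoff %g", cfg$cutoff))
  # -- coinertia + RV ---------------------------------------------------
  tm <- as_triplet(M, scale = TRUE)
  tg <- tE
  keep_g <- match(sel$retained, colnames(tE$X))
  tg$X <- tg$X[, keep_g, drop = FALSE]
  tg$col_w <- tg$col_w[keep_g]
  tg$means <- tg$means[keep_g]
  tg$sds <- tg$sds[keep_g]
  coi <- coinertia_fit(tm, tg, ncomp = 2)
  rvt <- rv_permutation_test(tm$X, tg$X, n_perm = cfg$n_perm,
                             seed = child_seed(cfg$seed, 4))
  log <- stage_log(log, "coinertia", nrow(M), length(sel$retained),
                   sprintf("RV %.3f p %.4g", rvt$rv, rvt$p_value))
  # -- enrichment -------------------------------------------------------
  universe <- colnames(tE$X)
  sets <- cfg$data$gene_sets %||%
    synthetic_gene_sets(truth_c, universe, seed = child_seed(cfg$seed, 5))
  sp <- setNames(cm$species, rownames(cm$counts))
  enr <- hypergeom_enrichment(sel$retained, universe, sets,
                              alpha = cfg$alpha, species = sp)
  log <- stage_log(log, "enrichment", length(sets), nrow(enr),
                   sprintf("%d significant", sum(enr$significant)))
  active <- unlist(truth_c$active_genes, use.names = FALSE)
  active <- intersect(active, universe)
  sensitivity <- if (length(active)) mean(active %in% sel$retained) else NA_real_
  report <- structure(list(
    selection = sel$selection_freq, retained = sel$retained,
    consolidation = sel, coinertia = coi, rv_test = rvt,
    enrichment = enr, sensitivity = sensitivity,
    metabolites = last, expression = E,
    truth = truth_c, stage_log = log, config = cfg
  ), class = "integration_report")
  write_report(list(selection = sel$selection_freq,
                    rv_test = rvt,
                    enrichment = dplyr::select(enr, -"overlapping_genes"),
                    coinertia_scores = tidy(coi, "scores")),
               cfg$out_dir, cfg, log)
  report
}

#' @export
print.integration_report <- function(x, ...) {
  cat("# Integration workflow report\n")
  cat(sprintf("  %d genes retained; RV = %.3f (p = %.4g); sensitivity %.2f\n",
              length(x$retained), x$rv_test$rv, x$rv_test$p_value,
              x$sensitivity))
  invisible(x)
}

#' Default configuration for the invaded-brain workflow
#'
#' @inheritParams trajectory_config
#' @return Config list.
#' @export
mouse_brain_config <- function(seed = 1, ...) {
  utils::modifyList(list(
    seed = seed,
    min_mouse_reads = 1e6,
    min_cpm = 1, min_fraction_samples = 0.25,
    keep = 50, ncomp = 2, n_boot = 50, cutoff = 0.1,
    k = 3, n_rep = 100,
    alpha = 0.1,
    longitudinal = list(),
    counts = list(compact_subjects = "P3"),
    out_dir = NULL
  ), list(...))
}

#' Invaded-brain workflow: mouse reads, sparse PCA, clustering, varpart
#'
#' Analyzes the host response: the mouse partition of the counts (samples
#' under the minimum mouse-read threshold excluded), TMM/log-CPM, sparse
#' PCA gene selection with bootstrap, consensus k-means of the selected
#' genes, per-cluster variation partitioning of the cluster's mean
#' expression over the human-read fraction (numeric), sample origin and
#' tissue type, and per-cluster enrichment.
#'
#' @param config See [mouse_brain_config()]; `config$data` may carry
#'   `counts` (a mixed-species [count_matrix()]), `truth` and `gene_sets`.
#' @return A `mouse_brain_report`: `selection`, `retained`, `clusters`,
#'   `varpart` (per-cluster), `enrichment` (per-cluster), `excluded_samples`,
#'   `stage_log`.
#' @export
run_mouse_brain_analysis <- function(config = mouse_brain_config()) {
  cfg <- fill_config(config, mouse_brain_config())
  log <- tibble::tibble()
  if (!is.null(cfg$data$counts)) {
    cm <- cfg$data$counts
    truth_c <- cfg$data$truth
  } else {
    sim <- do.call(simulate_longitudinal,
                   utils::modifyList(cfg$longitudinal,
                                     list(seed = child_seed(cfg$seed, 1))))
    bt <- dplyr::slice_max(sim$truth$burden, .data$time_days, n = 1,
                           by = c("subject", "mouse", "side"))
    # one mock-injected brain alongside the PDOX samples
    scores <- c(bt$burden, 0)
    subjects <- c(bt$subject, "mock")
    types <- c(bt$side, "mock_brain")
    ids <- c(paste0(bt$mouse, "_", substr(bt$side, 1, 4)), "mB")
    simc <- do.call(simulate_coupled_counts,
                    utils::modifyList(cfg$counts, list(
                      scores = scores, subjects = subjects, types = types,
                      sample_ids = ids, seed = child_seed(cfg$seed, 2))))
    cm <- simc$counts; truth_c <- simc$truth
  }
  parts <- partition_species(cm)
  mouse <- parts$mouse
  n_s0 <- ncol(mouse$counts)
  mouse <- exclude_low_read_samples(mouse, cfg$min_mouse_reads)
  excluded <- setdiff(cm$samples$sample, mouse$samples$sample)
  log <- stage_log(log, "mouse_partition", n_s0, ncol(mouse$counts),
                   sprintf("excluded: %s", toString(excluded)))
  mouse <- filter_low_counts(mouse, cfg$min_cpm, cfg$min_fraction_samples)
  expr <- log_normalize(mouse, tmm_factors(mouse))
  E <- t(expr$values)
  log <- stage_log(log, "normalize", nrow(E), ncol(E), "TMM + log-CPM")
  sel <- bootstrap_consolidate(E, ncomp = cfg$ncomp, keep = cfg$keep,
                               n_boot = cfg$n_boot, cutoff = cfg$cutoff,
                               strata = mouse$samples$subject,
                               seed = child_seed(cfg$seed, 3))
  log <- stage_log(log, "spca_bootstrap", ncol(E), length(sel$retained), "")
  # genes x samples, each gene's profile standardized across samples
  G <- t(scale(E[, sel$retained, drop = FALSE]))
  cl <- consensus_kmeans(G, k = cfg$k, n_rep = cfg$n_rep,
                         seed = child_seed(cfg$seed, 4))
  log <- stage_log(log, "consensus_kmeans", nrow(G), cfg$k, "")
  meta <- mouse$samples
  expl <- list(FreqHum = meta$fraction_human_reads,
               Origin = factor(meta$subject),
               Type = factor(meta$type))
  vp <- purrr::map_dfr(sort(unique(cl$labels)), function(k) {
    genes_k <- names(cl$labels)[cl$labels == k]
    resp <- rowMeans(E[, genes_k, drop = FALSE])
    v <- variation_partition(resp, expl)
    dplyr::mutate(v$fractions, cluster = k, combined = v$combined, .before = 1)
  })
  universe <- colnames(E)
  sets <- cfg$data$gene_sets %||%
    synthetic_gene_sets(truth_c, universe, seed = child_seed(cfg$seed, 5))
  enr <- purrr::map_dfr(sort(unique(cl$labels)), function(k) {
    genes_k <- names(cl$labels)[cl$labels == k]
    e <- hypergeom_enrichment(genes_k, universe, sets, alpha = cfg$alpha)
    if (nrow(e)) dplyr::mutate(e, cluster = k, .before = 1) else e
  })
  log <- stage_log(log, "varpart_enrichment", cfg$k, nrow(vp), "")
  report <- structure(list(
    selection = sel$selection_freq, retained = sel$retained,
    clusters = tidy(cl), consensus = cl,
    varpart = vp, enrichment = enr,
    excluded_samples = excluded,
    samples = meta, expression = E,
    truth = truth_c, stage_log = log, config = cfg
  ), class = "mouse_brain_report")
  write_report(list(selection = sel$selection_freq, clusters = tidy(cl),
                    varpart = vp,
                    enrichment = if (nrow(enr)) dplyr::select(enr, -"overlapping_genes") else enr),
               cfg$out_dir, cfg, log)
  report
}

#' @export
print.mouse_brain_report <- function(x, ...) {
  cat("# Invaded-brain workflow report\n")
  cat(sprintf("  %d mouse genes retained in %d clusters; %d sample(s) excluded\n",
              length(x$retained), max(x$clusters$cluster),
              length(x$excluded_samples)))
  invisible(x)
}
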