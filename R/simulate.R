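# Named metabolite panels matching the in vivo MRS figure legends: 21
# metabolites quantified in mice at 14.1 T, 16 in patient multi-voxel
# spectroscopy at 7 T; 13 are common once Cr/PCr serve as the tCr reference.

#' Metabolite panels of the simulated study
#'
#' @return Character vector of metabolite names.
#' @export
mouse_metabolite_panel <- function() {
  c("NAA", "NAAG", "Glu", "Gln", "GPC", "PCho", "Glc", "Gly", "Ins",
    "Cr", "PCr", "Lac", "GSH", "Tau", "Ala", "Asp", "Asc", "PE", "Ace",
    "GABA", "Mac")
}

#' @rdname mouse_metabolite_panel
#' @export
patient_metabolite_panel <- function() {
  c("NAA", "NAAG", "Glu", "Gln", "GPC", "PCho", "Gly", "Ins", "Lac",
    "GSH", "Tau", "PE", "GABA", "Lip09", "Lip13", "Lip20")
}

# Baseline concentrations (mM-like, healthy rodent brain order of
# magnitude) and the signed tumor signature: growth and invasion decrease
# neuronal markers (NAA, NAAG, Glu, GABA) and raise cell-turnover markers
# (choline compounds, Ins, Gly, Lac, Gln).
metab_baseline <- function(panel) {
  base <- c(NAA = 8.5, NAAG = 0.6, Glu = 9, Gln = 3, GPC = 0.6, PCho = 0.4,
            Glc = 2, Gly = 0.8, Ins = 5.5, Cr = 4.2, PCr = 3.8, Lac = 1.5,
            GSH = 1.1, Tau = 6, Ala = 0.5, Asp = 2.5, Asc = 1.5, PE = 1.5,
            Ace = 0.3, GABA = 1.8, Mac = 4,
            Lip09 = 0.4, Lip13 = 0.5, Lip20 = 0.3)
  base[panel]
}

#' Signed tumor-burden signature over a metabolite panel
#'
#' Relative change of each metabolite at full tumor burden: negative for
#' neuronal markers, positive for proliferation/turnover markers.
#'
#' @param panel Metabolite names.
#' @return Named numeric vector in roughly \[-1, 1\].
#' @export
tumor_signature <- function(panel = mouse_metabolite_panel()) {
  sig <- c(NAA = -1.0, NAAG = -0.5, Glu = -0.7, Gln = 0.5, GPC = 0.9,
           PCho = 0.5, Glc = -0.3, Gly = 0.8, Ins = 0.7, Cr = -0.15,
           PCr = 0.15, Lac = 0.6, GSH = 0.2, Tau = 0.3, Ala = 0.2,
           Asp = -0.3, Asc = -0.2, PE = 0.4, Ace = 0.05, GABA = -0.6,
           Mac = 0.3, Lip09 = 0.8, Lip13 = 0.9, Lip20 = 0.7)
  sig[panel]
}

# Draw CRLB percentages as the relative quantification uncertainty:
# absolute fitting noise over the fitted value, so low-concentration
# metabolites quantify worse — the usual LCModel behavior.
draw_crlb <- function(values, noise_sd) {
  sigma <- (noise_sd + 0.02) * rlnorm(length(values), 0, 0.3)
  crlb <- 100 * sigma / pmax(abs(values), 0.05)
  matrix(pmin(crlb, 999), nrow(values), ncol(values),
         dimnames = dimnames(values))
}

#' Simulate longitudinal PDOX metabolite profiles
#'
#' Emulates the mouse arm of the study: per subject (patient of origin), a
#' handful of mice are scanned every one to two weeks on the injected and
#' contralateral sides. Tumor burden follows a logistic growth curve
#' `plogis(rate * (t - t_mid))`; the contralateral side lags and is
#' attenuated (invasion). Each scan's profile is
#' `baseline * (1 + effect_scale * burden * signature)` plus additive
#' fitting noise in concentration units; CRLB values are drawn as the
#' relative uncertainty (noise over value), so low-concentration
#' metabolites exceed the quality threshold and the filter has work to do. A
#' subject with `growth_rate = 0` never develops a tumor (burden
#' identically 0), mirroring the non-engrafting IDH-mutant case.
#'
#' @param n_subjects Number of patients of origin (default 5; the last has
#'   growth rate 0 by default).
#' @param n_mice_per_subject Mice per subject (default 3).
#' @param timepoints Scan days post injection (default days 28-112, step
#'   14).
#' @param growth_rates Per-subject logistic rates per day (0 = no growth);
#'   default `c(0.08, 0.06, 0.1, 0.07, 0)` recycled/truncated to
#'   `n_subjects`.
#' @param rate_cv Log-normal coefficient of variation of the per-mouse
#'   growth rate around its subject's rate (default 0.25), reflecting the
#'   spread of engraftment latencies between mice of the same patient.
#' @param t_mid Logistic midpoint day (default 70).
#' @param contralateral_lag Days the contralateral burden lags (default 21).
#' @param contralateral_atten Attenuation of contralateral burden (default
#'   0.4).
#' @param effect_scale Relative metabolite change at burden 1 for a
#'   signature entry of 1 (default 0.6).
#' @param noise_sd Additive measurement noise sd in concentration units
#'   (default 0.2).
#' @param seed RNG seed (scoped).
#' @return List: `table` (one [metabolite_table()] with all scans; columns
#'   `subject`, `mouse`, `side`, `time_days` + 21 metabolites, CRLB
#'   attached) and `truth` (`burden` per row, `signature`, per-subject
#'   `growth_rates`, `seed`).
#' @export
simulate_longitudinal <- function(n_subjects = 5, n_mice_per_subject = 3,
                                  timepoints = seq(28, 112, by = 14),
                                  growth_rates = NULL, rate_cv = 0.25,
                                  t_mid = 70, contralateral_lag = 21,
                                  contralateral_atten = 0.4,
                                  effect_scale = 0.6, noise_sd = 0.2,
                                  seed = NULL) {
  growth_rates <- growth_rates %||% rep_len(c(0.08, 0.06, 0.1, 0.07, 0), n_subjects)
  if (length(growth_rates) != n_subjects) abort("one growth rate per subject required")
  panel <- mouse_metabolite_panel()
  base <- metab_baseline(panel)
  sig <- tumor_signature(panel)
  with_seed(seed, {
    meta <- tidyr::expand_grid(
      subject = paste0("P", seq_len(n_subjects)),
      mouse = seq_len(n_mice_per_subject),
      side = c("injected", "contralateral"),
      time_days = timepoints
    )
    subj_rate <- growth_rates[match(meta$subject, paste0("P", seq_len(n_subjects)))]
    mouse_id <- paste0(meta$subject, "m", meta$mouse)
    mice <- unique(mouse_id)
    mouse_mult <- setNames(rlnorm(length(mice), 0, rate_cv), mice)
    rate <- subj_rate * mouse_mult[mouse_id]
    burden <- ifelse(rate == 0, 0,
                     ifelse(meta$side == "injected",
                            plogis(rate * (meta$time_days - t_mid)),
                            contralateral_atten *
                              plogis(rate * (meta$time_days - t_mid - contralateral_lag))))
    nobs <- nrow(meta)
    clean <- outer(rep(1, nobs), base) *
      (1 + effect_scale * outer(burden, rep(1, length(panel))) *
         outer(rep(1, nobs), sig))
    vals <- clean + matrix(rnorm(nobs * length(panel), 0, noise_sd),
                           nobs, length(panel))
    vals <- pmax(vals, 0.01)
    colnames(vals) <- panel
    crlb <- draw_crlb(vals, noise_sd)
    meta$mouse <- paste0(meta$subject, "m", meta$mouse)
    tab <- metabolite_table(dplyr::bind_cols(meta, tibble::as_tibble(vals)),
                            crlb = crlb)
    truth <- list(burden = dplyr::mutate(meta[, c("subject", "mouse", "side", "time_days")],
                                         burden = burden),
                  signature = sig,
                  growth_rates = setNames(growth_rates, paste0("P", seq_len(n_subjects))),
                  mouse_rates = setNames(as.numeric(subj_rate[match(mice, mouse_id)] * mouse_mult),
                                         mice),
                  seed = seed)
    list(table = tab, truth = truth)
  })
}

#' Simulate a patient multi-voxel metabolite grid
#'
#' Emulates multi-voxel spectroscopy over a grid covering tumor core,
#' infiltration zone and adjacent brain: the per-voxel tumor mixing weight
#' decays smoothly from the tumor center (`exp(-d^2 / (2 radius^2))`), and
#' the voxel profile mixes the normal and tumor endmember profiles
#' accordingly. A configurable missingness pattern is injected
#' (tumor-specific lipids are missing in many normal voxels) so that a
#' "common metabolites with < 50% missing" selection rule is exercisable.
#'
#' @param grid_shape Rows x columns of the voxel grid (default `c(5, 5)`).
#' @param tumor_center Row/column of the tumor center (default `c(2, 2)`).
#' @param tumor_radius Gaussian decay radius in voxels (default 1.5;
#'   0 means all-normal tissue).
#' @param effect_scale,noise_sd As in [simulate_longitudinal()].
#' @param missing_rates Named per-metabolite missingness probabilities
#'   (default: 60% for `Lip20`, 10% for `GSH`).
#' @param subject Patient id recorded in the metadata.
#' @param seed RNG seed (scoped).
#' @return List: `table` (voxel-by-metabolite [metabolite_table()] with
#'   `voxel_row`, `voxel_col`) and `truth` (`burden` = mixing weight per
#'   voxel, `signature`, `seed`).
#' @export
simulate_mvs <- function(grid_shape = c(5, 5), tumor_center = c(2, 2),
                         tumor_radius = 1.5, effect_scale = 0.6,
                         noise_sd = 0.2,
                         missing_rates = c(Lip20 = 0.6, GSH = 0.1),
                         subject = "P1", seed = NULL) {
  if (any(grid_shape < 2)) abort("grid must be at least 2 x 2")
  panel <- patient_metabolite_panel()
  base <- metab_baseline(panel)
  sig <- tumor_signature(panel)
  with_seed(seed, {
    grid <- tidyr::expand_grid(voxel_row = seq_len(grid_shape[1]),
                               voxel_col = seq_len(grid_shape[2]))
    d2 <- (grid$voxel_row - tumor_center[1])^2 + (grid$voxel_col - tumor_center[2])^2
    w <- if (tumor_radius <= 0) rep(0, nrow(grid)) else exp(-d2 / (2 * tumor_radius^2))
    nobs <- nrow(grid)
    normal <- outer(rep(1, nobs), base)
    tumor <- outer(rep(1, nobs), base * (1 + effect_scale * sig))
    clean <- (1 - w) * normal + w * tumor
    vals <- clean + matrix(rnorm(nobs * length(panel), 0, noise_sd),
                           nobs, length(panel))
    vals <- pmax(vals, 0.01)
    colnames(vals) <- panel
    for (m in names(missing_rates)) {
      if (m %in% panel) {
        vals[runif(nobs) < missing_rates[m], m] <- NA_real_
      }
    }
    crlb <- draw_crlb(ifelse(is.na(vals), 1, vals), noise_sd)
    grid$subject <- subject
    tab <- metabolite_table(dplyr::bind_cols(grid[, c("subject", "voxel_row", "voxel_col")],
                                             tibble::as_tibble(vals)),
                            crlb = crlb)
    list(table = tab,
         truth = list(burden = dplyr::mutate(grid, burden = w),
                      signature = sig, seed = seed))
  })
}

#' Drop metabolites with too many missing values
#'
#' Keeps metabolites observed in more than `1 - max_missing` of the
#' observations (default: less than 50% missing).
#'
#' @param table A [metabolite_table()].
#' @param max_missing Maximum tolerated missing fraction (strict; default
#'   0.5).
#' @return Filtered metabolite table.
#' @export
filter_missing_metabolites <- function(table, max_missing = 0.5) {
  vals <- metab_values(table)
  keep <- colMeans(is.na(vals)) < max_missing
  out <- metab_replace(table, vals[, keep, drop = FALSE])
  crlb <- attr(table, "crlb")
  if (!is.null(crlb)) attr(out, "crlb") <- crlb[, keep, drop = FALSE]
  out
}

#' Simulate mixed-species counts coupled to a metabolite axis
#'
#' Emulates the RNA-seq arm: negative-binomial gene counts for human
#' (tumor) and mouse (host) genes in each sample, where a planted subset of
#' "active" genes per species tracks a latent per-sample score (the
#' standardized metabolite axis / tumor burden), all genes carry a
#' patient-level batch offset, and the per-sample fraction of human reads
#' rises with burden (tumor cells overtaking host tissue). Ambiguous-
#' labelled decoy genes are included for the classification filter.
#'
#' @param scores Per-sample latent score (e.g. truth burden or metabolite
#'   axis-1 score); standardized internally.
#' @param subjects Per-sample subject labels (batch structure).
#' @param types Per-sample tissue type (default `"injected"`).
#' @param sample_ids Sample names (default `S1..Sn`).
#' @param n_genes_per_species Genes per species (default 300).
#' @param n_active Planted score-tracking genes per species (default 5).
#' @param n_ambiguous Ambiguous decoy genes (default 20).
#' @param effect_size log2 change of active genes per score sd (default
#'   1.5).
#' @param dispersion NB dispersion (default 0.1).
#' @param lib_size_range Library-size range, uniform (default
#'   `c(2e7, 6e7)`, i.e. 20-60 million reads).
#' @param batch_sd sd of per-subject, per-gene log2 batch offsets (default
#'   0.5).
#' @param human_drift Human relative read weight goes from
#'   `1 - human_drift` at zero burden to 1 at full burden (default 0.95:
#'   trace human reads in uninvaded tissue, roughly half the reads at full
#'   burden — the typical end-stage tumor/mouse cell ratio).
#' @param mouse_drift Mouse relative read weight falls to
#'   `1 - mouse_drift` at full burden (default 0.2: infiltrative xenografts
#'   retain most of the host tissue).
#' @param compact_subjects Subjects whose xenografts are compact rather
#'   than infiltrative: their samples lose almost all mouse reads at high
#'   burden (extra factor `1 - compact_mouse_loss * burden`), which is what
#'   pushes samples under a mouse-read threshold downstream.
#' @param compact_mouse_loss Mouse-read loss at full burden for compact
#'   subjects (default 0.96).
#' @param seed RNG seed (scoped).
#' @return List: `counts` (a [count_matrix()]) and `truth`
#'   (`active_genes` per species, `score` per sample, `batch_effects`,
#'   `seed`).
#' @export
simulate_coupled_counts <- function(scores, subjects,
                                    types = NULL, sample_ids = NULL,
                                    n_genes_per_species = 300, n_active = 5,
                                    n_ambiguous = 20, effect_size = 1.5,
                                    dispersion = 0.1,
                                    lib_size_range = c(2e7, 6e7),
                                    batch_sd = 0.5, human_drift = 0.95,
                                    mouse_drift = 0.2,
                                    compact_subjects = NULL,
                                    compact_mouse_loss = 0.96,
                                    seed = NULL) {
  ns <- length(scores)
  if (length(subjects) != ns) abort("one subject per sample required")
  if (n_active > n_genes_per_species) abort("`n_active` exceeds genes per species")
  types <- types %||% rep("injected", ns)
  sample_ids <- sample_ids %||% paste0("S", seq_len(ns))
  z <- as.numeric(scale(scores))
  if (any(!is.finite(z))) z <- rep(0, ns)
  b01 <- (scores - min(scores)) / max(max(scores) - min(scores), 1e-9)
  with_seed(seed, {
    genes <- c(paste0("HG", seq_len(n_genes_per_species)),
               paste0("MG", seq_len(n_genes_per_species)),
               paste0("AG", seq_len(n_ambiguous)))
    species <- rep(c("human", "mouse", "ambiguous"),
                   c(n_genes_per_species, n_genes_per_species, n_ambiguous))
    G <- length(genes)
    active <- c(paste0("HG", seq_len(n_active)), paste0("MG", seq_len(n_active)))
    base_lm <- rnorm(G, mean = log2(50), sd = 1.2)
    subj_lev <- unique(subjects)
    batch <- matrix(rnorm(G * length(subj_lev), 0, batch_sd), G, length(subj_lev),
                    dimnames = list(genes, subj_lev))
    lm <- outer(base_lm, rep(1, ns)) + batch[, match(subjects, subj_lev)]
    act <- genes %in% active
    lm[act, ] <- lm[act, ] + effect_size * outer(rep(1, sum(act)), z)
    rel <- 2^lm
    # species-level read drift with tumor burden
    hscale <- (1 - human_drift) + human_drift * b01
    mscale <- 1 - mouse_drift * b01
    compact <- subjects %in% (compact_subjects %||% character())
    mscale[compact] <- mscale[compact] * (1 - compact_mouse_loss * b01[compact])
    rel[species == "human", ] <- sweep(rel[species == "human", , drop = FALSE], 2, hscale, "*")
    rel[species == "mouse", ] <- sweep(rel[species == "mouse", , drop = FALSE], 2, mscale, "*")
    prop <- sweep(rel, 2, colSums(rel), "/")
    lib <- runif(ns, lib_size_range[1], lib_size_range[2])
    mu <- sweep(prop, 2, lib, "*")
    counts <- matrix(rnbinom(G * ns, size = 1 / dispersion, mu = mu), G, ns,
                     dimnames = list(genes, sample_ids))
    meta <- tibble::tibble(sample = sample_ids, subject = subjects,
                           type = types, score = as.numeric(scores))
    cm <- count_matrix(counts, species, meta)
    list(counts = cm,
         truth = list(active_genes = list(human = paste0("HG", seq_len(n_active)),
                                          mouse = paste0("MG", seq_len(n_active))),
                      score = setNames(as.numeric(scores), sample_ids),
                      batch_effects = batch, seed = seed))
  })
}

#' Synthetic gene-set collection around planted truth
#'
#' Builds a small GMT-style collection for testing enrichment: one set per
#' species holding the planted active genes (padded with random members),
#' plus random decoy sets drawn from the universe.
#'
#' @param truth Truth object from [simulate_coupled_counts()].
#' @param universe Gene universe to draw decoys from.
#' @param n_decoy_sets Number of random sets (default 8).
#' @param set_size Size of each set (default 20).
#' @param seed RNG seed (scoped).
#' @return Named list of character vectors.
#' @export
synthetic_gene_sets <- function(truth, universe, n_decoy_sets = 8,
                                set_size = 20, seed = NULL) {
  with_seed(seed, {
    active <- unlist(truth$active_genes, use.names = FALSE)
    pad <- sample(setdiff(universe, active), max(set_size - length(active), 0))
    sets <- list(PLANTED_RESPONSE = c(active, pad))
    for (i in seq_len(n_decoy_sets)) {
      sets[[paste0("DECOY_", i)]] <- sample(universe, min(set_size, length(universe)))
    }
    sets
  })
}
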