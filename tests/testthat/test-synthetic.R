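test_that("generators are bit-reproducible given a seed", {
  a <- simulate_longitudinal(seed = 71)
  b <- simulate_longitudinal(seed = 71)
  expect_identical(as.data.frame(a$table), as.data.frame(b$table))
  expect_identical(attr(a$table, "crlb"), attr(b$table, "crlb"))
  m1 <- simulate_mvs(seed = 72); m2 <- simulate_mvs(seed = 72)
  expect_identical(as.data.frame(m1$table), as.data.frame(m2$table))
  score <- runif(6)
  c1 <- simulate_coupled_counts(score, rep("P1", 6), seed = 73)
  c2 <- simulate_coupled_counts(score, rep("P1", 6), seed = 73)
  expect_identical(c1$counts$counts, c2$counts$counts)
})

test_that("zero noise and zero burden give exactly the baseline profile", {
  sim <- simulate_longitudinal(noise_sd = 0, seed = 74)
  flat <- sim$table[sim$table$subject == "P5", ]   # growth rate 0
  vals <- as.matrix(flat[, metabolite_names(sim$table)])
  base <- mrsomics:::metab_baseline(mouse_metabolite_panel())
  for (j in seq_along(base)) expect_equal(unname(vals[, j]), rep(base[j], nrow(vals)),
                                          ignore_attr = TRUE)
})

test_that("the signature signs force NAA down and choline/Ins/Gly/Lac up in growing tumors", {
  sig <- tumor_signature()
  expect_true(all(sig[c("NAA", "Glu", "GABA", "NAAG")] < 0))
  expect_true(all(sig[c("GPC", "PCho", "Ins", "Gly", "Lac", "Gln")] > 0))
  sim <- simulate_longitudinal(noise_sd = 0, seed = 75)
  d <- tibble::as_tibble(as.data.frame(sim$table))
  growing <- d[d$side == "injected" & d$subject != "P5", ]
  for (sub in unique(growing$subject)) {
    g <- growing[growing$subject == sub, ]
    first <- g[g$time_days == min(g$time_days), ]
    last <- g[g$time_days == max(g$time_days), ]
    expect_lt(mean(last$NAA), mean(first$NAA))
    expect_gt(mean(last$GPC), mean(first$GPC))
  }
})

test_that("burden is in [0, 1], lagged and attenuated on the contralateral side", {
  sim <- simulate_longitudinal(seed = 76)
  bt <- sim$truth$burden
  expect_true(all(bt$burden >= 0 & bt$burden <= 1))
  for (sub in paste0("P", 1:4)) {
    for (tp in unique(bt$time_days)) {
      inj <- bt$burden[bt$subject == sub & bt$side == "injected" & bt$time_days == tp][1]
      con <- bt$burden[bt$subject == sub & bt$side == "contralateral" & bt$time_days == tp][1]
      expect_lte(con, inj + 1e-12)
    }
  }
})

test_that("MVS grids mix normal and tumor endmembers around the planted center", {
  sim0 <- simulate_mvs(tumor_radius = 0, noise_sd = 0, seed = 77,
                       missing_rates = c())
  base <- mrsomics:::metab_baseline(patient_metabolite_panel())
  vals <- metab_values(sim0$table)
  expect_equal(unname(vals[1, ]), unname(base), tolerance = 1e-12)
  expect_equal(unname(vals[nrow(vals), ]), unname(base), tolerance = 1e-12)
  # with a tumor, the center voxel is farther from baseline than a far corner
  sim <- simulate_mvs(tumor_center = c(2, 2), tumor_radius = 1.5,
                      noise_sd = 0, seed = 78, missing_rates = c())
  tb <- sim$table
  v <- metab_values(tb)
  dev <- rowSums(abs(sweep(v, 2, base) / base))
  center <- which(tb$voxel_row == 2 & tb$voxel_col == 2)
  corner <- which(tb$voxel_row == 5 & tb$voxel_col == 5)
  expect_gt(dev[center], dev[corner])
  expect_error(simulate_mvs(grid_shape = c(1, 5)), "2 x 2")
})

test_that("a metabolite missing in 60% of voxels falls to the under-50%-missing rule", {
  sim <- simulate_mvs(grid_shape = c(10, 10), seed = 79,
                      missing_rates = c(Lip20 = 0.6, GSH = 0.1))
  kept <- filter_missing_metabolites(sim$table, 0.5)
  expect_false("Lip20" %in% metabolite_names(kept))
  expect_true("GSH" %in% metabolite_names(kept))
})

test_that("coupled counts are integral, library-sized, and drift toward human reads with burden", {
  set.seed(80)
  score <- runif(12)
  sim <- simulate_coupled_counts(score, rep(paste0("P", 1:3), each = 4),
                                 seed = 81)
  cts <- sim$counts$counts
  expect_true(all(cts >= 0) && all(cts == round(cts)))
  tot <- colSums(cts)
  expect_true(all(tot > 2e7 * 0.7 & tot < 6e7 * 1.3))
  parts <- partition_species(sim$counts)
  expect_gt(cor(parts$fraction_human_reads, score, method = "spearman"), 0.9)
  # species labels include ambiguous decoys
  expect_gt(sum(sim$counts$species == "ambiguous"), 0)
})

test_that("active genes track the latent score and silent generators do not", {
  set.seed(82)
  score <- runif(20)
  sim <- simulate_coupled_counts(score, rep("P1", 20), effect_size = 2,
                                 batch_sd = 0, seed = 83)
  cm <- filter_low_counts(sim$counts)
  e <- log_normalize(cm, tmm_factors(cm))$values
  act <- intersect(unlist(sim$truth$active_genes), rownames(e))
  cors <- abs(apply(e[act, , drop = FALSE], 1, cor, y = score))
  expect_gt(min(cors), 0.8)
  sim0 <- simulate_coupled_counts(score, rep("P1", 20), effect_size = 0,
                                  batch_sd = 0, seed = 83)
  cm0 <- filter_low_counts(sim0$counts)
  e0 <- log_normalize(cm0, tmm_factors(cm0))$values
  act0 <- intersect(unlist(sim0$truth$active_genes), rownames(e0))
  other <- setdiff(rownames(e0), act0)
  cors_act0 <- abs(apply(e0[act0, , drop = FALSE], 1, cor, y = score))
  cors_bg <- abs(apply(e0[sample(other, 50), , drop = FALSE], 1, cor, y = score))
  # null behavior: "active" genes indistinguishable from background
  expect_lt(abs(mean(cors_act0) - mean(cors_bg)), 0.25)
})
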