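test_that("trajectory workflow reports all-metabolite loadings, per-mouse scores, and is rerun-identical", {
  cfg <- trajectory_config(seed = 91)
  rep1 <- run_trajectory_analysis(cfg)
  expect_equal(nrow(rep1$loadings), 21)   # tCr ratio keeps all measured metabolites
  sim_rows <- 5 * 3 * 2 * 7               # subjects x mice x sides x timepoints
  expect_equal(nrow(rep1$scores), sim_rows)
  expect_true(all(c("subject", "mouse", "side", "time_days", "Axis1") %in%
                    names(rep1$scores)))
  # the common panel is 13 metabolites by construction; CRLB and missing-value
  # exclusions can trim a couple depending on the draw
  expect_gte(rep1$loading_correlation$n_common, 11)
  expect_lte(rep1$loading_correlation$n_common, 13)
  common <- intersect(rep1$loadings$variable, rep1$mvs_loadings$variable)
  expect_true(all(common %in% intersect(mouse_metabolite_panel(),
                                        patient_metabolite_panel())))
  rep2 <- run_trajectory_analysis(cfg)
  expect_identical(rep1$scores, rep2$scores)           # determinism contract
  expect_identical(rep1$loadings, rep2$loadings)
})

test_that("the non-growing subject's injected and contralateral series are indistinguishable", {
  rep <- run_trajectory_analysis(trajectory_config(seed = 92))
  flat <- rep$scores[rep$scores$subject == "P5", ]
  tt <- t.test(flat$Axis1[flat$side == "injected"],
               flat$Axis1[flat$side == "contralateral"])
  expect_gt(tt$p.value, 0.01)
  # while a growing subject separates clearly
  grow <- rep$scores[rep$scores$subject == "P3" & rep$scores$time_days > 70, ]
  tt2 <- t.test(grow$Axis1[grow$side == "injected"],
                grow$Axis1[grow$side == "contralateral"])
  expect_lt(tt2$p.value, 0.01)
})

test_that("trajectory workflow writes artifacts and a manifest when out_dir is set", {
  dir <- withr::local_tempdir()
  run_trajectory_analysis(trajectory_config(seed = 93, out_dir = dir))
  for (f in c("scores.tsv", "loadings.tsv", "mvs_scores.tsv",
              "loading_correlation.tsv", "manifest.tsv", "stages.tsv")) {
    expect_true(file.exists(file.path(dir, f)), label = f)
  }
  man <- readr::read_tsv(file.path(dir, "manifest.tsv"), show_col_types = FALSE)
  expect_true(all(c("artifact", "rows", "hash", "config_hash") %in% names(man)))
})

test_that("integration workflow retains the planted genes and finds a significant RV", {
  rep <- suppressWarnings(
    run_integration_analysis(integration_config(seed = 94, n_perm = 199)))
  expect_equal(rep$sensitivity, 1)
  active <- unlist(rep$truth$active_genes, use.names = FALSE)
  expect_true(all(intersect(active, rep$selection$variable) %in% rep$retained))
  expect_lte(rep$rv_test$p_value, 0.05)
  expect_gte(rep$rv_test$rv, 0)
  # the planted gene set is flagged by enrichment of the retained list
  expect_true("PLANTED_RESPONSE" %in%
                rep$enrichment$set_name[rep$enrichment$significant])
})

test_that("integration workflow rejects mismatched sample names", {
  cfg <- integration_config(seed = 95)
  sim <- simulate_longitudinal(seed = mrsomics:::child_seed(95, 1))
  simc <- simulate_coupled_counts(runif(4), rep("P1", 4),
                                  sample_ids = paste0("zz", 1:4), seed = 1)
  cfg$data <- list(counts = simc$counts, truth_counts = simc$truth)
  expect_error(run_integration_analysis(cfg), "mismatch")
})

test_that("invaded-brain workflow drops low-coverage samples from every downstream table", {
  set.seed(96)
  score <- runif(10)
  sim <- simulate_coupled_counts(score, rep(paste0("P", 1:2), each = 5),
                                 types = rep(c("injected", "contralateral"), 5),
                                 seed = 97)
  cm <- sim$counts
  # force one sample far below the mouse-read threshold
  low <- which.max(score)
  keep_h <- cm$species == "human"
  cm$counts[!keep_h, low] <- pmin(cm$counts[!keep_h, low], 3L)
  cm <- count_matrix(cm$counts, cm$species,
                     cm$samples[setdiff(names(cm$samples), "lib_size")])
  cfg <- mouse_brain_config(seed = 98, n_boot = 10, n_rep = 20)
  cfg$data <- list(counts = cm, truth = sim$truth)
  rep <- suppressWarnings(suppressMessages(run_mouse_brain_analysis(cfg)))
  low_id <- cm$samples$sample[low]
  expect_true(low_id %in% rep$excluded_samples)
  expect_false(low_id %in% rep$samples$sample)
  expect_false(low_id %in% rownames(rep$expression))
})

test_that("invaded-brain workflow clusters the planted genes together with the strongest burden signal", {
  rep <- suppressWarnings(run_mouse_brain_analysis(mouse_brain_config(seed = 9)))
  act <- rep$truth$active_genes$mouse
  cl <- rep$clusters
  act_cl <- cl$cluster[cl$item %in% act]
  main <- as.integer(names(which.max(table(act_cl))))
  expect_gte(mean(act_cl == main), 0.8)   # planted genes co-cluster
  vp <- rep$varpart[rep$varpart$fraction == "FreqHum", ]
  expect_equal(vp$value[vp$cluster == main], max(vp$value))
  expect_true(all(rep$varpart$combined[rep$varpart$fraction == "FreqHum"] > 0.5))
})

test_that("report objects print a summary and autoplot returns ggplot objects", {
  rep <- run_trajectory_analysis(trajectory_config(seed = 99))
  expect_output(print(rep), "Trajectory workflow")
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(autoplot(rep$statis), "ggplot")
})
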