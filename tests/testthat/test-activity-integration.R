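test_that("activity is 1 for identical layers and tracks constructed ratios", {
  m <- tiny_table(c(10, 20, 30, 40, 50, 60, 5, 15, 25, 35, 45, 55), 3, 4)
  a <- compute_activity(m, m)
  expect_true(all(abs(a$activity - 1) < 1e-12))
  expect_gt(a$epsilon, 0)
  # MT relative abundance exactly 3x MG for one abundant species; a rare
  # fourth species keeps the shared pseudocount negligible
  mg <- tiny_table(rep(c(3e5, 3e5, 4e5, 1), 4), 4, 4)
  mt <- mg
  mt[1, ] <- mt[1, ] * 3
  mt <- sweep(mt, 2, colSums(mt), "/") * 1e6  # keep layer totals equal
  act <- compute_activity(mg, mt)
  rel_mg <- 3e5 / colSums(mg)[1]
  rel_mt <- 9e5 / (9e5 + 3e5 + 4e5 + 1)
  expect_equal(unname(act$activity["f01", 1]), unname(rel_mt / rel_mg),
               tolerance = 0.01)
})

test_that("species with no MG support are flagged and excluded", {
  mg <- tiny_table(c(0, 100, 200, 0, 150, 250, 0, 120, 220, 0, 130, 230), 3, 4)
  mt <- tiny_table(rep(c(50, 100, 200), 4), 3, 4)
  expect_message(a <- compute_activity(mg, mt), "low-MG-support")
  expect_true(a$low_support[["f01"]])
  expect_false(a$low_support[["f02"]])
})

test_that("activity requires aligned sample ids and names the offenders", {
  mg <- tiny_table(1:6, 2, 3)
  mt <- tiny_table(1:6, 2, 3, samples = c("s01", "s02", "zz9"))
  expect_error(compute_activity(mg, mt), "zz9")
})

test_that("activity is invariant to joint per-sample depth scaling", {
  sim <- simulate_paired_omics(omics_sim_config(n_per_group = 6,
                                                n_species = 30, depth = 2e4,
                                                seed = 13))
  f <- c(rep(3, 6), rep(7, 6))
  mg2 <- unclass(sim$mg); mt2 <- unclass(sim$mt)
  mg2 <- sweep(mg2, 2, f, "*"); mt2 <- sweep(mt2, 2, f, "*")
  a1 <- compute_activity(sim$mg, sim$mt)
  a2 <- compute_activity(mg2, mt2)
  ab <- rowMeans(unclass(sim$mg)) > 50   # well above the pseudocount
  expect_equal(a1$activity[ab, ], a2$activity[ab, ], tolerance = 1e-6)
})

test_that("intersection records directions and concordance", {
  mg <- data.frame(feature = c("a", "b", "c"),
                   enriched_group = c("fat", "fat", "lean"))
  mt <- data.frame(feature = c("b", "c", "d"),
                   enriched_group = c("fat", "fat", "lean"))
  ov <- intersect_differentials(mg, mt)
  expect_identical(ov$feature, c("b", "c"))
  expect_identical(ov$concordant, c(TRUE, FALSE))
  empty <- intersect_differentials(mg[0, ], mt)
  expect_identical(nrow(empty), 0L)
})

test_that("planted overlap is recovered exactly from generator truth", {
  sim <- simulate_paired_omics(omics_sim_config(seed = 19))
  cfg <- lefse_config(seed = 19)
  ov <- intersect_differentials(
    run_lefse(sim$mg, sim$metadata$group, cfg),
    run_lefse(sim$mt, sim$metadata$group, cfg))
  expect_true(all(sim$truth$overlap %in% ov$feature))
})

test_that("Spearman: monotone case, exact vs t-approximation, degenerate input", {
  v <- c(1, 3, 4, 7, 9, 12, 15, 20, 21, 30)
  expect_equal(spearman_test(v, v^3 + 2)$rho, 1)
  expect_equal(spearman_test(v, exp(v / 10))$rho, 1)
  set.seed(23)
  for (i in 1:15) {
    x <- rnorm(9); y <- rnorm(9)
    pe <- spearman_test(x, y, mode = "exact")$p
    pt_ <- spearman_test(x, y, mode = "approximate")$p
    expect_lt(abs(pe - pt_), 0.03)
    # cross-check the exact path against stats::cor.test (AS 89 algorithm)
    expect_lt(abs(pe - cor.test(x, y, method = "spearman")$p.value), 1e-8)
  }
  expect_message(r <- spearman_test(rep(1, 6), rnorm(6)), "constant")
  expect_true(is.na(r$rho))
})

test_that("null phenotypes give activity correlations centred at zero", {
  set.seed(29)
  rhos <- sapply(1:40, function(i) {
    v <- runif(12); y <- rnorm(12)
    spearman_test(v, y)$rho
  })
  expect_lt(abs(mean(rhos)), 0.12)
})

test_that("candidate gate: driver selected, sign flip rejected, empty in empty out", {
  sim <- simulate_paired_omics(omics_sim_config(seed = 37))
  cfg <- lefse_config(seed = 37)
  fit <- driver_screen(sim$mg, sim$mt, sim$metadata, config = cfg)
  sel <- fit$candidates[fit$candidates$selected, ]
  expect_identical(sel$feature, sim$truth$driver_id)
  expect_identical(sel$rank, 1L)
  expect_true(all(sel$rho_AFP > 0 & sel$rho_AFW > 0))
  # flipping the phenotype makes the driver's correlation negative -> the
  # driver itself can no longer pass the gate
  meta_flip <- sim$metadata
  meta_flip$AFW <- max(meta_flip$AFW) + 1 - meta_flip$AFW
  meta_flip$AFP <- meta_flip$AFW / meta_flip$BW
  fit2 <- driver_screen(sim$mg, sim$mt, meta_flip, config = cfg)
  cand2 <- fit2$candidates
  expect_false(any(cand2$selected & cand2$feature == sim$truth$driver_id))
  expect_lt(cand2$rho_AFW[cand2$feature == sim$truth$driver_id], 0)
  # empty overlap propagates to an empty (valid) report
  empty <- select_candidates(intersect_differentials(
    data.frame(feature = character(0), enriched_group = character(0)),
    data.frame(feature = "x", enriched_group = "fat")),
    fit$activity, fit$correlations, fit$groups)
  expect_identical(nrow(empty), 0L)
  expect_s3_class(empty, "candidate_report")
})

test_that("driver_screen methods expose the fit", {
  sim <- simulate_paired_omics(omics_sim_config(n_per_group = 10,
                                                n_species = 60, depth = 3e4,
                                                seed = 41))
  fit <- driver_screen(sim$mg, sim$mt, sim$metadata,
                       config = lefse_config(seed = 41))
  expect_s3_class(fit, "driver_screen")
  expect_output(print(fit), "Driver screen")
  expect_output(print(summary(fit)), "Gates")
  cf <- coef(fit)
  expect_true(is.data.frame(cf))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
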