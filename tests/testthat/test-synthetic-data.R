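test_that("paired-omics generator is seed-deterministic and depth-exact", {
  cfg <- omics_sim_config(n_per_group = 5, n_species = 40, depth = 1e4,
                          seed = 7)
  a <- simulate_paired_omics(cfg)
  b <- simulate_paired_omics(cfg)
  expect_identical(a, b)
  expect_true(all(colSums(a$mg) == 1e4))
  expect_true(all(colSums(a$mt) == 1e4))
  expect_true(all(a$mg >= 0) && all(a$mt >= 0))
  expect_identical(colnames(a$mg), colnames(a$mt))
  expect_identical(rownames(a$mg), rownames(a$mt))
})

test_that("simulated phenotypes satisfy AFP = AFW / BW exactly", {
  sim <- simulate_paired_omics(omics_sim_config(n_per_group = 8,
                                                n_species = 30, depth = 5e3,
                                                seed = 3))
  expect_identical(sim$metadata$AFP, sim$metadata$AFW / sim$metadata$BW)
})

test_that("planted truth is coherent: driver sits in the overlap of both sets", {
  sim <- simulate_paired_omics(omics_sim_config(n_per_group = 6,
                                                n_species = 50, depth = 1e4,
                                                seed = 9))
  tr <- sim$truth
  expect_length(tr$overlap, 5)
  expect_true(tr$driver_id %in% tr$overlap)
  expect_true(tr$driver_id %in% tr$diff_species_mg$feature)
  expect_true(tr$driver_id %in% tr$diff_species_mt$feature)
  expect_true(all(tr$overlap %in% tr$diff_species_mg$feature))
  expect_true(all(tr$overlap %in% tr$diff_species_mt$feature))
})

test_that("driver latent activity ratio matches the configured fold", {
  # geometric group means of the latent MT/MG ratio, before count sampling
  cfg <- omics_sim_config(n_per_group = 40, n_species = 60,
                          driver_activity_fold = 3, depth = 1e4, seed = 21)
  sim <- simulate_paired_omics(cfg)
  ratio <- sim$truth$latent_mt / sim$truth$latent_mg
  fat <- sim$metadata$group == "fat"
  gm <- function(v) exp(mean(log(v)))
  fold <- gm(ratio[sim$truth$driver_id, fat]) /
          gm(ratio[sim$truth$driver_id, !fat])
  expect_equal(fold, 3, tolerance = 0.15)
  # non-driver overlap species carry no activity shift
  other <- setdiff(sim$truth$overlap, sim$truth$driver_id)[1]
  fold0 <- gm(ratio[other, fat]) / gm(ratio[other, !fat])
  expect_equal(fold0, 1, tolerance = 0.2)
})

test_that("generator config validation names the offending field", {
  expect_error(omics_sim_config(n_overlap = 11, n_diff_mg = 10),
               "n_overlap")
  expect_error(omics_sim_config(depth = 0), "depth")
  expect_error(omics_sim_config(diff_fold = -1), "diff_fold")
  expect_error(simulate_metabolome(fc = 0), "fc")
  expect_error(simulate_metabolome(n_features = 5, n_up = 4, n_down = 4),
               "n_features")
  expect_error(simulate_ct_table(reference_gene = "nope"), "reference_gene")
  expect_error(simulate_adipocyte_panels(mean_diam_by_group = c(a = -1, b = 2)),
               "mean_diam_by_group")
})

test_that("adipocyte panel: zero spread gives identical areas; seeds reproduce", {
  p <- simulate_adipocyte_panels(n_per_group = 2,
                                 mean_diam_by_group = c(g1 = 50, g2 = 50),
                                 sd_diam = 0, cells_per_bird = 20, seed = 4)
  expect_true(all(abs(p[[1]]$areas_um2 - pi * 25^2) < 1e-9))
  p2 <- simulate_adipocyte_panels(n_per_group = 2,
                                  mean_diam_by_group = c(g1 = 50, g2 = 50),
                                  sd_diam = 0, cells_per_bird = 20, seed = 4)
  expect_identical(p, p2)
})

test_that("metabolome generator plants recoverable truth and honest QC", {
  mb <- simulate_metabolome(seed = 11)
  expect_true(all(mb$intensities >= 0))
  expect_length(mb$truth$up, 15)
  expect_length(mb$truth$down, 15)
  expect_identical(sum(mb$is_qc), 3L)
  qc <- mb$intensities[, mb$is_qc]
  rsd <- apply(qc, 1, sd) / rowMeans(qc)
  expect_lt(median(rsd, na.rm = TRUE), 0.10)
  expect_identical(mb, simulate_metabolome(seed = 11))
})

test_that("Ct generator keeps the reference stable and shifts targets", {
  ctb <- simulate_ct_table(n_per_group = 10, delta_by_gene = c(ACACA = -1),
                           sd_ct = 0.1, seed = 5)
  ref <- ctb$ct[ctb$reference_gene, ]
  trt <- ctb$groups == "treated"
  expect_lt(abs(mean(ref[trt]) - mean(ref[!trt])), 0.2)
  shift <- mean(ctb$ct["ACACA", trt]) - mean(ctb$ct["ACACA", !trt])
  expect_equal(shift, -1, tolerance = 0.2)
  expect_identical(ctb, simulate_ct_table(n_per_group = 10,
                                          delta_by_gene = c(ACACA = -1),
                                          sd_ct = 0.1, seed = 5))
})

test_that("simulation writes TSV tables and a JSON truth sidecar that reload", {
  sim <- simulate_paired_omics(omics_sim_config(n_per_group = 4,
                                                n_species = 20, depth = 2e3,
                                                seed = 2))
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  mg <- read_feature_table(paths[["mg"]], layer = "MG")
  expect_equal(unclass(mg), unclass(sim$mg), ignore_attr = TRUE)
  meta <- read_sample_metadata(paths[["metadata"]])
  expect_equal(meta$AFW, sim$metadata$AFW, tolerance = 1e-9)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_identical(truth$driver_id, sim$truth$driver_id)
})
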