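test_that("rank-sum exact p equals full enumeration for all n + m <= 12", {
  set.seed(3)
  sizes <- list(c(2, 2), c(2, 4), c(3, 3), c(3, 5), c(4, 4), c(5, 5),
                c(4, 8), c(6, 6), c(2, 10))
  for (sz in sizes) {
    # continuous data and tie-heavy integer data
    for (gen in list(function(k) rnorm(k), function(k) sample(1:3, k, TRUE))) {
      x <- gen(sz[1]); y <- gen(sz[2])
      mine <- rank_sum_test(x, y, mode = "exact")
      ref <- brute_rank_sum(x, y)
      expect_equal(mine$U, ref$U)
      expect_equal(mine$p, ref$p, tolerance = 1e-12)
    }
  }
})

test_that("rank-sum fixtures: separated groups and identical multisets", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_identical(r$mode, "exact")
  same <- rank_sum_test(c(2, 2, 5, 7), c(7, 2, 5, 2))
  expect_equal(same$p, 1)
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("exact and approximate rank-sum p agree at moderate n", {
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(15); y <- rnorm(15)
    pe <- rank_sum_test(x, y, mode = "exact")$p
    pa <- rank_sum_test(x, y, mode = "approximate")$p
    expect_lt(abs(pa - pe), 0.02)
  }
})

test_that("BH adjustment matches its defining minimum on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(4)
  for (i in 1:100) {
    p <- runif(sample(2:20, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("LDA effect size: constant features score zero, planted effects pass", {
  set.seed(6)
  n <- 10
  groups <- rep(c("fat", "lean"), each = n)
  mat <- matrix(10, 6, 2 * n,
                dimnames = list(paste0("f", 1:6), paste0("s", 1:(2 * n))))
  mat[2, ] <- abs(rnorm(2 * n, 100, 5))
  mat[3, ] <- c(rnorm(n, 1e5, 1e4), rnorm(n, 1e2, 10))  # planted
  sc <- lda_effect_size(mat, groups, lefse_config(seed = 1))
  expect_equal(unname(sc["f1"]), 0)
  expect_gt(sc["f3"], 2.5)
  expect_lt(sc["f2"], 1)
  # invariant to sample and feature ordering
  perm_s <- sample(2 * n); perm_f <- sample(6)
  sc2 <- lda_effect_size(mat[perm_f, perm_s], groups[perm_s],
                         lefse_config(seed = 1))
  expect_equal(sc2[names(sc)], sc, tolerance = 1e-10)
})

test_that("permuting group labels destroys a planted effect", {
  set.seed(12)
  n <- 12
  mat <- matrix(abs(rnorm(40 * 2 * n, 1000, 100)), 40, 2 * n,
                dimnames = list(paste0("f", 1:40), paste0("s", 1:(2 * n))))
  mat[1, 1:n] <- rnorm(n, 3000, 300)   # 3-fold class shift
  groups <- rep(c("a", "b"), each = n)
  sc <- lda_effect_size(mat, groups, lefse_config(seed = 2))
  perm_scores <- replicate(10, {
    g <- sample(groups)
    lda_effect_size(mat, g, lefse_config(seed = 2))["f1"]
  })
  expect_gt(sc["f1"], 2.5)
  expect_lt(mean(perm_scores), 2.5)
})

test_that("LEfSe screen recovers planted differentials with high recall", {
  sim <- simulate_paired_omics(omics_sim_config(n_per_group = 30,
                                                n_species = 120, seed = 31))
  res <- run_lefse(sim$mg, sim$metadata$group, lefse_config(seed = 31))
  truth <- sim$truth$diff_species_mg
  recall <- mean(truth$feature %in% res$feature)
  expect_gte(recall, 0.9)
  hit <- res[match(intersect(truth$feature, res$feature), res$feature), ]
  dir_truth <- truth$direction[match(hit$feature, truth$feature)]
  expect_true(all(hit$enriched_group == dir_truth))
  # deterministic ordering by (-lda, feature)
  expect_true(all(diff(res$lda_score) <= 1e-12))
  expect_true(all(res$q >= res$p))
})

test_that("LEfSe output is invariant to compositional depth scaling", {
  sim <- simulate_paired_omics(omics_sim_config(n_per_group = 8,
                                                n_species = 40, depth = 2e4,
                                                seed = 17))
  mg2 <- sim$mg
  mg2[] <- sweep(unclass(sim$mg), 2, c(rep(2, 8), rep(5, 8)), "*")
  r1 <- suppressMessages(run_lefse(sim$mg, sim$metadata$group,
                                   lefse_config(seed = 5)))
  r2 <- suppressMessages(run_lefse(mg2, sim$metadata$group,
                                   lefse_config(seed = 5)))
  expect_equal(r1, r2, ignore_attr = TRUE)
})

test_that("impossible gates give an empty, well-formed result", {
  sim <- simulate_paired_omics(omics_sim_config(n_per_group = 5,
                                                n_species = 20, depth = 5e3,
                                                seed = 1))
  expect_message(
    res <- run_lefse(sim$mg, sim$metadata$group,
                     lefse_config(lda_threshold = Inf, seed = 1)),
    "no feature")
  expect_identical(nrow(res), 0L)
  expect_named(res, c("feature", "p", "q", "lda_score", "enriched_group"))
  sparse <- tiny_table(rpois(40, 2), 4, 10)
  sparse[cbind(1:4, 1:4)] <- 0          # every feature misses one sample
  expect_message(
    resp <- run_lefse(sparse, rep(c("a", "b"), each = 5),
                      lefse_config(min_prevalence = 1.0, seed = 1)),
    "prevalence")
  expect_identical(nrow(resp), 0L)
  expect_error(run_lefse(sim$mg[, 1:5], rep("a", 5), lefse_config()),
               "two groups")
})
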