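test_that("Chao1 follows the classic / bias-corrected forms", {
  a <- alpha_diversity(c(5, 1, 1, 2, 3))   # S=5, F1=2, F2=1
  expect_equal(a$chao1, 7)
  expect_equal(a$S_obs, 5)
  a2 <- alpha_diversity(c(1, 1))           # F2=0 -> bias-corrected
  expect_equal(a2$chao1, 3)
  a3 <- alpha_diversity(c(4, 5, 6))        # no singletons
  expect_equal(a3$chao1, 3)
  expect_error(alpha_diversity(c(0, 0, 0)), "empty")
})

test_that("ACE matches the EstimateS convention (vegan cross-check)", {
  set.seed(42)
  for (i in 1:20) {
    x <- rpois(40, lambda = sample(1:8, 1))
    if (sum(x) == 0) next
    mine <- alpha_diversity(x)
    ref <- vegan::estimateR(x)
    if (!is.na(ref[["S.ACE"]]))
      expect_equal(mine$ACE, unname(ref[["S.ACE"]]), tolerance = 1e-8)
    expect_gte(mine$chao1, mine$S_obs)
    expect_gte(mine$shannon, 0)
  }
})

test_that("Shannon entropy of a one-species sample is zero", {
  expect_equal(alpha_diversity(c(0, 17, 0))$shannon, 0)
})

test_that("Bray-Curtis: fixture value, identity, disjoint supports, zero pairs", {
  m <- tiny_table(c(6, 0, 2, 2, 4, 0), 3, 2)
  expect_equal(as.numeric(bray_curtis(m)), 10 / 14)
  m2 <- tiny_table(c(1, 2, 3, 1, 2, 3), 3, 2)
  expect_equal(as.numeric(bray_curtis(m2)), 0)
  m3 <- tiny_table(c(5, 0, 0, 3), 2, 2)
  expect_equal(as.numeric(bray_curtis(m3)), 1)
  m4 <- tiny_table(c(0, 0, 0, 0, 1, 2), 2, 3)
  expect_message(d <- bray_curtis(m4), "all-zero")
  expect_equal(as.matrix(d)["s01", "s02"], 0)
  expect_error(bray_curtis(tiny_table(c(-1, 1, 1, 1), 2, 2)), "negative")
})

test_that("Bray-Curtis is symmetric and bounded on random tables", {
  set.seed(7)
  for (i in 1:25) {
    m <- matrix(rpois(60, 3), 6, 10,
                dimnames = list(paste0("f", 1:6), paste0("s", 1:10)))
    d <- as.matrix(suppressMessages(bray_curtis(m)))
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
  }
})

test_that("PCoA: two samples, degenerate input, Euclidean round trip", {
  d <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  o <- pcoa(d)
  expect_equal(abs(unname(diff(o$points[, 1]))), 3)
  o0 <- pcoa(matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3])))
  expect_true(all(o0$points == 0))
  set.seed(5)
  xy <- matrix(rnorm(24), 12, 2, dimnames = list(paste0("s", 1:12), NULL))
  rec <- pcoa(dist(xy))
  pr <- vegan::procrustes(xy, rec$points[, 1:2], symmetric = TRUE)
  expect_lt(pr$ss, 1e-8)
  expect_true(all(diff(rec$eigenvalues) <= 1e-8))
  expect_lte(sum(rec$proportion_explained), 1 + 1e-12)
  # agreement with classical scaling in stats
  cs <- cmdscale(dist(xy), k = 2, eig = TRUE)
  expect_equal(abs(rec$points[, 1:2]), abs(cs$points), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PERMANOVA pseudo-F matches vegan and enumeration is exact", {
  set.seed(1)
  pts <- rbind(matrix(rnorm(6, 0, 0.01), 3), matrix(rnorm(6, 10, 0.01), 3))
  d <- dist(pts)
  g <- rep(c("a", "b"), each = 3)
  pm <- permanova(d, g)
  expect_true(pm$exhaustive)
  expect_equal(pm$p, 1 / 10)        # C(6,3) = 20 assignments, 2 attain F_obs
  ref <- vegan::adonis2(d ~ grp, data = data.frame(grp = g), permutations = 19)
  expect_equal(pm$pseudo_F, ref$F[1], tolerance = 1e-10)
  # exhaustive p agrees with enumerating labels and re-scoring through vegan
  la <- utils::combn(6, 3)
  fs <- apply(la, 2, function(ix) {
    gg <- rep("b", 6); gg[ix] <- "a"
    vegan::adonis2(d ~ grp, data = data.frame(grp = gg), permutations = 2)$F[1]
  })
  expect_equal(pm$p, mean(fs >= pm$pseudo_F - 1e-9))
})

test_that("PERMANOVA flags a zero within-group sum of squares", {
  d <- matrix(1, 4, 4) - diag(4)
  d[1, 2] <- d[2, 1] <- 0
  d[3, 4] <- d[4, 3] <- 0
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  pm <- permanova(d, c("a", "a", "b", "b"))
  expect_true(pm$infinite_F)
  expect_true(is.infinite(pm$pseudo_F))
  expect_error(permanova(d, rep("a", 4)), "degenerate")
})

test_that("ANOSIM: perfect separation gives R = 1; ties stay bounded", {
  set.seed(2)
  pts <- c(rnorm(4, 0, 0.1), rnorm(4, 50, 0.1))
  d <- dist(pts)
  g <- rep(c("a", "b"), each = 4)
  an <- anosim(d, g)
  expect_equal(an$R, 1)
  expect_true(an$exhaustive)
  ref <- vegan::anosim(d, g, permutations = 19)
  expect_equal(an$R, unname(ref$statistic), tolerance = 1e-10)
  # heavy ties: midranks keep R within [-1, 1]
  dt <- matrix(1, 6, 6) - diag(6)
  dimnames(dt) <- list(paste0("s", 1:6), paste0("s", 1:6))
  at <- anosim(dt, rep(c("a", "b"), each = 3))
  expect_true(at$R >= -1 && at$R <= 1)
})

test_that("ANOSIM R is centred at zero when labels carry no structure", {
  set.seed(30)
  rs <- replicate(60, {
    d <- dist(matrix(rnorm(14), 7, 2))
    anosim(d, sample(rep(c("a", "b"), c(4, 3))), max_exhaustive = 1)$R
  })
  expect_lt(abs(mean(rs)), 0.08)
})

test_that("sampled permutation p converges to the exhaustive p", {
  set.seed(9)
  d <- dist(matrix(rnorm(16), 8, 2))
  g <- rep(c("a", "b"), each = 4)
  exact <- permanova(d, g)          # C(8,4) = 70 -> exhaustive
  expect_true(exact$exhaustive)
  approx <- permanova(d, g, n_perm = 9999, seed = 1, max_exhaustive = 1)
  expect_false(approx$exhaustive)
  expect_lt(abs(approx$p - exact$p), 0.03)
})
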