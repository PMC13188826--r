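#' Configuration for the LEfSe-style screen
#'
#' The screen combines a per-feature Mann-Whitney rank-sum test with a
#' bootstrapped linear-discriminant effect size on total-sum-scaled
#' abundances. The published method fixes only the gates (`P < 0.05`,
#' `LDA > 2.5`, or `LDA > 2` for coarser designs); the internals here -
#' bootstrap rounds, per-class subsampling, diagonal-loading regularization
#' of the within-class covariance, the half raw / half discriminant effect
#' combination and the `log10(1 + effect)` transform - are fixed for
#' determinism and are all adjustable through this object.
#'
#' @param alpha Rank-sum significance gate (default 0.05).
#' @param lda_threshold Effect-size gate on the log10 scale (default 2.5;
#'   2.0 is the common alternate).
#' @param n_bootstrap Bootstrap rounds for the effect size (default 30).
#' @param subsample_fraction Fraction of each class subsampled (without
#'   replacement) per round (default 2/3).
#' @param scale_total Per-sample total after scaling (default 1e6).
#' @param min_prevalence Minimum fraction of samples in which a feature must
#'   be non-zero to be tested (default 0 = test everything).
#' @param seed Integer seed for the bootstrap.
#' @return A validated list of class `lefse_config`.
#' @export
lefse_config <- function(alpha = 0.05, lda_threshold = 2.5, n_bootstrap = 30,
                         subsample_fraction = 2 / 3, scale_total = 1e6,
                         min_prevalence = 0, seed = 1L) {
  cfg <- list(alpha = check_number(alpha, "alpha", 1e-12, 1 - 1e-12),
              lda_threshold = check_number(lda_threshold, "lda_threshold", 0),
              n_bootstrap = check_count(n_bootstrap, "n_bootstrap", 1L),
              subsample_fraction = check_number(subsample_fraction,
                                                "subsample_fraction", 1e-6, 1),
              scale_total = check_number(scale_total, "scale_total", 1e-12),
              min_prevalence = check_number(min_prevalence, "min_prevalence",
                                            0, 1),
              seed = check_count(seed, "seed", 0L))
  class(cfg) <- "lefse_config"
  cfg
}

#' Two-sample Mann-Whitney rank-sum test
#'
#' Two-sided test of `x` vs `y`. `U` counts pairs with `x > y` (ties count
#' one half). Exact p-values come from the full null distribution: the
#' tie-free case uses the closed-form Mann-Whitney distribution, tied data
#' are handled by enumerating all assignments of the pooled midranks.
#' The approximate path is the midrank normal approximation with the tie
#' correction and a continuity correction. `mode = "auto"` picks exact
#' enumeration when `n + m <= 12` and the approximation otherwise.
#'
#' @param x,y Non-empty numeric vectors.
#' @param mode `"auto"`, `"exact"` or `"approximate"`.
#' @return List: `U`, `p`, `mode` actually used.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p  # exact 0.1
#' @export
rank_sum_test <- function(x, y, mode = c("auto", "exact", "approximate")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both vectors must be non-empty")
  if (anyNA(c(x, y))) stop("missing values are not supported")
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (mode == "auto") mode <- if (N <= 12) "exact" else "approximate"
  if (mode == "exact") {
    ties <- anyDuplicated(c(x, y)) > 0
    if (!ties) {
      # symmetric null: double the smaller tail of the exact distribution
      lo <- pwilcox(U, n, m)
      hi <- 1 - pwilcox(U - 1, n, m)
      p <- min(1, 2 * min(lo, hi))
    } else {
      if (choose(N, n) > 5e5)
        stop("exact mode with ties is limited to choose(n+m, n) <= 5e5")
      dev <- abs(U - n * m / 2)
      sel <- combn(N, n)
      us <- colSums(matrix(r[sel], nrow = n)) - n * (n + 1) / 2
      p <- mean(abs(us - n * m / 2) >= dev - 1e-9)
    }
  } else {
    mu <- n * m / 2
    tie_tab <- table(r)
    sigma2 <- n * m / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  list(U = U, p = p, mode = mode)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (via [stats::p.adjust()]).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Bootstrapped linear-discriminant effect size
#'
#' Per bootstrap round, `subsample_fraction` of each class is drawn without
#' replacement; the per-feature effect is the mean of the absolute raw
#' class-mean difference and the feature's additive contribution to the
#' projected class-mean separation along the one-dimensional regularized
#' linear discriminant (`w` proportional to `(S_w + lambda I)^-1 (mu1 -
#' mu2)`, unit norm, diagonal loading `lambda = 1e-6 trace(S_w)`). The
#' reported score is `log10(1 + mean bootstrap effect)`, so a feature that
#' is constant across samples scores exactly 0.
#'
#' @param table_scaled Features x samples matrix already scaled to
#'   `scale_total` per sample.
#' @param groups Two-level group label per sample.
#' @param cfg A [lefse_config()].
#' @return Named numeric vector of per-feature scores (log10 scale).
#' @export
lda_effect_size <- function(table_scaled, groups, cfg = lefse_config()) {
  mat <- as.matrix(unclass(table_scaled))
  g <- factor(groups)
  if (nlevels(g) != 2) stop("exactly two groups are required")
  # canonicalize orderings so the seeded bootstrap is invariant to the
  # order in which samples and features arrive
  feat_in <- rownames(mat)
  if (!is.null(colnames(mat))) {
    ord_s <- order(colnames(mat))
    mat <- mat[, ord_s, drop = FALSE]
    g <- g[ord_s]
  }
  if (!is.null(feat_in)) mat <- mat[order(feat_in), , drop = FALSE]
  idx1 <- which(g == levels(g)[1]); idx2 <- which(g == levels(g)[2])
  k1 <- ceiling(cfg$subsample_fraction * length(idx1))
  k2 <- ceiling(cfg$subsample_fraction * length(idx2))
  if (k1 < 3 || k2 < 3)
    stop("design error: a class has fewer than 3 samples after subsampling")
  p <- nrow(mat)
  eff <- matrix(0, p, cfg$n_bootstrap)
  with_seed(cfg$seed, {
    for (b in seq_len(cfg$n_bootstrap)) {
      s1 <- sample(idx1, k1); s2 <- sample(idx2, k2)
      x1 <- mat[, s1, drop = FALSE]; x2 <- mat[, s2, drop = FALSE]
      mu1 <- rowMeans(x1); mu2 <- rowMeans(x2)
      dmu <- mu1 - mu2
      c1 <- x1 - mu1; c2 <- x2 - mu2
      sw <- (tcrossprod(c1) + tcrossprod(c2)) / (k1 + k2 - 2)
      tr <- sum(diag(sw))
      lambda <- if (tr > 0) 1e-6 * tr else 1
      w <- solve(sw + diag(lambda, p), dmu)
      nw <- sqrt(sum(w^2))
      d_lda <- if (nw > 0) (w / nw) * dmu else rep(0, p)
      eff[, b] <- 0.5 * (abs(dmu) + abs(d_lda))
    }
  })
  out <- setNames(log10(1 + rowMeans(eff)), rownames(mat))
  if (!is.null(feat_in)) out <- out[feat_in]
  out
}

#' LEfSe-style differential-abundance screen
#'
#' Scales each sample to `scale_total` (total-sum scaling), tests every
#' feature with the two-sided rank-sum test, computes the bootstrapped
#' discriminant effect size, and reports features passing both gates
#' (`p < alpha` and score `> lda_threshold`). The enriched group is the one
#' with the higher mean scaled abundance. Results are ordered by decreasing
#' score, ties broken by feature id; BH-adjusted q-values are computed over
#' all tested features.
#'
#' @param table Features x samples count/abundance matrix or
#'   [feature_table()].
#' @param groups Two-level group label per sample (>= 3 samples per group).
#' @param cfg A [lefse_config()].
#' @return A data.frame (class `lefse_result`) of significant features with
#'   columns `feature`, `p`, `q`, `lda_score`, `enriched_group`. The full
#'   per-feature table (before gating) is attached as attribute `"tested"`.
#' @export
run_lefse <- function(table, groups, cfg = lefse_config()) {
  mat <- as.matrix(unclass(table))
  g <- factor(groups)
  if (nlevels(g) != 2) stop("exactly two groups are required")
  if (any(tabulate(g) < 3)) stop("need at least 3 samples per group")
  if (ncol(mat) != length(groups))
    stop("groups length must match the number of samples")
  if (cfg$min_prevalence > 0) {
    keep <- rowMeans(mat > 0) >= cfg$min_prevalence
    if (!any(keep)) {
      message("run_lefse: all features removed by the prevalence filter")
      out <- empty_lefse_result()
      attr(out, "tested") <- out
      return(out)
    }
    mat <- mat[keep, , drop = FALSE]
  }
  scaled <- tss(mat, cfg$scale_total)
  i1 <- g == levels(g)[1]
  pvals <- vapply(seq_len(nrow(scaled)), function(f)
    rank_sum_test(scaled[f, i1], scaled[f, !i1])$p, numeric(1))
  scores <- lda_effect_size(scaled, g, cfg)
  mu1 <- rowMeans(scaled[, i1, drop = FALSE])
  mu2 <- rowMeans(scaled[, !i1, drop = FALSE])
  enriched <- ifelse(mu1 >= mu2, levels(g)[1], levels(g)[2])
  tested <- data.frame(feature = rownames(scaled), p = pvals,
                       q = bh_adjust(pvals), lda_score = unname(scores),
                       enriched_group = enriched, stringsAsFactors = FALSE,
                       row.names = NULL)
  hit <- tested$p < cfg$alpha & tested$lda_score > cfg$lda_threshold
  out <- tested[hit, , drop = FALSE]
  out <- out[order(-out$lda_score, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) message("run_lefse: no feature passed both gates")
  class(out) <- c("lefse_result", "data.frame")
  attr(out, "tested") <- tested
  out
}

empty_lefse_result <- function() {
  structure(data.frame(feature = character(0), p = numeric(0), q = numeric(0),
                       lda_score = numeric(0), enriched_group = character(0),
                       stringsAsFactors = FALSE),
            class = c("lefse_result", "data.frame"))
}
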