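# Distance-based permutation tests (PERMANOVA, ANOSIM).
#
# Both tests permute group labels over a fixed distance matrix. When the
# total number of distinct label assignments is small (<= max_exhaustive)
# the null distribution is enumerated exhaustively and the p-value is the
# exact proportion of assignments with a statistic at least as extreme as
# the observed one; otherwise Monte-Carlo permutations are used with the
# (b + 1) / (m + 1) estimator, which never reports p = 0.

# all distinct assignments of labels with the given group sizes, as an
# integer matrix (assignments x n); assignment k gives the group index of
# each position
label_assignments <- function(sizes) {
  n <- sum(sizes)
  rec <- function(positions, g) {
    if (g == length(sizes))
      return(matrix(positions, nrow = 1))
    ch <- combn(positions, sizes[g])
    out <- vector("list", ncol(ch))
    for (j in seq_len(ncol(ch))) {
      rest <- rec(setdiff(positions, ch[, j]), g + 1)
      out[[j]] <- cbind(matrix(rep(ch[, j], nrow(rest)), nrow = nrow(rest),
                               byrow = TRUE), rest)
    }
    do.call(rbind, out)
  }
  ord <- rec(seq_len(n), 1)
  # ord rows list positions grouped by label; convert to per-position labels
  t(apply(ord, 1, function(r) {
    gi <- integer(n)
    at <- 1L
    for (g in seq_along(sizes)) {
      gi[r[at:(at + sizes[g] - 1L)]] <- g
      at <- at + sizes[g]
    }
    gi
  }))
}

n_assignments <- function(sizes) {
  exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
}

check_grouping <- function(m, groups) {
  if (length(groups) != nrow(m))
    stop("groups length must match the number of samples")
  g <- factor(groups)
  if (nlevels(g) < 2)
    stop("degenerate design: need at least two groups")
  if (any(table(g) < 2))
    stop("degenerate design: every group needs at least two samples")
  g
}

perm_engine <- function(stat_fun, gi, sizes, n_perm, seed, max_exhaustive) {
  obs <- stat_fun(gi)
  eps <- 1e-12
  if (n_assignments(sizes) <= max_exhaustive) {
    la <- label_assignments(sizes)
    stats <- apply(la, 1, stat_fun)
    ge <- if (is.infinite(obs)) sum(is.infinite(stats) & stats > 0)
          else sum(stats >= obs - eps)
    list(statistic = obs, p = ge / nrow(la), n_perm = nrow(la),
         exhaustive = TRUE)
  } else {
    stats <- with_seed(seed, vapply(seq_len(n_perm),
                                    function(i) stat_fun(sample(gi)),
                                    numeric(1)))
    ge <- if (is.infinite(obs)) sum(is.infinite(stats) & stats > 0)
          else sum(stats >= obs - eps)
    list(statistic = obs, p = (ge + 1) / (n_perm + 1), n_perm = n_perm,
         exhaustive = FALSE)
  }
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-way PERMANOVA on a distance matrix. Sums of squares are computed from
#' squared distances (`SS_T = sum d_ij^2 / N` over unordered pairs, within-
#' group terms analogously), giving the pseudo-F
#' `[SS_B / (a - 1)] / [SS_W / (N - a)]`. The p-value is by label
#' permutation; designs with at most `max_exhaustive` distinct label
#' assignments are enumerated exhaustively (exact p). A design whose
#' within-group sum of squares is zero yields an infinite pseudo-F, which is
#' flagged.
#'
#' @param d `dist` object or symmetric distance matrix.
#' @param groups Group label per sample (>= 2 groups, each >= 2 samples).
#' @param n_perm Monte-Carlo permutations when enumeration is not triggered.
#' @param seed Optional integer seed for the Monte-Carlo path.
#' @param max_exhaustive Enumeration threshold on the number of distinct
#'   label assignments (default 10000).
#' @return List of class `permanova`: `pseudo_F`, `p`, `df`, `n_perm`,
#'   `exhaustive`, `infinite_F`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL,
                      max_exhaustive = 10000) {
  m <- as.matrix(d)
  g <- check_grouping(m, groups)
  gi <- as.integer(g)
  sizes <- as.integer(table(g))
  n <- nrow(m); a <- nlevels(g)
  d2 <- m^2
  ss_t <- sum(d2) / (2 * n)
  fstat <- function(gidx) {
    ss_w <- 0
    for (k in seq_len(a)) {
      idx <- gidx == k
      ss_w <- ss_w + sum(d2[idx, idx]) / (2 * sum(idx))
    }
    if (ss_w <= 1e-14 * max(ss_t, 1)) return(Inf)
    ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
  }
  r <- perm_engine(fstat, gi, sizes, n_perm, seed, max_exhaustive)
  structure(list(pseudo_F = r$statistic, p = r$p,
                 df = c(between = a - 1, within = n - a),
                 n_perm = r$n_perm, exhaustive = r$exhaustive,
                 infinite_F = is.infinite(r$statistic)),
            class = "permanova")
}

#' Analysis of similarities (ANOSIM)
#'
#' `R = (mean between-group rank - mean within-group rank) / (n (n - 1) / 4)`
#' on the midranks of all pairwise distances; `R` lies in `[-1, 1]`, with 1
#' when every between-group distance outranks every within-group distance.
#' Permutation p-value as in [permanova()], including automatic exhaustive
#' enumeration on small designs.
#'
#' @inheritParams permanova
#' @return List of class `cd_anosim`: `R`, `p`, `n_perm`, `exhaustive`.
#' @export
anosim <- function(d, groups, n_perm = 999, seed = NULL,
                   max_exhaustive = 10000) {
  m <- as.matrix(d)
  g <- check_grouping(m, groups)
  gi <- as.integer(g)
  sizes <- as.integer(table(g))
  n <- nrow(m)
  ut <- upper.tri(m)
  rk <- rank(m[ut])  # midranks over the n(n-1)/2 pairs
  pair_i <- row(m)[ut]; pair_j <- col(m)[ut]
  denom <- n * (n - 1) / 4
  rstat <- function(gidx) {
    w <- gidx[pair_i] == gidx[pair_j]
    (mean(rk[!w]) - mean(rk[w])) / denom
  }
  r <- perm_engine(rstat, gi, sizes, n_perm, seed, max_exhaustive)
  structure(list(R = r$statistic, p = r$p, n_perm = r$n_perm,
                 exhaustive = r$exhaustive),
            class = "cd_anosim")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %s (df %d, %d), p = %.4g [%s, %d perms]%s\n",
              format(x$pseudo_F, digits = 4), x$df[1], x$df[2], x$p,
              if (x$exhaustive) "exhaustive" else "sampled", x$n_perm,
              if (x$infinite_F) " (zero within-group SS)" else ""))
  invisible(x)
}

#' @export
print.cd_anosim <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g [%s, %d perms]\n", x$R, x$p,
              if (x$exhaustive) "exhaustive" else "sampled", x$n_perm))
  invisible(x)
}
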