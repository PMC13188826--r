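# Independent oracles used to check the package's statistics on tiny inputs.
# These deliberately take different computational routes from the
# implementations they validate.

# Mann-Whitney U and two-sided p by direct enumeration of every assignment
# of the pooled observations to the x-group, counting x > y pairs directly.
brute_rank_sum <- function(x, y) {
  pool <- c(x, y)
  n <- length(x); N <- length(pool)
  u_of <- function(xi, yi) {
    sum(outer(xi, yi, ">")) + 0.5 * sum(outer(xi, yi, "=="))
  }
  u_obs <- u_of(x, y)
  sel <- utils::combn(N, n)
  us <- apply(sel, 2, function(ix) u_of(pool[ix], pool[-ix]))
  mid <- n * (N - n) / 2
  list(U = u_obs, p = mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9))
}

# BH q-values from the defining minimum: q_i = min_{j: p_j >= p_i} m p_(j) / j
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- sapply(seq_len(m), function(i)
    min(1, min(m * p[o][i:m] / (i:m))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# tiny labelled count matrix
tiny_table <- function(values, n_features, n_samples,
                       features = sprintf("f%02d", seq_len(n_features)),
                       samples = sprintf("s%02d", seq_len(n_samples))) {
  matrix(values, n_features, n_samples, dimnames = list(features, samples))
}

null_sim_config <- function(seed, n_per_group = 15, n_species = 100,
                            depth = 5e4) {
  omics_sim_config(n_per_group = n_per_group, n_species = n_species,
                   n_diff_mg = 0, n_diff_mt = 0, n_overlap = 0,
                   driver_activity_fold = 1, driver_phenotype_beta = 0,
                   depth = depth, seed = seed)
}
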