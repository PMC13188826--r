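# Internal helpers shared across modules.

# Deterministic sub-seed derivation: one global integer seed is split into
# independent streams for each sub-generator.  Kept below 2^31 - 1.
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 113 * k) %% 2147483647L)
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# stream is restored afterwards.  seed = NULL uses (and advances) the global
# stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_config <- function(field, why) {
  stop(sprintf("invalid configuration: field '%s' %s", field, why), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != round(x))
    stop_config(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_number <- function(x, field, lower = -Inf, upper = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < lower || x > upper)
    stop_config(field, sprintf("must be a single number in [%s, %s]", lower, upper))
  as.numeric(x)
}

# Total-sum scaling of a features x samples matrix; all-zero samples are left
# as zero columns.
tss <- function(mat, total = 1) {
  cs <- colSums(mat)
  cs[cs == 0] <- 1
  sweep(mat, 2, cs, "/") * total
}

# Midrank-based Spearman rho.
spearman_rho <- function(x, y) {
  cor(rank(x), rank(y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
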