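#' Preprocess an untargeted-metabolomics intensity matrix
#'
#' Ordered filter chain, mirroring the standard LC-MS workflow:
#' \enumerate{
#'   \item retain features non-zero in at least `min_prevalence` (default
#'     80\%, boundary inclusive) of the test (non-QC) samples;
#'   \item impute remaining zero/missing entries with the feature's minimum
#'     observed positive intensity;
#'   \item per-sample sum normalization;
#'   \item drop features whose relative standard deviation across the QC
#'     injections exceeds `max_qc_rsd` (default 30\%); skipped with a log
#'     notice when there are no QC samples;
#'   \item log10 transform.
#' }
#' Every step's drop count is recorded in the processing log. The returned
#' object is flagged as processed; preprocessing it again is a no-op, so
#' the chain is idempotent.
#'
#' @param raw Feature table / matrix of intensities (features x samples), or
#'   the list returned by [simulate_metabolome()].
#' @param is_qc Logical flag per sample column (ignored when `raw` carries
#'   its own flags).
#' @param min_prevalence Non-zero prevalence threshold over test samples.
#' @param max_qc_rsd QC relative-standard-deviation threshold.
#' @return List of class `metabo_matrix`: `data` (log10 matrix), `raw_norm`
#'   (normalized pre-log matrix), `is_qc`, `log` (character vector of
#'   processing messages), `processed = TRUE`.
#' @export
preprocess_metabolome <- function(raw, is_qc = NULL, min_prevalence = 0.8,
                                  max_qc_rsd = 0.3) {
  if (inherits(raw, "metabo_matrix")) {
    message("preprocess_metabolome: input already processed; returning as-is")
    return(raw)
  }
  if (is.list(raw) && !is.null(raw$intensities)) {
    is_qc <- is_qc %||% raw$is_qc
    raw <- raw$intensities
  }
  mat <- as.matrix(unclass(raw))
  if (is.null(is_qc)) is_qc <- rep(FALSE, ncol(mat))
  if (length(is_qc) != ncol(mat)) stop("is_qc must flag every sample column")
  if (!any(!is_qc)) stop("need at least one test (non-QC) sample")
  logm <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message("preprocess_metabolome: ", msg)
    logm <<- c(logm, msg)
  }
  test <- mat[, !is_qc, drop = FALSE]

  # (1) prevalence over test samples, boundary inclusive
  prev <- rowMeans(!is.na(test) & test > 0)
  keep <- prev >= min_prevalence
  note("prevalence filter (>= %d%% non-zero): dropped %d of %d features",
       round(100 * min_prevalence), sum(!keep), length(keep))
  mat <- mat[keep, , drop = FALSE]
  if (!nrow(mat)) stop("empty matrix: all features removed by the prevalence filter")

  # (2) minimum imputation per feature
  n_imp <- sum(is.na(mat) | mat == 0)
  if (n_imp > 0) {
    for (f in seq_len(nrow(mat))) {
      z <- is.na(mat[f, ]) | mat[f, ] == 0
      if (any(z)) mat[f, z] <- min(mat[f, !z])
    }
  }
  note("minimum-value imputation: %d entries", n_imp)

  # (3) per-sample sum normalization
  mat <- sweep(mat, 2, colSums(mat), "/")
  note("per-sample sum normalization applied")

  # (4) QC RSD filter
  if (any(is_qc)) {
    qc <- mat[, is_qc, drop = FALSE]
    rsd <- apply(qc, 1, sd) / rowMeans(qc)
    rsd[is.nan(rsd)] <- 0
    keep <- rsd <= max_qc_rsd
    note("QC RSD filter (<= %d%%): dropped %d of %d features",
         round(100 * max_qc_rsd), sum(!keep), length(keep))
    mat <- mat[keep, , drop = FALSE]
    if (!nrow(mat)) stop("empty matrix: all features removed by the QC RSD filter")
  } else {
    note("no QC samples: RSD filter skipped")
  }

  # (5) log10
  structure(list(data = log10(mat), raw_norm = mat, is_qc = is_qc,
                 log = logm, processed = TRUE),
            class = "metabo_matrix")
}

#' @export
print.metabo_matrix <- function(x, ...) {
  cat(sprintf("metabo_matrix: %d features x %d samples (%d QC)\n",
              nrow(x$data), ncol(x$data), sum(x$is_qc)))
  cat(paste0("  - ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' PLS-DA variable importance in projection (VIP)
#'
#' Fits a PLS1 regression (NIPALS) of the autoscaled feature matrix against
#' a centred +/-1 class vector and returns per-feature VIP scores,
#' `VIP_j = sqrt(p sum_a SSY_a w_aj^2 / sum_a SSY_a)` with unit-norm
#' component weights `w_a` and `SSY_a` the y-variance captured by component
#' `a`. The VIP normalization identity `sum_j VIP_j^2 = p` holds for every
#' fit. Components beyond the informative rank (negligible residual
#' X'y) are dropped automatically.
#'
#' @param x Processed matrix (features x samples), a `metabo_matrix`, or any
#'   numeric matrix.
#' @param groups Two-level class label per (test) sample.
#' @param n_components Number of PLS components (default 2).
#' @return Named numeric vector of VIP scores; the number of components
#'   actually used is attached as attribute `"n_components"`.
#' @export
plsda_vip <- function(x, groups, n_components = 2) {
  if (inherits(x, "metabo_matrix")) x <- x$data[, !x$is_qc, drop = FALSE]
  mat <- as.matrix(unclass(x))
  g <- factor(groups)
  if (nlevels(g) != 2) stop("design error: exactly two classes are required")
  if (any(tabulate(g) < 3)) stop("need at least 3 samples per class")
  if (ncol(mat) != length(groups))
    stop("groups length must match the number of samples")
  n_components <- check_count(n_components, "n_components", 1L)
  X <- t(mat)                                   # samples x features
  p <- ncol(X)
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  sdev[sdev == 0] <- 1
  X <- scale(X, center = mu, scale = sdev)
  y <- ifelse(g == levels(g)[1], 1, -1)
  y <- y - mean(y)
  ssy_tot <- sum(y^2)
  W <- matrix(0, p, 0); ssy <- numeric(0)
  Xa <- X; ya <- y
  for (a in seq_len(min(n_components, nrow(X) - 1L, p))) {
    wv <- crossprod(Xa, ya)[, 1]
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-10 * max(ssy_tot, 1)) break
    wv <- wv / nw
    tv <- Xa %*% wv
    tt <- sum(tv^2)
    if (tt < 1e-12) break
    pv <- crossprod(Xa, tv)[, 1] / tt
    b <- sum(tv * ya) / tt
    W <- cbind(W, wv); ssy <- c(ssy, b^2 * tt)
    Xa <- Xa - tv %*% t(pv)
    ya <- ya - b * tv
  }
  if (!ncol(W)) stop("PLS fit failed: no informative component")
  vip <- sqrt(p * as.vector(W^2 %*% ssy) / sum(ssy))
  names(vip) <- rownames(mat)
  attr(vip, "n_components") <- length(ssy)
  vip
}

#' Select differentially abundant metabolites (DAMs)
#'
#' Per feature: Welch t-test on the log10 data (BH-adjusted to q), fold
#' change from the raw-scale (de-logged, normalized) group means
#' (treated/control), fold-change magnitude `max(r, 1/r)`. A metabolite is
#' selected when `q < alpha_q`, `VIP > vip_min` and magnitude `> fc_min`;
#' direction (`up`/`down` in the treated group) follows the fold-change
#' sign.
#'
#' @param x A `metabo_matrix` from [preprocess_metabolome()].
#' @param groups Class label per test sample (two levels).
#' @param vip Named VIP vector from [plsda_vip()] (aligned by feature id).
#' @param treated,control Labels defining the fold-change direction.
#' @param alpha_q,vip_min,fc_min Gate thresholds (defaults 0.05, 1, 1).
#' @return Data.frame of class `dam_result`: `feature`, `VIP`, `p`, `q`,
#'   `fold_change`, `fc_magnitude`, `direction`, `selected`.
#' @export
select_dams <- function(x, groups, vip, treated = "treated",
                        control = "control", alpha_q = 0.05, vip_min = 1,
                        fc_min = 1) {
  stopifnot(inherits(x, "metabo_matrix"))
  dat <- x$data[, !x$is_qc, drop = FALSE]
  raw <- x$raw_norm[, !x$is_qc, drop = FALSE]
  if (!nrow(dat)) return(empty_dam_result())
  if (ncol(dat) != length(groups))
    stop("groups length must match the number of test samples")
  if (!is.null(names(vip))) {
    if (!all(rownames(dat) %in% names(vip)))
      stop("alignment error: VIP vector missing feature(s): ",
           paste(utils::head(setdiff(rownames(dat), names(vip)), 5),
                 collapse = ", "))
    vip <- vip[rownames(dat)]
  } else if (length(vip) != nrow(dat)) {
    stop("alignment error: VIP vector length does not match the matrix")
  }
  it <- groups == treated; ic <- groups == control
  if (!any(it) || !any(ic)) stop("both groups must be present")
  res <- do.call(rbind, lapply(seq_len(nrow(dat)), function(f) {
    a <- dat[f, it]; b <- dat[f, ic]
    p <- if (sd(a) == 0 && sd(b) == 0) 1 else t.test(a, b)$p.value
    r <- mean(raw[f, it]) / mean(raw[f, ic])
    data.frame(feature = rownames(dat)[f], VIP = unname(vip[f]), p = p,
               fold_change = r, fc_magnitude = max(r, 1 / r),
               direction = if (r >= 1) "up" else "down",
               stringsAsFactors = FALSE)
  }))
  res$q <- bh_adjust(res$p)
  res$selected <- res$q < alpha_q & res$VIP > vip_min & res$fc_magnitude > fc_min
  res <- res[, c("feature", "VIP", "p", "q", "fold_change", "fc_magnitude",
                 "direction", "selected")]
  class(res) <- c("dam_result", "data.frame")
  res
}

empty_dam_result <- function() {
  structure(data.frame(feature = character(0), VIP = numeric(0),
                       p = numeric(0), q = numeric(0),
                       fold_change = numeric(0), fc_magnitude = numeric(0),
                       direction = character(0), selected = logical(0),
                       stringsAsFactors = FALSE),
            class = c("dam_result", "data.frame"))
}

#' Fisher-exact category enrichment
#'
#' For each category, builds the 2x2 table (selected-in-category,
#' selected-outside, unselected-in-category, unselected-outside) over the
#' universe and computes the one-sided (upper-tail hypergeometric) Fisher
#' exact p-value, BH-adjusted across categories. Empty categories (no
#' member in the universe) are skipped with a log notice.
#'
#' @param selected Ids of the hits (must be a subset of `universe`).
#' @param universe All tested ids.
#' @param category_map Named list: category -> member ids.
#' @return Data.frame: `category`, `n_selected`, `n_category`, `odds_ratio`
#'   (sample estimate), `p`, `q`.
#' @examples
#' fisher_enrichment(c("a", "b", "c", "d"), letters[1:8],
#'   list(cat1 = c("a", "b", "c", "e")))  # p = 17/70
#' @export
fisher_enrichment <- function(selected, universe, category_map) {
  if (!all(selected %in% universe))
    stop("selected ids must be a subset of the universe")
  n <- length(universe)
  rows <- lapply(names(category_map), function(cat) {
    members <- intersect(category_map[[cat]], universe)
    if (!length(members)) {
      message("fisher_enrichment: category '", cat,
              "' has no member in the universe; skipped")
      return(NULL)
    }
    a <- length(intersect(selected, members))
    b <- length(selected) - a
    c_ <- length(members) - a
    d <- n - a - b - c_
    p <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                     alternative = "greater")$p.value
    orr <- if (b * c_ == 0) Inf else (a * d) / (b * c_)
    data.frame(category = cat, n_selected = a, n_category = length(members),
               odds_ratio = orr, p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(category = character(0), n_selected = integer(0),
                      n_category = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), q = numeric(0)))
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
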