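#' Per-species transcriptional activity (MT/MG ratio)
#'
#' Activity is the ratio of a species' relative abundance in the
#' metatranscriptome to its relative abundance in the metagenome, per
#' sample: `activity = (relMT + eps) / (relMG + eps)` on total-sum-scaled
#' abundances. The pseudocount `eps` is half the smallest non-zero relative
#' abundance across both layers, applied symmetrically so MG and MT zeros
#' are treated alike. Species whose MG abundance is zero in more than half
#' of the samples are flagged as low-support (their ratios are dominated by
#' the pseudocount) and are excluded from downstream testing.
#'
#' @param mg,mt [feature_table()]s (or matrices) over the same sample ids.
#' @param species Species ids to score; default: all species present in both
#'   tables.
#' @return List of class `activity_table`: `activity` (species x samples),
#'   `epsilon`, `low_support` (named logical).
#' @export
compute_activity <- function(mg, mt, species = NULL) {
  mg <- as.matrix(unclass(mg)); mt <- as.matrix(unclass(mt))
  if (is.null(colnames(mg)) || is.null(colnames(mt)))
    stop("both tables need sample ids")
  if (!setequal(colnames(mg), colnames(mt))) {
    off <- c(setdiff(colnames(mg), colnames(mt)),
             setdiff(colnames(mt), colnames(mg)))
    stop("sample ids differ between layers: ", paste(off, collapse = ", "))
  }
  mt <- mt[, colnames(mg), drop = FALSE]
  if (is.null(species)) species <- intersect(rownames(mg), rownames(mt))
  miss <- setdiff(species, intersect(rownames(mg), rownames(mt)))
  if (length(miss))
    stop("species absent from a layer: ", paste(miss, collapse = ", "))
  rel_mg <- tss(mg); rel_mt <- tss(mt)
  nz <- c(rel_mg[rel_mg > 0], rel_mt[rel_mt > 0])
  if (!length(nz)) stop("both tables are entirely zero")
  eps <- min(nz) / 2
  act <- (rel_mt[species, , drop = FALSE] + eps) /
         (rel_mg[species, , drop = FALSE] + eps)
  low <- rowMeans(mg[species, , drop = FALSE] == 0) > 0.5
  if (any(low))
    message("compute_activity: ", sum(low),
            " species flagged low-MG-support and excluded from testing")
  structure(list(activity = act, epsilon = eps, low_support = low),
            class = "activity_table")
}

#' Intersect differential-species calls from two omics layers
#'
#' @param mg_diff,mt_diff Results of [run_lefse()] on the metagenome and
#'   metatranscriptome tables (or data.frames with `feature` and
#'   `enriched_group` columns).
#' @return Data.frame with one row per shared feature: `feature`,
#'   `mg_enriched_group`, `mt_enriched_group`, `concordant` (same enrichment
#'   direction in both layers).
#' @export
intersect_differentials <- function(mg_diff, mt_diff) {
  shared <- intersect(mg_diff$feature, mt_diff$feature)
  mgd <- mg_diff$enriched_group[match(shared, mg_diff$feature)]
  mtd <- mt_diff$enriched_group[match(shared, mt_diff$feature)]
  out <- data.frame(feature = shared, mg_enriched_group = mgd,
                    mt_enriched_group = mtd, concordant = mgd == mtd,
                    stringsAsFactors = FALSE)
  out[order(out$feature), , drop = FALSE]
}

#' Spearman rank correlation with permutation or t-approximation p-value
#'
#' Midranks are used for ties. For `n <= 9` the two-sided p-value is exact,
#' from full enumeration of rank permutations; for larger samples the
#' t-approximation `t = rho sqrt((n - 2) / (1 - rho^2))` is used.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @param mode `"auto"`, `"exact"` or `"approximate"`.
#' @return List: `rho`, `p`, `mode` used. A constant input gives `rho = NA`.
#' @export
spearman_test <- function(x, y, mode = c("auto", "exact", "approximate")) {
  mode <- match.arg(mode)
  n <- length(x)
  if (length(y) != n || n < 3) stop("x and y must share length >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    message("spearman_test: constant input, correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, mode = "degenerate"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (mode == "auto") mode <- if (n <= 9) "exact" else "approximate"
  if (mode == "exact") {
    if (n > 9) stop("exact mode is limited to n <= 9")
    perms <- all_permutations(n)
    rxc <- rx - mean(rx); ryc <- ry - mean(ry)
    num <- as.vector(matrix(ryc[perms], nrow(perms)) %*% rxc)
    rhos <- num / sqrt(sum(rxc^2) * sum(ryc^2))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1 - 1e-15) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), n - 2)
    }
  }
  list(rho = rho, p = p, mode = mode)
}

# all permutations of 1..n as a matrix (n! x n); n <= 9
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- k
    tmp <- sub
    tmp[tmp >= k] <- tmp[tmp >= k] + 1L
    out[rows, -1L] <- tmp
  }
  out
}

#' Correlate species activity with host phenotypes
#'
#' Spearman correlation of each species' per-sample activity ratio with the
#' abdominal fat percentage (AFP), abdominal fat weight (AFW) and body
#' weight (BW).
#'
#' @param act An `activity_table` from [compute_activity()].
#' @param meta Sample metadata data.frame with `sample_id`, `BW`, `AFW`
#'   (AFP is computed as AFW/BW when absent); >= 5 phenotyped samples.
#' @return Data.frame: one row per species with `rho_AFP`, `p_AFP`,
#'   `rho_AFW`, `p_AFW`, `rho_BW`, `p_BW`.
#' @export
correlate_activity_phenotype <- function(act, meta) {
  stopifnot(inherits(act, "activity_table"))
  if (is.null(meta$AFP)) meta$AFP <- meta$AFW / meta$BW
  ids <- intersect(colnames(act$activity), meta$sample_id)
  if (length(ids) < 5) stop("need at least 5 samples with phenotypes")
  a <- act$activity[, ids, drop = FALSE]
  ph <- meta[match(ids, meta$sample_id), ]
  one <- function(v, y) spearman_test(v, y)
  res <- lapply(rownames(a), function(sp) {
    v <- a[sp, ]
    afp <- one(v, ph$AFP); afw <- one(v, ph$AFW); bw <- one(v, ph$BW)
    data.frame(feature = sp, rho_AFP = afp$rho, p_AFP = afp$p,
               rho_AFW = afw$rho, p_AFW = afw$p,
               rho_BW = bw$rho, p_BW = bw$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Select candidate driver species
#'
#' Applies the full candidate gate to the species shared by both
#' differential lists: a species is selected when (1) it is enriched in the
#' same group on both omics layers, (2) its activity differs between groups
#' (rank-sum `p < alpha`) with the higher activity in that same group,
#' (3) its activity correlates positively with both AFP and AFW at
#' `p < alpha`, and (4) it is not low-MG-support. Selected species are
#' ranked by decreasing `rho_AFP`, ties broken by smaller activity p.
#'
#' @param overlap Result of [intersect_differentials()].
#' @param act An `activity_table` from [compute_activity()].
#' @param corr Result of [correlate_activity_phenotype()].
#' @param groups Named group label per sample (names = sample ids), or a
#'   vector aligned with the activity columns.
#' @param alpha Significance gate (default 0.05).
#' @return Data.frame of class `candidate_report`: one row per overlap
#'   species with the per-layer directions, activity test, correlations,
#'   `selected` flag and `rank`.
#' @export
select_candidates <- function(overlap, act, corr, groups, alpha = 0.05) {
  stopifnot(inherits(act, "activity_table"))
  if (!is.null(names(groups)))
    groups <- groups[colnames(act$activity)]
  g <- factor(groups)
  if (nrow(overlap) == 0) {
    out <- data.frame(feature = character(0), mg_enriched_group = character(0),
                      mt_enriched_group = character(0),
                      activity_p = numeric(0), activity_higher_in = character(0),
                      rho_AFP = numeric(0), p_AFP = numeric(0),
                      rho_AFW = numeric(0), p_AFW = numeric(0),
                      rho_BW = numeric(0), p_BW = numeric(0),
                      low_support = logical(0), selected = logical(0),
                      rank = integer(0), stringsAsFactors = FALSE)
    class(out) <- c("candidate_report", "data.frame")
    return(out)
  }
  i1 <- g == levels(g)[1]
  rows <- lapply(seq_len(nrow(overlap)), function(k) {
    sp <- overlap$feature[k]
    low <- isTRUE(act$low_support[sp])
    v <- act$activity[sp, ]
    if (!low) {
      ts <- rank_sum_test(v[i1], v[!i1])
      higher <- if (mean(v[i1]) >= mean(v[!i1])) levels(g)[1] else levels(g)[2]
      act_p <- ts$p
    } else {
      act_p <- NA_real_; higher <- NA_character_
    }
    cr <- corr[match(sp, corr$feature), ]
    data.frame(feature = sp,
               mg_enriched_group = overlap$mg_enriched_group[k],
               mt_enriched_group = overlap$mt_enriched_group[k],
               activity_p = act_p, activity_higher_in = higher,
               rho_AFP = cr$rho_AFP, p_AFP = cr$p_AFP,
               rho_AFW = cr$rho_AFW, p_AFW = cr$p_AFW,
               rho_BW = cr$rho_BW, p_BW = cr$p_BW,
               low_support = low, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$selected <- !out$low_support &
    out$mg_enriched_group == out$mt_enriched_group &
    !is.na(out$activity_p) & out$activity_p < alpha &
    out$activity_higher_in == out$mg_enriched_group &
    !is.na(out$rho_AFP) & out$rho_AFP > 0 & out$p_AFP < alpha &
    !is.na(out$rho_AFW) & out$rho_AFW > 0 & out$p_AFW < alpha
  out$selected[is.na(out$selected)] <- FALSE
  out$rank <- NA_integer_
  sel <- which(out$selected)
  if (length(sel)) {
    ord <- sel[order(-out$rho_AFP[sel], out$activity_p[sel])]
    out$rank[ord] <- seq_along(ord)
  }
  out <- out[order(!out$selected, out$rank, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_report", "data.frame")
  out
}
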