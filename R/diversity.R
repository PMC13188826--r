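#' Alpha-diversity estimators
#'
#' Computes observed richness, Chao1, ACE and Shannon entropy per sample.
#' Chao1 uses the classic estimator `S_obs + F1^2 / (2 F2)` when doubletons
#' exist and the bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`
#' when `F2 = 0`. ACE follows the EstimateS convention with the rare-species
#' abundance cutoff at 10; when every rare species is a singleton the
#' coverage estimate degenerates and the bias-corrected Chao1 is reported in
#' its place. Shannon entropy is in nats.
#'
#' @param counts Non-negative integer vector of species counts for one
#'   sample, or a features x samples matrix / [feature_table()].
#' @return For a vector, a one-row data.frame with `S_obs`, `chao1`, `ACE`,
#'   `shannon`; for a matrix, one row per sample.
#' @examples
#' alpha_diversity(c(5, 1, 1, 2, 3))  # Chao1 = 7
#' @export
alpha_diversity <- function(counts) {
  if (is.matrix(counts)) {
    out <- do.call(rbind, lapply(seq_len(ncol(counts)),
                                 function(j) alpha_diversity(counts[, j])))
    out$sample_id <- colnames(counts)
    return(out[, c("sample_id", "S_obs", "chao1", "ACE", "shannon")])
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  x <- counts[counts > 0]
  if (!length(x)) stop("empty sample: all counts are zero")
  s_obs <- length(x)
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  chao1 <- if (f2 > 0) s_obs + f1^2 / (2 * f2)
           else s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  # ACE (EstimateS): rare = abundance <= 10
  rare <- x[x <= 10]
  s_abund <- sum(x > 10); s_rare <- length(rare)
  n_rare <- sum(rare)
  if (s_rare == 0) {
    ace <- s_obs
  } else if (f1 == n_rare) {
    ace <- chao1_bc(s_obs, f1, f2)  # undefined coverage; Chao1 fallback
  } else {
    c_ace <- 1 - f1 / n_rare
    fi <- tabulate(rare, nbins = 10)
    g2 <- max(s_rare / c_ace * sum(seq_len(10) * (seq_len(10) - 1) * fi) /
                (n_rare * (n_rare - 1)) - 1, 0)
    ace <- s_abund + s_rare / c_ace + f1 / c_ace * g2
  }
  p <- x / sum(x)
  data.frame(S_obs = s_obs, chao1 = chao1, ACE = ace,
             shannon = -sum(p * log(p)))
}

chao1_bc <- function(s_obs, f1, f2) s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))

#' Bray-Curtis dissimilarity matrix
#'
#' `d(u, v) = sum |u - v| / sum (u + v)` over features, computed with
#' [vegan::vegdist()]. A pair in which both samples are entirely zero has an
#' undefined dissimilarity; it is set to 0 with a log notice.
#'
#' @param table A [feature_table()] or features x samples matrix with
#'   non-negative entries and at least two samples.
#' @param normalize If `TRUE`, apply total-sum scaling per sample first.
#' @return A `dist` object over samples.
#' @examples
#' m <- cbind(s1 = c(6, 0, 2), s2 = c(2, 4, 0))
#' rownames(m) <- paste0("sp", 1:3)
#' bray_curtis(m)  # 10/14
#' @export
bray_curtis <- function(table, normalize = FALSE) {
  mat <- as.matrix(unclass(table))
  if (any(mat < 0)) stop("negative entries are not allowed")
  if (ncol(mat) < 2) stop("need at least two samples")
  if (normalize) mat <- tss(mat)
  d <- suppressWarnings(vegan::vegdist(t(mat), method = "bray"))
  if (anyNA(d)) {
    message("bray_curtis: ", sum(is.na(d)),
            " all-zero sample pair(s); their distance is defined as 0")
    d[is.na(d)] <- 0
  }
  d
}

#' Principal coordinate analysis
#'
#' Classical metric scaling of a distance matrix: the Gower-centered matrix
#' `-1/2 J D^2 J` is eigendecomposed; coordinates are eigenvectors scaled by
#' the square root of their (positive) eigenvalues. Axes with non-positive
#' eigenvalues are discarded; negative eigenvalues, which arise for
#' non-Euclidean dissimilarities such as Bray-Curtis, are reported.
#'
#' @param d A `dist` object or symmetric matrix with zero diagonal.
#' @return A list of class `pcoa_ordination`: `points` (samples x retained
#'   axes), `eigenvalues` (retained, non-increasing), `negative_eigenvalues`,
#'   and `proportion_explained` (relative to the sum of positive
#'   eigenvalues).
#' @export
pcoa <- function(d) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix must have zero diagonal")
  n <- nrow(m)
  a <- -0.5 * m^2
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  e <- eigen(g, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > max(tol, 0)
  if (!any(pos)) {
    pts <- matrix(0, n, 1, dimnames = list(rownames(m), "Axis1"))
    return(structure(list(points = pts, eigenvalues = 0,
                          negative_eigenvalues = e$values[e$values < -tol],
                          proportion_explained = 1),
                     class = "pcoa_ordination"))
  }
  ev <- e$values[pos]
  pts <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev), length(ev))
  dimnames(pts) <- list(rownames(m), paste0("Axis", seq_along(ev)))
  structure(list(points = pts, eigenvalues = ev,
                 negative_eigenvalues = e$values[e$values < -tol],
                 proportion_explained = ev / sum(ev)),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat("PCoA:", nrow(x$points), "samples,", length(x$eigenvalues),
      "retained axes\n")
  cat("proportion explained:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$proportion_explained, 3)),
            collapse = ", "), "\n")
  if (length(x$negative_eigenvalues))
    cat(length(x$negative_eigenvalues), "negative eigenvalues discarded\n")
  invisible(x)
}
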