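#' Screen paired omics layers for phenotype-driving microbes
#'
#' The package's central estimator. Given paired metagenome (DNA) and
#' metatranscriptome (RNA) species-abundance tables over the same samples
#' and per-sample adiposity phenotypes, it
#' \enumerate{
#'   \item runs the LEfSe-style screen ([run_lefse()]) on each layer,
#'   \item intersects the differential species
#'     ([intersect_differentials()]),
#'   \item computes per-sample transcriptional activity ratios
#'     ([compute_activity()]),
#'   \item correlates activity with AFP, AFW and BW
#'     ([correlate_activity_phenotype()]), and
#'   \item applies the candidate gate ([select_candidates()]): concordant
#'     enrichment on both layers, significantly higher activity in the
#'     enriched group, and positive activity-phenotype correlation.
#' }
#'
#' @param mg,mt [feature_table()]s (features x samples) for the metagenome
#'   and metatranscriptome layers, sharing sample ids.
#' @param meta Sample metadata data.frame: `sample_id`, `group` (two
#'   levels), `BW`, `AFW` (AFP derived as AFW/BW when absent).
#' @param config A [lefse_config()]; its `alpha` also gates the activity and
#'   correlation tests unless `alpha` is given.
#' @param alpha Significance gate for the activity and correlation stages
#'   (defaults to `config$alpha`).
#' @return An object of class `driver_screen` with components `mg_diff`,
#'   `mt_diff`, `overlap`, `activity`, `correlations`, `candidates`,
#'   `groups`, `meta`, `config`, `alpha` and `call`.
#' @examples
#' sim <- simulate_paired_omics(omics_sim_config(n_per_group = 8,
#'   n_species = 60, depth = 2e4, seed = 11))
#' fit <- driver_screen(sim$mg, sim$mt, sim$metadata,
#'   config = lefse_config(seed = 11))
#' print(fit)
#' @export
driver_screen <- function(mg, mt, meta, config = lefse_config(),
                          alpha = config$alpha) {
  cl <- match.call()
  need <- c("sample_id", "group", "BW", "AFW")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("meta missing column(s): ", paste(miss, collapse = ", "))
  ids <- colnames(mg)
  if (!setequal(ids, meta$sample_id))
    stop("metadata sample ids do not match the feature tables")
  meta <- meta[match(ids, meta$sample_id), ]
  if (is.null(meta$AFP)) meta$AFP <- meta$AFW / meta$BW
  groups <- setNames(as.character(meta$group), meta$sample_id)

  mg_diff <- run_lefse(mg, groups[colnames(mg)], config)
  mt_diff <- run_lefse(mt, groups[colnames(mt)], config)
  overlap <- intersect_differentials(mg_diff, mt_diff)
  act <- compute_activity(mg, mt)
  corr <- if (nrow(overlap))
    correlate_activity_phenotype(
      structure(list(activity = act$activity[overlap$feature, , drop = FALSE],
                     epsilon = act$epsilon,
                     low_support = act$low_support[overlap$feature]),
                class = "activity_table"),
      meta)
  else data.frame(feature = character(0), rho_AFP = numeric(0),
                  p_AFP = numeric(0), rho_AFW = numeric(0),
                  p_AFW = numeric(0), rho_BW = numeric(0), p_BW = numeric(0))
  cand <- select_candidates(overlap, act, corr, groups, alpha = alpha)

  structure(list(mg_diff = mg_diff, mt_diff = mt_diff, overlap = overlap,
                 activity = act, correlations = corr, candidates = cand,
                 groups = groups, meta = meta, config = config,
                 alpha = alpha, call = cl),
            class = "driver_screen")
}

#' @export
print.driver_screen <- function(x, ...) {
  cat("Driver screen (paired MG/MT)\n")
  cat(sprintf("  samples: %d (%s)\n", length(x$groups),
              paste(sprintf("%s n=%d", names(table(x$groups)),
                            as.integer(table(x$groups))), collapse = ", ")))
  cat(sprintf("  differential species: %d MG, %d MT, %d overlapping\n",
              nrow(x$mg_diff), nrow(x$mt_diff), nrow(x$overlap)))
  sel <- x$candidates[x$candidates$selected, , drop = FALSE]
  if (nrow(sel)) {
    cat(sprintf("  selected candidate driver(s): %s\n",
                paste(sel$feature, collapse = ", ")))
  } else cat("  no candidate passed the full gate\n")
  invisible(x)
}

#' @export
summary.driver_screen <- function(object, ...) {
  structure(list(fit = object), class = "summary.driver_screen")
}

#' @export
print.summary.driver_screen <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("\nGates: rank-sum p < %.3g, LDA score > %.2f, activity and\n",
              f$config$alpha, f$config$lda_threshold))
  cat(sprintf("correlation alpha = %.3g; pseudocount eps = %.3g\n\n",
              f$alpha, f$activity$epsilon))
  if (nrow(f$candidates)) {
    cat("Candidate report (overlap species):\n")
    print(as.data.frame(f$candidates), digits = 3, row.names = FALSE)
  } else cat("Empty overlap: no species differential on both layers.\n")
  invisible(x)
}

#' Candidate report of a driver screen
#'
#' @param object A `driver_screen` fit.
#' @param ... Unused.
#' @return The candidate report data.frame (one row per overlap species).
#' @export
coef.driver_screen <- function(object, ...) {
  as.data.frame(object$candidates)
}

#' Plot a driver screen
#'
#' Scatter of the top candidate's per-sample activity ratio against
#' abdominal fat weight, coloured by group, with the Spearman rho in the
#' title. Falls back to the per-layer effect-size profile when no candidate
#' was selected.
#'
#' @param x A `driver_screen` fit.
#' @param ... Passed to [plot()].
#' @export
plot.driver_screen <- function(x, ...) {
  sel <- x$candidates[x$candidates$selected, , drop = FALSE]
  if (nrow(sel)) {
    sp <- sel$feature[1]
    v <- x$activity$activity[sp, x$meta$sample_id]
    col <- as.integer(factor(x$meta$group)) + 1L
    plot(v, x$meta$AFW, col = col, pch = 19,
         xlab = sprintf("%s activity (MT/MG)", sp),
         ylab = "abdominal fat weight (g)",
         main = sprintf("%s: rho_AFW = %.2f", sp, sel$rho_AFW[1]), ...)
    graphics::legend("topleft", legend = levels(factor(x$meta$group)),
                     col = 2:3, pch = 19, bty = "n")
  } else {
    tested <- attr(x$mg_diff, "tested")
    plot(sort(tested$lda_score, decreasing = TRUE), type = "h",
         xlab = "feature rank", ylab = "LDA score (MG layer)",
         main = "no selected candidate", ...)
    graphics::abline(h = x$config$lda_threshold, lty = 2)
  }
  invisible(x)
}
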