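#' Adipocyte stereology from section areas
#'
#' Adipocytes are treated as spheres sectioned at their equator: each
#' measured area gives a diameter `d = 2 sqrt(A / pi)`. With the sample
#' mean `d_bar` and standard deviation `s` (n - 1 denominator) of the
#' diameters, the mean cell volume is
#' `V_bar = (pi / 6) (3 s^2 d_bar + d_bar^3)` - the spherical volume
#' corrected for diameter dispersion, exact when the diameter distribution
#' has zero third central moment. The total adipocyte number is
#' `N = W / (0.915 V_bar)` with the fat-pad mass `W` in grams, fat density
#' 0.915 g/mL and `V_bar` converted to mL (1 mL = 1e12 um^3).
#'
#' @param areas Cell section areas (um^2), at least 10 positive values; or a
#'   panel list from [simulate_adipocyte_panels()] (fields `areas_um2`,
#'   `W_g`).
#' @param W Fat-pad mass (g, >= 0). Ignored when `areas` is a panel.
#' @param density Adipose tissue density (g/mL), default 0.915.
#' @return List of class `stereology_result`: `d_bar` (um), `s` (um),
#'   `V_bar_um3`, `V_bar_mL`, `N`, `n_cells`, `W_g`, `density`.
#' @examples
#' r <- adipocyte_stereology(rep(78.5398, 12), W = 0)
#' r$d_bar  # 10 um
#' @export
adipocyte_stereology <- function(areas, W = NULL, density = 0.915) {
  if (is.list(areas) && !is.null(areas$areas_um2)) {
    W <- W %||% areas$W_g
    areas <- areas$areas_um2
  }
  if (is.null(W)) stop("fat-pad mass W (g) is required")
  if (length(areas) < 10) stop("insufficient data: need at least 10 cells")
  if (any(areas <= 0)) stop("cell areas must be positive")
  if (W < 0) stop("fat-pad mass must be non-negative")
  d <- 2 * sqrt(areas / pi)
  d_bar <- mean(d)
  s <- sd(d)
  v_um3 <- pi / 6 * (3 * s^2 * d_bar + d_bar^3)
  v_ml <- v_um3 / 1e12
  structure(list(d_bar = d_bar, s = s, V_bar_um3 = v_um3, V_bar_mL = v_ml,
                 N = W / (density * v_ml), n_cells = length(areas),
                 W_g = W, density = density),
            class = "stereology_result")
}

#' @export
print.stereology_result <- function(x, ...) {
  cat(sprintf(paste0("Adipocyte stereology (%d cells): d_bar = %.2f um, ",
                     "s = %.2f um,\n  V_bar = %.1f um^3, N = %.3g ",
                     "(W = %.3g g, density %.3f g/mL)\n"),
              x$n_cells, x$d_bar, x$s, x$V_bar_um3, x$N, x$W_g, x$density))
  invisible(x)
}

#' Stereology over a panel of individuals
#'
#' @param panels List of panels (see [simulate_adipocyte_panels()]).
#' @return Data.frame with one row per individual: id, group, `d_bar`, `s`,
#'   `V_bar_um3`, `N`, and `N_true` when recorded.
#' @export
adipocyte_stereology_panel <- function(panels) {
  do.call(rbind, lapply(panels, function(p) {
    r <- adipocyte_stereology(p$areas_um2, W = p$W_g)
    data.frame(individual_id = p$individual_id, group = p$group,
               d_bar = r$d_bar, s = r$s, V_bar_um3 = r$V_bar_um3, N = r$N,
               N_true = p$N_true %||% NA_real_, stringsAsFactors = FALSE)
  }))
}

#' Compare villus morphometry between two groups
#'
#' Per shared numeric metric (villus length, middle width, area, goblet
#' cells per villus, crypt depth, length/crypt ratio, mucosal and muscle
#' thickness, ...), reports group means with SEM and the two-sided Welch
#' t-test p-value. A BH adjustment across metrics is available but off by
#' default, matching the per-metric reporting convention of morphometry
#' studies.
#'
#' @param groupA,groupB Data.frames of per-individual metrics (>= 3 rows
#'   each); shared numeric columns are compared.
#' @param adjust Apply BH across metrics (default `FALSE`).
#' @return Data.frame: `metric`, `mean_A`, `sem_A`, `mean_B`, `sem_B`,
#'   `difference`, `p` (and `q` when `adjust`).
#' @export
villus_morphometry_compare <- function(groupA, groupB, adjust = FALSE) {
  if (nrow(groupA) < 3 || nrow(groupB) < 3)
    stop("insufficient data: need at least 3 individuals per group")
  metrics <- intersect(names(groupA)[vapply(groupA, is.numeric, logical(1))],
                       names(groupB)[vapply(groupB, is.numeric, logical(1))])
  if (!length(metrics)) stop("no shared numeric metrics to compare")
  sem <- function(v) sd(v) / sqrt(length(v))
  out <- do.call(rbind, lapply(metrics, function(mname) {
    a <- groupA[[mname]]; b <- groupB[[mname]]
    p <- if (sd(a) == 0 && sd(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0
    } else t.test(a, b)$p.value
    data.frame(metric = mname, mean_A = mean(a), sem_A = sem(a),
               mean_B = mean(b), sem_B = sem(b),
               difference = mean(a) - mean(b), p = p,
               stringsAsFactors = FALSE)
  }))
  if (adjust) out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; per gene,
#' `ddCt = mean dCt(treated) - mean dCt(control)` and the fold change is
#' `2^-ddCt`. Per-sample `2^-dCt` values are returned for group testing
#' (Welch t-test on dCt). The result is invariant to global Ct shifts that
#' affect target and reference alike.
#'
#' @param ct A `ct_table` from [simulate_ct_table()], or a list with `ct`
#'   (gene x sample matrix, positive cycles), `groups` (named per sample)
#'   and `reference_gene`.
#' @param treated,control Group labels to contrast.
#' @return Data.frame of class `ddct_result`: `gene`, `ddCt`,
#'   `fold_change`, `p`; per-sample `2^-dCt` values attached as attribute
#'   `"rel_expression"`.
#' @export
ddct_relative_expression <- function(ct, treated = "treated",
                                     control = "control") {
  m <- ct$ct; groups <- ct$groups; ref <- ct$reference_gene
  if (!ref %in% rownames(m)) stop("reference gene not in the Ct table")
  if (anyNA(m[ref, ])) {
    bad <- colnames(m)[is.na(m[ref, ])]
    stop("reference Ct missing in sample(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(names(groups))) names(groups) <- colnames(m)
  it <- names(groups)[groups == treated]
  ic <- names(groups)[groups == control]
  if (!length(it) || !length(ic)) stop("both groups must be non-empty")
  targets <- setdiff(rownames(m), ref)
  dct <- sweep(m[targets, , drop = FALSE], 2, m[ref, ], "-")
  out <- do.call(rbind, lapply(targets, function(gname) {
    ddct <- mean(dct[gname, it]) - mean(dct[gname, ic])
    p <- if (length(it) >= 2 && length(ic) >= 2 &&
             (sd(dct[gname, it]) > 0 || sd(dct[gname, ic]) > 0))
      t.test(dct[gname, it], dct[gname, ic])$p.value else NA_real_
    data.frame(gene = gname, ddCt = ddct, fold_change = 2^(-ddct), p = p,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "rel_expression") <- 2^(-dct)
  class(out) <- c("ddct_result", "data.frame")
  out
}
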