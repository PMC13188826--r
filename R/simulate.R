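#' Configuration for the paired-omics simulator
#'
#' Defines the study conditions emulated by [simulate_paired_omics()]: a
#' two-line donor design ("fat" vs "lean", `n_per_group` birds each) profiled
#' on two omics layers (metagenome and metatranscriptome) over the same
#' species panel, with planted differentially abundant species and one
#' planted "driver" whose transcriptional activity (RNA/DNA ratio) is
#' elevated in the fat group and coupled to the abdominal-fat phenotype.
#'
#' @param n_per_group Samples per group (default 30, the donor design).
#' @param n_species Number of species in the panel (default 200).
#' @param n_diff_mg,n_diff_mt Planted differential species per layer.
#' @param n_overlap Species differential in both layers (must not exceed the
#'   smaller of `n_diff_mg`, `n_diff_mt`); the driver is one of them.
#' @param diff_fold Multiplicative fold applied to a planted species' latent
#'   abundance in its enriched group.
#' @param driver_activity_fold MT/MG activity multiplier of the driver in the
#'   fat group (default 3).
#' @param driver_phenotype_beta Coupling (g per activity unit) of the driver's
#'   per-sample latent activity to abdominal fat weight.
#' @param base_logmean,base_logsd Log-normal baseline of species mean
#'   abundances (natural-log scale).
#' @param sample_logsd Per-sample biological variability of latent abundances
#'   (log scale sd).
#' @param act_logsd Per-sample variability of the driver's (and every
#'   species') MT-layer activity multiplier (log scale sd).
#' @param afw_base,afw_sd Baseline abdominal fat weight (g) and residual sd.
#' @param bw_mean,bw_sd Body weight distribution (g).
#' @param depth Sequencing depth: multinomial total per sample and layer.
#' @param seed Integer seed; split deterministically across sub-generators.
#' @return A validated list of class `omics_sim_config`.
#' @export
omics_sim_config <- function(n_per_group = 30, n_species = 200,
                             n_diff_mg = 10, n_diff_mt = 10, n_overlap = 5,
                             diff_fold = 4, driver_activity_fold = 3,
                             driver_phenotype_beta = 20,
                             base_logmean = 0, base_logsd = 1,
                             sample_logsd = 0.7, act_logsd = 0.3,
                             afw_base = 30, afw_sd = 30,
                             bw_mean = 2500, bw_sd = 150,
                             depth = 1e5, seed = 1L) {
  cfg <- list(
    n_per_group = check_count(n_per_group, "n_per_group", 2L),
    n_species = check_count(n_species, "n_species", 2L),
    n_diff_mg = check_count(n_diff_mg, "n_diff_mg", 0L),
    n_diff_mt = check_count(n_diff_mt, "n_diff_mt", 0L),
    n_overlap = check_count(n_overlap, "n_overlap", 0L),
    diff_fold = check_number(diff_fold, "diff_fold", lower = 1e-12),
    driver_activity_fold = check_number(driver_activity_fold,
                                        "driver_activity_fold", lower = 1e-12),
    driver_phenotype_beta = check_number(driver_phenotype_beta,
                                         "driver_phenotype_beta"),
    base_logmean = check_number(base_logmean, "base_logmean"),
    base_logsd = check_number(base_logsd, "base_logsd", lower = 0),
    sample_logsd = check_number(sample_logsd, "sample_logsd", lower = 0),
    act_logsd = check_number(act_logsd, "act_logsd", lower = 0),
    afw_base = check_number(afw_base, "afw_base", lower = 0),
    afw_sd = check_number(afw_sd, "afw_sd", lower = 0),
    bw_mean = check_number(bw_mean, "bw_mean", lower = 1),
    bw_sd = check_number(bw_sd, "bw_sd", lower = 0),
    depth = check_count(depth, "depth", 1L),
    seed = check_count(seed, "seed", 0L))
  if (cfg$n_overlap > min(cfg$n_diff_mg, cfg$n_diff_mt))
    stop_config("n_overlap", "must be <= min(n_diff_mg, n_diff_mt)")
  if (cfg$n_diff_mg + cfg$n_diff_mt - cfg$n_overlap > cfg$n_species)
    stop_config("n_species", "too small for the requested differential sets")
  class(cfg) <- "omics_sim_config"
  cfg
}

#' Simulate paired metagenome/metatranscriptome tables with planted truth
#'
#' Latent species abundances are log-normal: a fixed per-species baseline plus
#' per-sample biological noise. Planted differential species get a
#' multiplicative `diff_fold` on the latent scale in their enriched group
#' (overlap species, including the driver, in both layers; the remaining
#' per-layer differentials alternate enrichment direction). The MT layer
#' multiplies every species' latent by a per-sample activity factor
#' `exp(N(0, act_logsd))`; the driver's factor additionally carries
#' `driver_activity_fold` in the fat group, so its latent group-geometric-mean
#' activity ratio equals the configured fold. Counts are drawn multinomially
#' at `depth` per sample and layer from the TSS-normalized latents.
#' Phenotypes: BW is normal; AFW = `afw_base` + `driver_phenotype_beta` x
#' (per-sample latent driver activity) + normal noise (floored at 1 g);
#' AFP = AFW / BW exactly.
#'
#' When effect parameters are at their nulls (`diff_fold = 1`,
#' `driver_activity_fold = 1`, `driver_phenotype_beta = 0`) the generator is
#' a pure null for every downstream test.
#'
#' @param cfg An [omics_sim_config()].
#' @return A list with elements `mg`, `mt` (feature tables), `metadata`
#'   (data.frame: sample_id, group, BW, AFW, AFP) and `truth` (planted
#'   differential sets with directions, `driver_id`, per-sample latent driver
#'   activity, and the latent abundance matrices of both layers).
#' @examples
#' sim <- simulate_paired_omics(omics_sim_config(n_per_group = 5,
#'   n_species = 40, depth = 1e4, seed = 7))
#' colSums(sim$mg)  # every sample sums to depth
#' @export
simulate_paired_omics <- function(cfg = omics_sim_config()) {
  if (!inherits(cfg, "omics_sim_config"))
    stop("cfg must be built with omics_sim_config()")
  n <- cfg$n_per_group
  p <- cfg$n_species
  species <- sprintf("sp_%03d", seq_len(p))
  samples <- c(sprintf("fat_%02d", seq_len(n)), sprintf("lean_%02d", seq_len(n)))
  group <- rep(c("fat", "lean"), each = n)

  with_seed(sub_seed(cfg$seed, 1L), {
    base_log <- rnorm(p, cfg$base_logmean, cfg$base_logsd)

    # planted sets: overlap species first (fat-enriched, driver among them),
    # then layer-specific differentials with alternating directions
    idx <- sample.int(p, cfg$n_diff_mg + cfg$n_diff_mt - cfg$n_overlap)
    ov <- idx[seq_len(cfg$n_overlap)]
    mg_only <- idx[cfg$n_overlap + seq_len(cfg$n_diff_mg - cfg$n_overlap)]
    mt_only <- idx[cfg$n_diff_mg + seq_len(cfg$n_diff_mt - cfg$n_overlap)]
    alt_dir <- function(k) rep(c("fat", "lean"), length.out = k)
    mg_idx <- c(ov, mg_only)
    mg_dir <- c(rep("fat", length(ov)), alt_dir(length(mg_only)))
    mt_idx <- c(ov, mt_only)
    mt_dir <- c(rep("fat", length(ov)), alt_dir(length(mt_only)))
    driver <- if (length(ov)) ov[1] else NA_integer_
    # the driver is pinned to a comfortably abundant baseline so its signal
    # is not confounded with sampling noise at low depth
    if (!is.na(driver)) base_log[driver] <- cfg$base_logmean + cfg$base_logsd

    e <- matrix(rnorm(p * 2L * n, 0, cfg$sample_logsd), p, 2L * n)
    lat_mg <- exp(base_log + e)
    fold_mg <- matrix(1, p, 2L * n)
    for (k in seq_along(mg_idx))
      fold_mg[mg_idx[k], group == mg_dir[k]] <- cfg$diff_fold
    lat_mg <- lat_mg * fold_mg

    # MT layer: shared latent, per-sample activity multiplier per species
    act <- exp(matrix(rnorm(p * 2L * n, 0, cfg$act_logsd), p, 2L * n))
    driver_act <- rep(1, 2L * n)
    if (!is.na(driver)) {
      act[driver, group == "fat"] <- act[driver, group == "fat"] *
        cfg$driver_activity_fold
      driver_act <- act[driver, ]
    }
    fold_mt <- matrix(1, p, 2L * n)
    for (k in seq_along(mt_idx))
      fold_mt[mt_idx[k], group == mt_dir[k]] <- cfg$diff_fold
    lat_mt <- exp(base_log + e) * fold_mt * act

    dimnames(lat_mg) <- dimnames(lat_mt) <- list(species, samples)

    counts <- function(lat) {
      pr <- tss(lat)
      out <- vapply(seq_len(ncol(pr)),
                    function(j) rmultinom(1, cfg$depth, pr[, j])[, 1],
                    numeric(nrow(pr)))
      dimnames(out) <- dimnames(lat)
      out
    }
    mg <- feature_table(counts(lat_mg), layer = "MG")
    mt <- feature_table(counts(lat_mt), layer = "MT")

    bw <- pmax(rnorm(2L * n, cfg$bw_mean, cfg$bw_sd), 1)
    afw <- pmax(cfg$afw_base + cfg$driver_phenotype_beta * driver_act +
                  rnorm(2L * n, 0, cfg$afw_sd), 1)
    metadata <- data.frame(sample_id = samples, group = group,
                           BW = bw, AFW = afw, AFP = afw / bw,
                           stringsAsFactors = FALSE)

    truth <- list(
      diff_species_mg = data.frame(feature = species[mg_idx], direction = mg_dir,
                                   stringsAsFactors = FALSE),
      diff_species_mt = data.frame(feature = species[mt_idx], direction = mt_dir,
                                   stringsAsFactors = FALSE),
      overlap = species[ov],
      driver_id = if (is.na(driver)) NA_character_ else species[driver],
      driver_activity = setNames(driver_act, samples),
      latent_mg = lat_mg, latent_mt = lat_mt)

    list(mg = mg, mt = mt, metadata = metadata, truth = truth)
  })
}

#' Simulate per-bird adipocyte measurement panels
#'
#' Per bird, adipocyte diameters are drawn from a normal distribution
#' truncated below at 1 um and converted to section areas
#' `A = pi (d/2)^2`. The fat-pad mass is set unit-consistently from a
#' recorded true cell number: `W = 0.915 g/mL x N_true x E[V]` with
#' `E[V] = (pi/6) E[d^3]` of the truncated diameter distribution (in mL),
#' so the stereology stage can be validated as a round trip.
#'
#' @param n_per_group Birds per group.
#' @param mean_diam_by_group Named numeric pair of group mean diameters (um);
#'   names are the group labels (default `c(treated = 75, control = 60)`).
#' @param sd_diam Diameter sd (um), common to both groups.
#' @param cells_per_bird Cells measured per bird (>= 10).
#' @param n_true True adipocyte count per bird.
#' @param seed Integer seed.
#' @return A list of panels; each panel is a list with `individual_id`,
#'   `group`, `areas_um2`, `W_g` and the recorded `N_true` and `EV_um3`.
#' @export
simulate_adipocyte_panels <- function(n_per_group = 6,
                                      mean_diam_by_group = c(treated = 75,
                                                             control = 60),
                                      sd_diam = 12, cells_per_bird = 100,
                                      n_true = 5e6, seed = 1L) {
  if (length(mean_diam_by_group) != 2 || any(mean_diam_by_group <= 0))
    stop_config("mean_diam_by_group", "must be two positive diameters (um)")
  if (sd_diam < 0) stop_config("sd_diam", "must be non-negative")
  check_count(cells_per_bird, "cells_per_bird", 10L)
  if (is.null(names(mean_diam_by_group)))
    names(mean_diam_by_group) <- c("treated", "control")

  # E[d^3] of a normal truncated below at `lo`
  trunc_third_moment <- function(mu, sigma, lo = 1) {
    if (sigma == 0) return(mu^3)
    z <- integrate(function(d) d^3 * stats::dnorm(d, mu, sigma),
                   lower = lo, upper = mu + 12 * sigma)$value
    z / (1 - stats::pnorm(lo, mu, sigma))
  }

  with_seed(sub_seed(seed, 2L), {
    panels <- list()
    id <- 0L
    for (g in names(mean_diam_by_group)) {
      mu <- mean_diam_by_group[[g]]
      ev <- pi / 6 * trunc_third_moment(mu, sd_diam)
      for (b in seq_len(n_per_group)) {
        id <- id + 1L
        d <- rnorm(cells_per_bird, mu, sd_diam)
        while (any(d < 1)) d[d < 1] <- rnorm(sum(d < 1), mu, sd_diam)
        w <- 0.915 * n_true * (ev / 1e12)           # g = g/mL * count * mL
        panels[[id]] <- list(individual_id = sprintf("bird_%02d", id),
                             group = g, areas_um2 = pi * (d / 2)^2,
                             W_g = w, N_true = n_true, EV_um3 = ev)
      }
    }
    panels
  })
}

#' Simulate an untargeted metabolome intensity matrix
#'
#' Log-normal intensities with planted up/down features (multiplicative
#' `fc` in the treated group), pooled-QC replicates drawn near each
#' feature's grand mean with small dispersion, and left-censored missing
#' values: entries below the `zero_fraction` quantile of all test-sample
#' intensities are set to zero, emulating the detection limit of LC-MS
#' (missingness concentrates in low-abundance features).
#'
#' @param n_per_group Test samples per group.
#' @param n_features Number of metabolite features.
#' @param n_up,n_down Features planted up/down in the treated group.
#' @param fc Planted fold change (> 0; `fc = 1` is the null).
#' @param n_qc Number of pooled QC injections (0 disables the QC stage).
#' @param zero_fraction Fraction of test-sample entries falling below the
#'   detection limit (left-censored to zero).
#' @param sample_logsd Per-sample log10 dispersion of intensities.
#' @param qc_rsd Relative standard deviation of QC injections.
#' @param seed Integer seed.
#' @return List: `intensities` (feature table, layer `"metabolome"`, columns
#'   are test then QC samples), `is_qc` logical flag per column, `groups`
#'   (per test sample), and `truth` (up/down feature id sets).
#' @export
simulate_metabolome <- function(n_per_group = 6, n_features = 300,
                                n_up = 15, n_down = 15, fc = 4, n_qc = 3,
                                zero_fraction = 0.05, sample_logsd = 0.15,
                                qc_rsd = 0.05, seed = 1L) {
  if (fc <= 0) stop_config("fc", "must be positive")
  if (n_up + n_down > n_features)
    stop_config("n_features", "must be >= n_up + n_down")
  if (zero_fraction < 0 || zero_fraction >= 1)
    stop_config("zero_fraction", "must be in [0, 1)")
  with_seed(sub_seed(seed, 3L), {
    feats <- sprintf("metab_%04d", seq_len(n_features))
    test_ids <- c(sprintf("trt_%02d", seq_len(n_per_group)),
                  sprintf("ctl_%02d", seq_len(n_per_group)))
    groups <- rep(c("treated", "control"), each = n_per_group)
    base <- 10^rnorm(n_features, 5, 0.8)
    # planted truth goes on quantifiable features: a low-abundance feature
    # pushed below the detection limit is censored, not differential
    eligible <- feats[base > quantile(base, 0.4)]
    if (n_up + n_down > length(eligible))
      stop_config("n_features", "too few quantifiable features for the planted sets")
    up <- if (n_up) sample(eligible, n_up) else character(0)
    down <- if (n_down) sample(setdiff(eligible, up), n_down) else character(0)
    m <- base * 10^matrix(rnorm(n_features * length(test_ids), 0, sample_logsd),
                          n_features, length(test_ids))
    rownames(m) <- feats; colnames(m) <- test_ids
    m[up, groups == "treated"] <- m[up, groups == "treated"] * fc
    m[down, groups == "treated"] <- m[down, groups == "treated"] / fc
    if (zero_fraction > 0) {
      lod <- quantile(m, zero_fraction)  # detection limit
      m[m < lod] <- 0
    }
    if (n_qc > 0) {
      grand <- rowMeans(m)
      qc <- grand * matrix(exp(rnorm(n_features * n_qc, 0, qc_rsd)),
                           n_features, n_qc)
      colnames(qc) <- sprintf("QC_%02d", seq_len(n_qc))
      m <- cbind(m, qc)
    }
    list(intensities = feature_table(m, layer = "metabolome"),
         is_qc = grepl("^QC_", colnames(m)),
         groups = groups,
         truth = list(up = up, down = down))
  })
}

#' Simulate a qPCR Ct table
#'
#' The reference gene's Ct is stable across groups; each target gene's Ct is
#' shifted by `delta_by_gene` cycles in the treated group (a negative shift
#' means higher expression, i.e. fold change `2^-delta` downstream).
#'
#' @param n_per_group Samples per group.
#' @param genes Character vector of gene ids (reference included).
#' @param reference_gene Internal reference gene id; must be in `genes`.
#' @param delta_by_gene Named numeric vector of per-gene Ct shifts (cycles)
#'   applied in the treated group; genes not named get 0.
#' @param base_ct Baseline target-gene Ct.
#' @param ref_ct Reference-gene Ct.
#' @param sd_ct Technical/biological Ct noise (cycles).
#' @param seed Integer seed.
#' @return List of class `ct_table`: `ct` (gene x sample matrix), `groups`,
#'   `reference_gene`.
#' @export
simulate_ct_table <- function(n_per_group = 6,
                              genes = c("TBP", "ACACA", "CPT1A", "FABP4", "LPL"),
                              reference_gene = "TBP",
                              delta_by_gene = c(ACACA = -1),
                              base_ct = 25, ref_ct = 20, sd_ct = 0.2,
                              seed = 1L) {
  if (!reference_gene %in% genes)
    stop_config("reference_gene", "must be one of `genes`")
  with_seed(sub_seed(seed, 4L), {
    ids <- c(sprintf("trt_%02d", seq_len(n_per_group)),
             sprintf("ctl_%02d", seq_len(n_per_group)))
    groups <- rep(c("treated", "control"), each = n_per_group)
    ct <- matrix(rnorm(length(genes) * length(ids), base_ct, sd_ct),
                 length(genes), length(ids), dimnames = list(genes, ids))
    ct[reference_gene, ] <- rnorm(length(ids), ref_ct, sd_ct)
    for (g in intersect(names(delta_by_gene), genes)) {
      if (g == reference_gene) next
      ct[g, groups == "treated"] <- ct[g, groups == "treated"] + delta_by_gene[[g]]
    }
    structure(list(ct = ct, groups = setNames(groups, ids),
                   reference_gene = reference_gene),
              class = "ct_table")
  })
}

#' Write a simulated paired-omics study to disk
#'
#' Writes the MG and MT tables as TSV (feature id first column), the sample
#' metadata as TSV, and the planted truth as a JSON sidecar.
#'
#' @param sim Result of [simulate_paired_omics()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(mg = file.path(dir, "mg_table.tsv"),
             mt = file.path(dir, "mt_table.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.json"))
  write_feature_table(sim$mg, paths["mg"])
  write_feature_table(sim$mt, paths["mt"])
  write.table(sim$metadata, paths["metadata"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- sim$truth
  truth$latent_mg <- NULL  # latents are in-memory diagnostics, not study data
  truth$latent_mt <- NULL
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
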