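#' Build (or load) a pipeline configuration
#'
#' A configuration names the input tables, the stages to run, the screening
#' thresholds and the global seed. It can be written in YAML with the same
#' field names and loaded by passing the file path.
#'
#' Fields: `mg_table`, `mt_table`, `metadata` (TSV paths; required when the
#' screen stage is enabled), `ecology_table` (optional TSV for the
#' transplant-verification stage), `metabolome_table` + `metabolome_groups`
#' (optional), `stages` (subset of `c("ecology", "screen", "metabolomics")`),
#' `lefse` (list of [lefse_config()] overrides), `alpha`, `seed`,
#' `output_dir`.
#'
#' @param path Optional YAML file to load.
#' @param ... Fields overriding the defaults (and anything loaded).
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(mg_table = NULL, mt_table = NULL, metadata = NULL,
              ecology_table = NULL, ecology_groups = NULL,
              metabolome_table = NULL, metabolome_groups = NULL,
              metabolome_qc = NULL,
              stages = c("screen"), lefse = list(), alpha = 0.05,
              seed = 1L, output_dir = "cecaldriver_out")
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    loaded <- yaml::read_yaml(path)
    cfg[names(loaded)] <- loaded
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg$stages <- as.character(unlist(cfg$stages))
  bad <- setdiff(cfg$stages, c("ecology", "screen", "metabolomics"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg$alpha <- check_number(cfg$alpha, "alpha", 1e-12, 1 - 1e-12)
  cfg$seed <- check_count(cfg$seed, "seed", 0L)
  class(cfg) <- "pipeline_config"
  cfg
}

preflight <- function(cfg) {
  need <- character(0)
  if ("screen" %in% cfg$stages)
    need <- c(need, mg_table = cfg$mg_table %||% NA,
              mt_table = cfg$mt_table %||% NA,
              metadata = cfg$metadata %||% NA)
  if ("ecology" %in% cfg$stages)
    need <- c(need, ecology_table = cfg$ecology_table %||% NA)
  if ("metabolomics" %in% cfg$stages)
    need <- c(need, metabolome_table = cfg$metabolome_table %||% NA)
  miss <- names(need)[is.na(need)]
  if (length(miss))
    stop("pre-flight validation failed: missing input(s) for enabled stage(s): ",
         paste(miss, collapse = ", "))
  absent <- need[!is.na(need) & !file.exists(need)]
  if (length(absent))
    stop("pre-flight validation failed: file(s) not found: ",
         paste(absent, collapse = ", "))
  invisible(TRUE)
}

#' Run the full screening pipeline
#'
#' Stage order: transplant-verification ecology (alpha diversity, PCoA,
#' PERMANOVA and ANOSIM on the 16S/ecology table), the paired MG/MT driver
#' screen ([driver_screen()]), then optional metabolomics (preprocessing,
#' PLS-DA VIP, DAM gating). All inputs are validated before any stage
#' executes; every stage writes its outputs as TSV under `output_dir` and
#' the machine-readable run report (with per-output MD5 checksums) is
#' written as `report.json`. Re-running with the same config and seed
#' produces byte-identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return The run report (list of class `run_report`), invisibly the same
#'   object that was written to `report.json`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  preflight(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(schema_version = "1.0",
                 package_version = as.character(utils::packageVersion("cecaldriver")),
                 seed = cfg$seed, stages = list())
  t0 <- proc.time()[["elapsed"]]
  stage_log <- function(name, t_start, outputs) {
    message(sprintf("[%s] done in %.1fs (%d output file(s))", name,
                    proc.time()[["elapsed"]] - t_start, length(outputs)))
    list(name = name, status = "ok",
         outputs = lapply(outputs, function(pp)
           list(file = basename(pp),
                md5 = unname(tools::md5sum(pp)))))
  }
  run_stage <- function(name, fun) {
    ts <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    report$stages[[name]] <<- stage_log(name, ts, out$files)
    out$extra
  }

  if ("ecology" %in% cfg$stages) {
    eco <- run_stage("ecology", function() {
      tab <- read_feature_table(cfg$ecology_table, layer = "16S")
      groups <- if (!is.null(cfg$ecology_groups)) unlist(cfg$ecology_groups)
                else read_sample_metadata(cfg$metadata)$group
      ad <- alpha_diversity(unclass(tab))
      d <- bray_curtis(tab)
      ord <- pcoa(d)
      pm <- permanova(d, groups, seed = sub_seed(cfg$seed, 11L))
      an <- anosim(d, groups, seed = sub_seed(cfg$seed, 12L))
      f1 <- file.path(cfg$output_dir, "alpha_diversity.tsv")
      write.table(ad, f1, sep = "\t", quote = FALSE, row.names = FALSE)
      f2 <- file.path(cfg$output_dir, "bray_curtis.tsv")
      write.table(as.matrix(d), f2, sep = "\t", quote = FALSE)
      f3 <- file.path(cfg$output_dir, "pcoa_coordinates.tsv")
      write.table(ord$points, f3, sep = "\t", quote = FALSE)
      list(files = c(f1, f2, f3),
           extra = list(permanova = list(pseudo_F = pm$pseudo_F, p = pm$p),
                        anosim = list(R = an$R, p = an$p)))
    })
    report$ecology <- eco
  }

  if ("screen" %in% cfg$stages) {
    scr <- run_stage("screen", function() {
      mg <- read_feature_table(cfg$mg_table, layer = "MG")
      mt <- read_feature_table(cfg$mt_table, layer = "MT")
      meta <- read_sample_metadata(cfg$metadata)
      lcfg <- do.call(lefse_config,
                      c(cfg$lefse, list(seed = sub_seed(cfg$seed, 13L))))
      fit <- driver_screen(mg, mt, meta, config = lcfg, alpha = cfg$alpha)
      f1 <- file.path(cfg$output_dir, "mg_differentials.tsv")
      write.table(as.data.frame(fit$mg_diff), f1, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      f2 <- file.path(cfg$output_dir, "mt_differentials.tsv")
      write.table(as.data.frame(fit$mt_diff), f2, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      f3 <- file.path(cfg$output_dir, "candidate_report.tsv")
      write.table(as.data.frame(fit$candidates), f3, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      sel <- fit$candidates[fit$candidates$selected, , drop = FALSE]
      list(files = c(f1, f2, f3),
           extra = list(n_mg_diff = nrow(fit$mg_diff),
                        n_mt_diff = nrow(fit$mt_diff),
                        n_overlap = nrow(fit$overlap),
                        candidates = sel$feature))
    })
    report$screen <- scr
  }

  if ("metabolomics" %in% cfg$stages) {
    met <- run_stage("metabolomics", function() {
      tab <- read_feature_table(cfg$metabolome_table, layer = "metabolome")
      is_qc <- if (!is.null(cfg$metabolome_qc)) as.logical(unlist(cfg$metabolome_qc))
               else grepl("^QC", colnames(tab))
      groups <- unlist(cfg$metabolome_groups)
      mm <- preprocess_metabolome(tab, is_qc = is_qc)
      vip <- plsda_vip(mm, groups)
      dams <- select_dams(mm, groups, vip)
      f1 <- file.path(cfg$output_dir, "dam_results.tsv")
      write.table(as.data.frame(dams), f1, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      f2 <- file.path(cfg$output_dir, "metabo_processing_log.txt")
      writeLines(mm$log, f2)
      list(files = c(f1, f2),
           extra = list(n_dams = sum(dams$selected),
                        n_up = sum(dams$selected & dams$direction == "up"),
                        n_down = sum(dams$selected & dams$direction == "down")))
    })
    report$metabolomics <- met
  }

  message(sprintf("pipeline finished in %.1fs",
                  proc.time()[["elapsed"]] - t0))
  class(report) <- "run_report"
  write_report(report, file.path(cfg$output_dir, "report.json"))
  invisible(report)
}

#' Write a run report
#'
#' JSON (schema-versioned, machine readable) plus a short human-readable
#' summary next to it.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  txt <- c(sprintf("cecaldriver run report (schema %s, seed %s)",
                   report$schema_version, report$seed),
           vapply(report$stages, function(s)
             sprintf("  stage %-14s %s", s$name, s$status), character(1)),
           if (!is.null(report$screen$candidates))
             sprintf("  candidates: %s",
                     paste(report$screen$candidates, collapse = ", ")))
  writeLines(txt, sub("\\.json$", ".txt", path))
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report (schema %s, seed %s): %d stage(s)\n",
              x$schema_version, x$seed, length(x$stages)))
  for (s in x$stages) cat("  -", s$name, ":", s$status, "\n")
  if (!is.null(x$screen$candidates))
    cat("  candidates:", paste(x$screen$candidates, collapse = ", "), "\n")
  invisible(x)
}
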