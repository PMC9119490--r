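#' Build a run configuration
#'
#' Collects every tunable of the scan into one object that is serialized
#' verbatim into the run manifest.
#'
#' @param vcf,popmap,genes,degs Input file paths (a simulated dataset
#'   directory provides all four).
#' @param out_dir Output directory.
#' @param polarization Polarization mode for \code{\link{read_phased_vcf}}.
#' @param cutoff EHH cutoff.
#' @param maf_min iHS core-site minor-allele-frequency floor.
#' @param window_size,window_step Window geometry in bp.
#' @param ihs_pop Population scanned for iHS ("pooled" by default; see
#'   \code{\link{ihs_scan}}).
#' @param ihs_std_mode,bin_width,min_bin_n iHS standardization controls.
#' @param agg_mode Window aggregation mode.
#' @param hp_pop Population pooled for Hp ("A" or "pooled").
#' @param thresholds \code{\link{scan_thresholds}} object.
#' @param sim_params \code{\link{sweep_sim_params}} for the simulate stage
#'   (NULL to scan existing inputs).
#' @param seed Seed for the simulate stage.
#' @return List of class \code{"RunConfig"}.
#' @export
run_config <- function(vcf = NULL, popmap = NULL, genes = NULL, degs = NULL,
                       out_dir = "haplosweep_out",
                       polarization = "ref_ancestral", cutoff = 0.05,
                       maf_min = 0.05, ihs_pop = "pooled",
                       window_size = 10000L,
                       window_step = window_size,
                       ihs_std_mode = "freq_binned", bin_width = 0.02,
                       min_bin_n = 20L, agg_mode = "max_abs", hp_pop = "A",
                       thresholds = scan_thresholds(), sim_params = NULL,
                       seed = 1L) {
  structure(list(vcf = vcf, popmap = popmap, genes = genes, degs = degs,
                 out_dir = out_dir, polarization = polarization,
                 cutoff = cutoff, maf_min = maf_min, ihs_pop = ihs_pop,
                 window_size = as.integer(window_size),
                 window_step = as.integer(window_step),
                 ihs_std_mode = ihs_std_mode, bin_width = bin_width,
                 min_bin_n = as.integer(min_bin_n), agg_mode = agg_mode,
                 hp_pop = hp_pop, thresholds = thresholds,
                 sim_params = sim_params, seed = as.integer(seed)),
            class = "RunConfig")
}

write_manifest <- function(config, out_dir, stage, status, timings = list(),
                           error = NULL) {
  inputs <- Filter(Negate(is.null),
                   config[c("vcf", "popmap", "genes", "degs")])
  checksums <- lapply(inputs, function(p)
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_)
  m <- list(package = "haplosweep",
            version = as.character(utils::packageVersion("haplosweep")),
            stage = stage, status = status, error = error,
            timings_sec = timings, input_md5 = checksums,
            config = rapply(unclass(config), unclass, how = "replace"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(m)
}

require_inputs <- function(config, what) {
  for (key in what) {
    p <- config[[key]]
    if (is.null(p)) stop("config is missing required input '", key, "'")
    if (!file.exists(p)) stop("input file for '", key, "' not found: ", p)
  }
}

#' Pipeline stage: simulate a dataset
#'
#' @param config \code{\link{run_config}} with \code{sim_params} set (a
#'   default \code{\link{sweep_sim_params}} seeded from \code{config$seed}
#'   is used when NULL).
#' @return The config, updated to point at the simulated input files.
#' @export
cmd_simulate <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  sp <- config$sim_params
  if (is.null(sp)) sp <- sweep_sim_params(seed = config$seed)
  sim_dir <- file.path(config$out_dir, "sim")
  res <- simulate_dataset(sp, sim_dir)
  config$vcf <- res$vcf; config$popmap <- res$popmap
  config$genes <- res$genes; config$degs <- res$degs
  config$sim_params <- sp
  write_manifest(config, config$out_dir, "simulate", "ok",
                 list(simulate = proc.time()[["elapsed"]] - t0))
  config
}

#' Pipeline stage: haplotype and window scans
#'
#' Reads the phased VCF, runs the iHS and XP-EHH site scans and the window
#' statistics (Hp/ZHp, per-population pi, score aggregation), and writes
#' per-chromosome site-score and window-record TSVs.
#'
#' @param config \code{\link{run_config}} pointing at vcf + popmap.
#' @return List: \code{hms} (haplotype matrices), \code{ihs}, \code{xpehh}
#'   (site scores), \code{windows} (window records), all concatenated over
#'   chromosomes.
#' @export
cmd_scan <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  on_fail <- function(e) {
    write_manifest(config, config$out_dir, "scan", "failed",
                   error = conditionMessage(e))
    stop("stage scan failed: ", conditionMessage(e), call. = FALSE)
  }
  res <- tryCatch({
    require_inputs(config, c("vcf", "popmap"))
    hms <- read_phased_vcf(config$vcf, config$popmap, config$polarization)
    per_chrom <- lapply(hms, function(hm) {
      ihs <- ihs_scan(hm, pop = config$ihs_pop, cutoff = config$cutoff,
                      maf_min = config$maf_min,
                      std_mode = config$ihs_std_mode,
                      bin_width = config$bin_width,
                      min_bin_n = config$min_bin_n)
      xp <- xpehh_scan(hm, cutoff = config$cutoff)
      win <- window_scan(hm, ihs_sites = ihs, xpehh_sites = xp,
                         size = config$window_size, step = config$window_step,
                         hp_pop = config$hp_pop, agg_mode = config$agg_mode)
      list(ihs = ihs, xpehh = xp, windows = win)
    })
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    ihs <- do.call(rbind, lapply(per_chrom, `[[`, "ihs"))
    xp <- do.call(rbind, lapply(per_chrom, `[[`, "xpehh"))
    win <- do.call(rbind, lapply(per_chrom, `[[`, "windows"))
    rownames(ihs) <- rownames(xp) <- rownames(win) <- NULL
    write_site_scores(ihs, file.path(config$out_dir, "ihs_sites.tsv"))
    write_site_scores(xp, file.path(config$out_dir, "xpehh_sites.tsv"))
    write_window_records(win, file.path(config$out_dir, "windows.tsv"))
    list(hms = hms, ihs = ihs, xpehh = xp, windows = win)
  }, error = on_fail)
  write_manifest(config, config$out_dir, "scan", "ok",
                 list(scan = proc.time()[["elapsed"]] - t0))
  res
}

#' Pipeline stage: gene-set integration
#'
#' @param config \code{\link{run_config}} pointing at genes + degs.
#' @param windows Window records from \code{\link{cmd_scan}} (reloaded from
#'   the output directory when NULL).
#' @return \code{IntegrationResult}; also writes \code{common_genes.tsv}
#'   (the per-gene report), \code{venn_counts.json} and per-test gene lists.
#' @export
cmd_integrate <- function(config, windows = NULL) {
  t0 <- proc.time()[["elapsed"]]
  on_fail <- function(e) {
    write_manifest(config, config$out_dir, "integrate", "failed",
                   error = conditionMessage(e))
    stop("stage integrate failed: ", conditionMessage(e), call. = FALSE)
  }
  res <- tryCatch({
    require_inputs(config, c("genes", "degs"))
    if (is.null(windows))
      windows <- read_window_records(file.path(config$out_dir, "windows.tsv"))
    genes <- read_annotation(config$genes)
    degs <- read_deg_table(config$degs)
    r <- integrate_scan(windows, genes, degs, config$thresholds)
    out <- config$out_dir
    rep_out <- r$report
    num <- vapply(rep_out, is.numeric, TRUE)
    rep_out[num] <- lapply(rep_out[num], fmt_num)
    utils::write.table(rep_out, file.path(out, "common_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(as.list(r$venn_counts),
                         file.path(out, "venn_counts.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    for (t in c("ihs", "xpehh", "zhp", "deg"))
      writeLines(r[[paste0("genes_", t)]],
                 file.path(out, paste0("genes_", t, ".txt")))
    r
  }, error = on_fail)
  write_manifest(config, config$out_dir, "integrate", "ok",
                 list(integrate = proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full pipeline: simulate (optional), scan, integrate
#'
#' @param config \code{\link{run_config}}.
#' @param simulate Run the simulate stage first (default: TRUE when no VCF is
#'   configured).
#' @return List: \code{config}, \code{scan}, \code{integration}.
#' @export
cmd_run_all <- function(config, simulate = is.null(config$vcf)) {
  if (simulate) config <- cmd_simulate(config)
  scan <- cmd_scan(config)
  integration <- cmd_integrate(config, windows = scan$windows)
  write_manifest(config, config$out_dir, "run_all", "ok")
  list(config = config, scan = scan, integration = integration)
}
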