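# Pipeline orchestration: simulate or ingest, score, associate, report.

default_thresholds <- function() {
  list(
    lga_hrd = 20, lga_hrp = 18,        # classification window boundaries
    min_segment = 10e6, max_gap = 3e6, # LGA geometry
    loh_min = 15e6, tai_min_probes = 500, lst_min = 10e6, smooth = 3e6,
    foci_threshold = 5, percent_threshold = 10,
    vaf_min = 0.05, cov_min = 100, popfreq_max = 0.001,
    deletion_quantile = 0.10)
}

#' Build a validated run configuration
#'
#' A run configuration names the inputs (or a simulation spec), the genome,
#' the output directory, the seed and every scoring threshold; thresholds
#' default to the method's standard constants and unknown keys are rejected.
#'
#' @param config named list, or path to a YAML file with the same structure.
#'   Recognised top-level keys: `genome`, `seed`, `out_dir`, `simulate`
#'   (logical or a named list of [cohort_spec()] overrides), `inputs`
#'   (named list of file paths: `measurements`, `foci`, `annotations`,
#'   `bins`, `allelic`), `thresholds` (named list overriding
#'   `default_thresholds()`).
#' @return A `run_config` list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  known <- c("genome", "seed", "out_dir", "simulate", "inputs", "thresholds")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    hrd_stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  thr <- default_thresholds()
  extra <- setdiff(names(config$thresholds), names(thr))
  if (length(extra))
    hrd_stop("unknown threshold key(s): ", paste(extra, collapse = ", "))
  thr[names(config$thresholds)] <- config$thresholds
  structure(list(
    genome = config$genome %||% "toy3",
    seed = as.integer(config$seed %||% 1L),
    out_dir = config$out_dir,
    simulate = config$simulate %||% is.null(config$inputs),
    inputs = config$inputs, thresholds = thr), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — simulation (or ingest), LGA
#' calling from binned profiles, scar scoring from allelic profiles,
#' response classification from treated-arm growth measurements, RAD51
#' scoring, biomarker association statistics — and assembles a per-PDX
#' table plus association results.  Every reported statistic is
#' recomputable from the per-PDX table.  When `out_dir` is set, per-stage
#' TSVs and a report JSON are written there.
#'
#' @param config a [run_config()], or anything accepted by it.
#' @return A `run_report`: list with `per_pdx` (data frame), `associations`
#'   (list of contingency analyses), and `provenance`.
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  thr <- config$thresholds
  genome <- load_genome(config$genome)
  if (isTRUE(config$simulate) || is.list(config$simulate)) {
    overrides <- if (is.list(config$simulate)) config$simulate else list()
    spec <- do.call(cohort_spec,
                    c(overrides,
                      list(genome = config$genome, seed = config$seed)))
    sim <- simulate_cohort(spec, profiles = TRUE)
    measurements <- sim$measurements
    foci <- sim$foci
    annotations <- sim$annotations
    binned <- lapply(sim$binned, `[[`, "profile")
    allelic <- lapply(sim$allelic, `[[`, "profile")
    truth <- sim$truth
  } else {
    inp <- config$inputs
    measurements <- if (!is.null(inp$measurements))
      read_measurements(inp$measurements)
    foci <- if (!is.null(inp$foci)) read_foci(inp$foci)
    annotations <- if (!is.null(inp$annotations))
      read_annotations(inp$annotations)
    binned <- if (!is.null(inp$bins))
      lapply(inp$bins, read_binned_profile)
    allelic <- if (!is.null(inp$allelic))
      lapply(inp$allelic, read_allelic_segments)
    truth <- NULL
  }
  # stage: shallow HRD
  lga <- NULL
  if (!is.null(binned)) {
    lga <- do.call(rbind, lapply(binned, function(p) {
      seg <- segment_profile(p)
      cut <- estimate_level_cutoff(seg)
      merged <- merge_segments(seg, cut)
      rep_ <- call_lgas(merged, genome, cut,
                        min_segment = thr$min_segment, max_gap = thr$max_gap)
      data.frame(pdx = p$sample, lga_total = rep_$lga_total,
                 hrd_class = rep_$classification,
                 cutoff = rep_$parameters$cutoff, stringsAsFactors = FALSE)
    }))
    rownames(lga) <- NULL
  }
  # stage: scar scores
  scars <- NULL
  if (!is.null(allelic)) {
    scars <- do.call(rbind, lapply(allelic, function(p) {
      s <- hrd_scar_score(p, genome, loh_min = thr$loh_min,
                          tai_min_probes = thr$tai_min_probes,
                          lst_min = thr$lst_min, smooth = thr$smooth)
      data.frame(pdx = p$sample, loh = s$loh, tai = s$tai, lst = s$lst,
                 scar_total = s$total, stringsAsFactors = FALSE)
    }))
    rownames(scars) <- NULL
  }
  # stage: response
  response <- NULL
  if (!is.null(measurements)) {
    m <- measurements
    if (!is.null(m$arm)) m <- m[m$arm == "treated", , drop = FALSE]
    response <- classify_cohort_response(m)
  }
  # stage: RAD51
  rad51 <- NULL
  if (!is.null(foci)) {
    rad51 <- score_rad51_cohort(foci, foci_threshold = thr$foci_threshold,
                                percent_threshold = thr$percent_threshold,
                                min_cells = 0)$pdx
  }
  # assemble per-PDX table
  per_pdx <- NULL
  for (piece in list(lga, scars, response, rad51, annotations)) {
    if (is.null(piece)) next
    per_pdx <- if (is.null(per_pdx)) piece
               else merge(per_pdx, piece, by = "pdx", all = TRUE,
                          suffixes = c("", ".ann"))
  }
  # associations computable from the per-PDX table
  associations <- list()
  if (!is.null(per_pdx$hrd_class) && !is.null(per_pdx$category)) {
    tab <- build_contingency(per_pdx, per_pdx$hrd_class == "HRD",
                             grouping = "cr_pr_sd_vs_pd")
    associations$hrd_vs_response <- list(
      table = unclass(tab), fisher_p = fisher_exact_two_sided(tab),
      metrics = diagnostic_metrics(tab))
  }
  if (!is.null(per_pdx$status) && !is.null(per_pdx$hrd_class)) {
    tab2 <- contingency_from_flags(per_pdx$status == "HR-deficient",
                                   per_pdx$hrd_class == "HRD")
    associations$rad51_vs_genomic_hrd <- list(
      table = unclass(tab2), fisher_p = fisher_exact_two_sided(tab2),
      metrics = diagnostic_metrics(tab2))
  }
  if (!is.null(lga) && !is.null(scars)) {
    j <- merge(lga, scars, by = "pdx")
    if (nrow(j) >= 3 && stats::sd(j$lga_total) > 0 &&
        stats::sd(j$scar_total) > 0)
      associations$lga_scar_correlation <-
        pearson_r(j$lga_total, j$scar_total)
  }
  report <- structure(list(per_pdx = per_pdx, associations = associations,
                           truth = truth,
                           provenance = list(seed = config$seed,
                                             genome = config$genome,
                                             thresholds = thr)),
                      class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$per_pdx, file.path(out_dir, "per_pdx.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$per_pdx$median_best_avg)) {
    wf <- report$per_pdx[order(report$per_pdx$median_best_avg,
                               decreasing = TRUE), ]
    utils::write.csv(wf[, intersect(c("pdx", "median_best_avg", "category"),
                                    names(wf))],
                     file.path(out_dir, "waterfall.csv"), row.names = FALSE)
  }
  jsonlite::write_json(
    list(associations = report$associations,
         provenance = report$provenance),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", nrow(x$per_pdx), " PDX models\n", sep = "")
  if (!is.null(x$associations$hrd_vs_response))
    cat("  HRD vs response Fisher p = ",
        signif(x$associations$hrd_vs_response$fisher_p, 3), "\n", sep = "")
  if (!is.null(x$associations$lga_scar_correlation))
    cat("  LGA ~ scar-score Pearson r = ",
        signif(x$associations$lga_scar_correlation, 3), "\n", sep = "")
  invisible(x)
}
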