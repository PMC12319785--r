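# End-to-end orchestration: selection -> reliability -> properties
# (+ structural metrics), per-stage TSV outputs and a run manifest.

#' Pipeline configuration
#'
#' All analysis parameters with their standard defaults: uncorrected
#' selection threshold (preset A 1e-3 / B 1e-4), 4 cm endpoint distance
#' filter, 1.3 cm bundle linkage with minimum bundle size 20, ICC
#' consistency threshold 0.4 (0.5 for the stricter replication), power
#' screen at 20% relative difference in more than four subjects, and
#' automatic chi-square continuity correction (Yates iff 2 x 2). All
#' are overridable.
#'
#' @param selection `"A"` (p < 1e-3) or `"B"` (p < 1e-4).
#' @param icc_threshold Consistency threshold (0.4 or 0.5).
#' @param bundle_min_size Minimum bundle membership (default 20).
#' @param bundle_max_link_mm Single-linkage threshold, mm (default 13).
#' @param min_endpoint_distance_mm Connection distance filter, mm
#'   (default 40).
#' @param power_threshold Relative power-difference threshold
#'   (default 0.20).
#' @param power_min_subjects Subjects above threshold for a flag
#'   (default 5).
#' @param chi2_correction `"auto"`, `"on"` or `"off"`.
#' @param length_mode Structural weight-to-length mapping.
#' @param seed Seed recorded in the manifest.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(selection = c("A", "B"),
                            icc_threshold = 0.4,
                            bundle_min_size = 20,
                            bundle_max_link_mm = 13,
                            min_endpoint_distance_mm = 40,
                            power_threshold = 0.20,
                            power_min_subjects = 5L,
                            chi2_correction = c("auto", "on", "off"),
                            length_mode = c("reciprocal", "neglog"),
                            seed = 1L) {
  selection <- match.arg(selection)
  stopifnot(icc_threshold > 0, icc_threshold < 1)
  structure(list(selection = selection,
                 alpha = selection_alpha(selection),
                 icc_threshold = icc_threshold,
                 bundle_min_size = bundle_min_size,
                 bundle_max_link_mm = bundle_max_link_mm,
                 min_endpoint_distance_mm = min_endpoint_distance_mm,
                 power_threshold = power_threshold,
                 power_min_subjects = power_min_subjects,
                 chi2_correction = match.arg(chi2_correction),
                 length_mode = match.arg(length_mode),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Run the full consistency-analysis pipeline
#'
#' Executes, in order: connection selection on session 1 (paired
#' t-tests, distance filter, bundle clustering, parcel mapping),
#' ICC(3,1) consistency analysis with confidence intervals on the
#' parcel-level series, the behavioral regression screen on the
#' mean-over-sessions contrasts, functional strength, structural
#' profiles, and the pooled consistent-vs-inconsistent property report.
#'
#' @param study A `synth_study`, or any list with components `tensor`,
#'   `geometry`, `parcellation`, `behavior` and optionally
#'   `connectomes` and `power`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for per-stage TSVs, the property
#'   report and `manifest.json`.
#' @param verbose Per-stage progress messages with edge counts.
#' @return Object of class `retest_run`: list with `config`, `counts`
#'   (per band/window selection bookkeeping), `edges` (one row per
#'   selected parcel edge with ICC, CI, label, behavioral fit,
#'   strength, laterality and structural profile), `report`
#'   (a `property_report`), `power_flags`, `timings` and `manifest`.
#' @export
run_pipeline <- function(study, config = pipeline_config(),
                         out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  tensor <- study$tensor; geometry <- study$geometry
  parcellation <- study$parcellation; behavior <- study$behavior
  connectomes <- study$connectomes
  ns <- tensor$n_subjects
  subj <- seq_len(ns)
  if (!is.null(behavior)) {
    extra <- setdiff(behavior$subject, subj)
    missing_ <- setdiff(subj, behavior$subject)
    if (length(extra) || length(missing_))
      stop("subject mismatch between connectivity and behavior: ",
           paste(c(if (length(missing_)) paste("missing", toString(missing_)),
                   if (length(extra)) paste("unknown", toString(extra))),
                 collapse = "; "), call. = FALSE)
    behavior <- behavior[match(subj, behavior$subject), , drop = FALSE]
  }
  if (!is.null(connectomes) && length(connectomes) != ns)
    stop(sprintf("subject mismatch: %d connectomes for %d subjects",
                 length(connectomes), ns), call. = FALSE)

  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  power_flags <- NULL
  if (!is.null(study$power))
    power_flags <- power_screen(study$power, config$power_threshold,
                                config$power_min_subjects)

  sel <- select_connections(tensor, geometry, parcellation,
                            alpha = config$alpha,
                            min_distance_mm = config$min_endpoint_distance_mm,
                            max_link_mm = config$bundle_max_link_mm,
                            min_size = config$bundle_min_size,
                            verbose = verbose)
  timings["select"] <- tic() - t0; t0 <- tic()
  edges <- sel$edges
  if (verbose)
    message(sprintf("selection %s: %d parcel edge(s) pooled over %d band/window combinations",
                    config$selection, nrow(edges), nrow(sel$counts)))

  if (nrow(edges)) {
    iccs <- lapply(sel$series, icc, threshold = config$icc_threshold)
    edges$icc <- vapply(iccs, `[[`, 0, "icc")
    edges$ci_low <- vapply(iccs, `[[`, 0, "ci_low")
    edges$ci_high <- vapply(iccs, `[[`, 0, "ci_high")
    edges$label <- vapply(iccs, `[[`, "", "label")
    n_deg <- sum(vapply(iccs, `[[`, TRUE, "degenerate"))
    if (n_deg && verbose)
      message(n_deg, " degenerate edge(s) classified inconsistent")
  } else {
    edges$icc <- edges$ci_low <- edges$ci_high <- numeric(0)
    edges$label <- character(0)
  }
  timings["icc"] <- tic() - t0; t0 <- tic()
  if (verbose && nrow(edges))
    message(sprintf("ICC(3,1) > %.1f: %d of %d edges consistent (%.1f%%)",
                    config$icc_threshold, sum(edges$label == "consistent"),
                    nrow(edges),
                    100 * mean(edges$label == "consistent")))

  report <- NULL
  if (nrow(edges)) {
    Y <- vapply(sel$series, rowMeans, numeric(ns))
    if (!is.null(behavior)) {
      scr <- behavior_screen(Y, behavior)
      edges$F <- scr$F; edges$p_behavior <- scr$p; edges$fitted <- scr$fitted
    } else {
      edges$F <- edges$p_behavior <- NA_real_; edges$fitted <- NA
    }
    edges$strength <- vapply(sel$series, strength_summary, 0)
    edges$laterality <- edge_laterality(edges$parcel_a, edges$parcel_b,
                                        parcellation)
    if (!is.null(connectomes)) {
      prof <- structural_profiles(edges, connectomes, config$length_mode)
      edges$mean_streamlines <- prof$mean_streamlines
      edges$mean_spl <- prof$mean_spl
      edges$n_finite_spl <- prof$n_finite_spl
      edges$mean_ebc <- prof$mean_ebc
    }
    timings["properties"] <- tic() - t0; t0 <- tic()
    report <- property_report(edges, config$chi2_correction)
    if (verbose) for (nt in report$notices) message("note: ", nt)
  } else if (verbose) {
    message("no edges selected; downstream stages are no-ops")
  }
  timings["report"] <- tic() - t0

  manifest <- list(package = "retestconn",
                   version = as.character(utils::packageVersion("retestconn")),
                   r_version = R.version.string,
                   config = unclass(config),
                   config_hash = .config_hash(config),
                   n_subjects = ns,
                   stage_counts = list(
                     parcel_edges = nrow(edges),
                     consistent = sum(edges$label == "consistent"),
                     per_band_window = sel$counts),
                   timings_s = as.list(round(timings, 3)))

  run <- structure(list(config = config, counts = sel$counts,
                        edges = edges, series = sel$series,
                        report = report, power_flags = power_flags,
                        timings = timings, manifest = manifest),
                   class = "retest_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Write pipeline results to a directory
#'
#' Per-stage TSVs (`selected_edges.tsv`, `selection_counts.tsv`,
#' `power_flags.tsv` when present), the property-report comparisons
#' (`property_report.tsv`) and `manifest.json`.
#'
#' @param run A `retest_run`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  stopifnot(inherits(run, "retest_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(run$edges, file.path(out_dir, "selected_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$counts, file.path(out_dir, "selection_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$power_flags))
    utils::write.table(run$power_flags,
                       file.path(out_dir, "power_flags.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$report)) {
    cmp <- run$report$comparisons
    rows <- lapply(names(cmp), function(nm) {
      x <- cmp[[nm]]
      data.frame(comparison = nm, kind = x$kind,
                 statistic = x$statistic,
                 df = if (x$kind == "chi2") x$df else NA,
                 p = x$p,
                 median_consistent = if (!is.null(run$report$medians[[nm]]))
                   run$report$medians[[nm]][["consistent"]] else NA,
                 median_inconsistent = if (!is.null(run$report$medians[[nm]]))
                   run$report$medians[[nm]][["inconsistent"]] else NA)
    })
    utils::write.table(do.call(rbind, rows),
                       file.path(out_dir, "property_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(jsonlite::toJSON(run$manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

#' @export
print.retest_run <- function(x, ...) {
  cat(sprintf("Test-retest consistency run (selection %s, ICC > %.1f)\n",
              x$config$selection, x$config$icc_threshold))
  cat(sprintf("  parcel edges: %d pooled over %d band/window combinations\n",
              nrow(x$edges), nrow(x$counts)))
  if (nrow(x$edges))
    cat(sprintf("  consistent: %d (%.1f%%)\n",
                sum(x$edges$label == "consistent"),
                100 * mean(x$edges$label == "consistent")))
  invisible(x)
}

#' @export
summary.retest_run <- function(object, ...) {
  print(object)
  if (!is.null(object$report)) print(object$report)
  invisible(object)
}
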