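#' Default run configuration
#'
#' Defaults follow the analysis conventions used throughout the package:
#' 4th-order zero-phase Butterworth at 6 Hz, last 50 steps per trial, 2%
#' swing grid, alpha 0.05.
#'
#' @param ... Overrides (`last_n_steps`, `grid_step`, `alpha`, `filter`
#'   (list: `order`, `cutoff_hz`, `zero_phase`, `enabled`), `gap_max_frames`,
#'   `seed`, `out_dir`, `simulate` (list passed to [make_cohort()]), or
#'   `inputs`: a list of trial records, each
#'   `list(subject, field, limb_labels, path, axis_map, rate_hz)`).
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    last_n_steps = 50,
    grid_step = 2,
    alpha = 0.05,
    filter = list(order = 4, cutoff_hz = 6, zero_phase = TRUE,
                  enabled = NULL),
    gap_max_frames = 10,
    seed = 1,
    out_dir = NULL,
    simulate = NULL,
    inputs = NULL)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stopf("unknown run_config field(s): %s", paste(unknown, collapse = ", "))
  for (nm in names(ov)) {
    if (is.list(cfg[[nm]]) && is.list(ov[[nm]])) {
      cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
    } else cfg[[nm]] <- ov[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are [run_config()] fields.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Analyze one trial: markers to swing-level regression inputs
#'
#' Runs gap-filling, optional low-pass filtering, event detection, swing
#' assembly, last-n-step selection, COM-state resampling, foot-placement
#' extraction and step widths for a single trial.
#'
#' @param ms A [marker_set()] (or a `sim_trial`, whose markers are used).
#' @param limb_labels Named `c(left=, right=)` limb mapping.
#' @param last_n Steps retained (tail). Default 50.
#' @param filter A [filter_spec()] or `NULL` to skip filtering (synthetic
#'   noise-free markers do not need it).
#' @param gap_max_frames Longest gap filled, frames.
#' @param grid_step Swing grid spacing, %.
#' @return List: `design` (from [swing_design()], plus per-swing `limb`),
#'   `widths` (a `step_table`), `swings`, `events`.
#' @export
analyze_trial <- function(ms, limb_labels = c(left = "control",
                                              right = "control"),
                          last_n = 50, filter = NULL, gap_max_frames = 10,
                          grid_step = 2) {
  if (inherits(ms, "sim_trial")) ms <- ms$markers
  validate_markers(ms)
  ms <- gap_fill(ms, gap_max_frames)
  if (!is.null(filter)) ms <- lowpass_filter(ms, filter)
  events <- detect_events(ms)
  swings <- build_swings(events)
  sel <- select_last_n_steps(swings, last_n)
  design <- swing_design(ms, sel, grid_step = grid_step)
  design$limb <- unname(limb_labels[design$sides])
  widths <- compute_step_widths(ms, events, labels = limb_labels,
                                ic_frames = sel$end_frame)
  list(design = design, widths = widths, swings = sel, events = events)
}

#' Run the full analysis pipeline
#'
#' Orchestrates ingest (or simulation), event detection, COM-state
#' extraction, the per-node foot-placement regression, step-width metrics
#' and the SPM stage, collecting per-stage warnings into the report.
#'
#' @param config A [run_config()]. Supply either `simulate` (arguments for
#'   [make_cohort()]) or `inputs` (marker files with metadata).
#' @return A `run_report` list: `subject_series` (long data.frame of
#'   per-subject/limb/field regression series), `cell_series` (the six
#'   limb x field series fit on subject-demeaned pooled steps), `metrics`
#'   (step-width summaries), `spm` (ANOVA effects and, when the limb
#'   effect or interaction shows clusters, post-hoc pairwise t fields),
#'   `warnings`, `provenance`.
#' @export
run_pipeline <- function(config = run_config()) {
  warn_log <- character()
  note <- function(w) warn_log <<- c(warn_log, conditionMessage(w))

  trials <- withCallingHandlers(pipeline_inputs(config),
                                warning = function(w) {
                                  note(w); invokeRestart("muffleWarning")
                                })
  filt <- if (isTRUE(pipeline_filter_enabled(config, trials))) {
    filter_spec(config$filter$order, config$filter$cutoff_hz,
                config$filter$zero_phase)
  } else NULL

  analyzed <- lapply(trials, function(tr) {
    res <- withCallingHandlers(
      analyze_trial(tr$trial %||% tr$ms, tr$limb_labels,
                    last_n = config$last_n_steps, filter = filt,
                    gap_max_frames = config$gap_max_frames,
                    grid_step = config$grid_step),
      warning = function(w) { note(w); invokeRestart("muffleWarning") })
    c(tr[c("subject", "group", "field", "limb_labels")], res)
  })

  node_pct <- sf_grid(config$grid_step)
  subject_series <- list()
  metrics <- list()
  for (a in analyzed) {
    for (limb in unique(a$design$limb)) {
      rows <- a$design$limb == limb
      ser <- withCallingHandlers(
        fit_series(a$design$com_x[rows, , drop = FALSE],
                   a$design$com_v[rows, , drop = FALSE],
                   a$design$fp[rows], limb = limb, field = a$field,
                   node_pct = node_pct),
        warning = function(w) { note(w); invokeRestart("muffleWarning") })
      if (is.null(ser)) next
      ser$subject <- a$subject
      subject_series[[length(subject_series) + 1]] <- ser
    }
    sm <- summarize_steps(a$widths, field = a$field)
    sm$subject <- a$subject
    metrics[[length(metrics) + 1]] <- sm
  }
  subject_series <- do.call(rbind, subject_series)
  metrics <- do.call(rbind, metrics)

  cell_series <- pooled_cell_series(analyzed, node_pct)

  spm <- pipeline_spm(subject_series, node_pct, config$alpha)

  report <- list(
    subject_series = subject_series,
    cell_series = cell_series,
    metrics = metrics,
    spm = spm,
    warnings = warn_log,
    provenance = list(
      config = unclass(config),
      package_version = as.character(utils::packageVersion("stridefield")),
      n_trials = length(analyzed)))
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    args <- config$simulate
    if (is.null(args$seed)) args$seed <- config$seed
    return(do.call(make_cohort, args))
  }
  if (is.null(config$inputs))
    stopf("run_config must provide either `simulate` or `inputs`")
  lapply(config$inputs, function(inp) {
    ms <- read_markers(inp$path,
                       axis_map = inp$axis_map %||%
                         c(ml = "x", ap = "y", vert = "z"),
                       rate_hz = inp$rate_hz)
    list(subject = inp$subject, group = inp$group %||% "control",
         field = inp$field %||% "null",
         limb_labels = inp$limb_labels %||%
           c(left = "control", right = "control"),
         ms = ms)
  })
}

pipeline_filter_enabled <- function(config, trials) {
  en <- config$filter$enabled
  if (!is.null(en)) return(isTRUE(en))
  # simulated markers are noise-free; measured files default to filtering
  is.null(config$simulate)
}

# six limb x field series on steps pooled across subjects after per-subject
# demeaning (so between-subject offsets do not masquerade as COM coupling)
pooled_cell_series <- function(analyzed, node_pct) {
  acc <- list()
  for (a in analyzed) {
    d <- a$design
    for (limb in unique(d$limb)) {
      rows <- which(d$limb == limb)
      if (length(rows) < 3) next
      key <- paste(limb, a$field, sep = "|")
      acc[[key]] <- c(acc[[key]], list(list(
        com_x = apply(d$com_x[rows, , drop = FALSE], 2, demean),
        com_v = apply(d$com_v[rows, , drop = FALSE], 2, demean),
        fp = demean(d$fp[rows]))))
    }
  }
  out <- list()
  for (key in names(acc)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    ser <- fit_series(do.call(rbind, lapply(acc[[key]], `[[`, "com_x")),
                      do.call(rbind, lapply(acc[[key]], `[[`, "com_v")),
                      unlist(lapply(acc[[key]], `[[`, "fp")),
                      limb = parts[1], field = parts[2],
                      node_pct = node_pct)
    out[[key]] <- ser
  }
  do.call(rbind, out)
}

pipeline_spm <- function(subject_series, node_pct, alpha) {
  wide <- split(subject_series,
                list(subject_series$subject, subject_series$limb,
                     subject_series$field), drop = TRUE)
  Y <- t(vapply(wide, function(d) d$r2[order(d$node_pct)],
                numeric(length(node_pct))))
  meta <- do.call(rbind, lapply(wide, function(d)
    data.frame(subject = d$subject[1], limb = d$limb[1], field = d$field[1])))
  effects <- anova2_field(Y, meta$limb, meta$field, alpha = alpha,
                          node_pct = node_pct)
  posthoc <- NULL
  if (nrow(effects$limb$clusters) || nrow(effects$interaction$clusters)) {
    posthoc <- posthoc_tfields(Y, meta$limb, subject = meta$subject,
                               alpha_family = alpha, node_pct = node_pct)
  }
  list(effects = effects, posthoc = posthoc, samples = Y, design = meta)
}

#' Extremity-by-field table of R-squared at foot-off and initial contact
#'
#' Across-subject mean and SD of the regression R-squared at node 0
#' (foot-off) and node 100 (initial contact), per limb and field.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @return A data.frame with one row per limb and columns
#'   `<field>_foot_off_mean/sd` and `<field>_initial_contact_mean/sd`.
#' @export
make_table2 <- function(report) {
  ss <- report$subject_series
  nodes <- range(ss$node_pct)
  rows <- list()
  for (limb in unique(ss$limb)) {
    row <- list(limb = limb)
    for (fld in unique(ss$field)) {
      for (nd in nodes) {
        v <- ss$r2[ss$limb == limb & ss$field == fld & ss$node_pct == nd]
        lab <- if (nd == nodes[1]) "foot_off" else "initial_contact"
        row[[paste(fld, lab, "mean", sep = "_")]] <- mean(v, na.rm = TRUE)
        row[[paste(fld, lab, "sd", sep = "_")]] <- sd(v)
      }
    }
    rows[[limb]] <- as.data.frame(row)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$subject_series, file.path(out_dir, "subject_series.csv"),
            row.names = FALSE)
  write.csv(report$cell_series, file.path(out_dir, "cell_series.csv"),
            row.names = FALSE)
  write.csv(report$metrics, file.path(out_dir, "metrics.csv"),
            row.names = FALSE)
  spm_export <- lapply(report$spm$effects, spm_result_record)
  if (!is.null(report$spm$posthoc))
    spm_export$posthoc <- lapply(report$spm$posthoc, spm_result_record)
  jsonlite::write_json(spm_export, file.path(out_dir, "spm.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(provenance = report$provenance,
                   warnings = report$warnings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

spm_result_record <- function(x) {
  list(statistic = x$statistic, effect = x$effect, df = x$df,
       fwhm_nodes = x$fwhm_nodes, alpha = x$alpha, threshold = x$threshold,
       clusters = x$clusters)
}
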