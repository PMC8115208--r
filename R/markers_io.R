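#' Construct a marker trajectory set
#'
#' Container for labeled 3D marker position time-series sampled at a fixed
#' rate. Positions are stored in meters in lab axes `x`, `y`, `z`; the
#' `axis_map` declares which lab axis is mediolateral (`ml`), fore-aft
#' (`ap`) and vertical (`vert`). Missing samples are stored as `NA`.
#'
#' @param markers Named list of numeric matrices, one per marker, each with
#'   the same number of rows (frames) and columns `x`, `y`, `z` (m).
#' @param rate_hz Sampling frequency in Hz (> 0).
#' @param axis_map Named character vector mapping roles `ml`, `ap`, `vert`
#'   to lab axis names, e.g. `c(ml = "x", ap = "y", vert = "z")`.
#' @return An object of class `marker_set`.
#' @export
marker_set <- function(markers, rate_hz,
                       axis_map = c(ml = "x", ap = "y", vert = "z")) {
  if (!is.list(markers) || is.null(names(markers)) || any(names(markers) == ""))
    stopf("`markers` must be a named list of frame x 3 matrices")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1 || rate_hz <= 0)
    stopf("`rate_hz` must be a single positive number")
  if (!all(c("ml", "ap", "vert") %in% names(axis_map)) ||
      !setequal(unname(axis_map[c("ml", "ap", "vert")]), c("x", "y", "z")))
    stopf("`axis_map` must assign roles ml/ap/vert to distinct axes x/y/z")
  markers <- lapply(markers, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3) stopf("each marker matrix must have 3 columns")
    colnames(m) <- c("x", "y", "z")
    storage.mode(m) <- "double"
    m
  })
  frames <- unique(vapply(markers, nrow, integer(1)))
  if (length(frames) != 1)
    stopf("inconsistent frame counts across markers: %s",
          paste(frames, collapse = ", "))
  structure(
    list(markers = markers, rate_hz = rate_hz, frames = frames,
         axis_map = axis_map[c("ml", "ap", "vert")]),
    class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %d markers, %d frames @ %g Hz (%.2f s)\n",
              length(x$markers), x$frames, x$rate_hz, x$frames / x$rate_hz))
  cat("  markers:", paste(names(x$markers), collapse = ", "), "\n")
  cat(sprintf("  axes: ml=%s ap=%s vert=%s\n",
              x$axis_map[["ml"]], x$axis_map[["ap"]], x$axis_map[["vert"]]))
  invisible(x)
}

# one coordinate (by role) of one marker, as a numeric vector
marker_axis <- function(ms, label, role = c("ml", "ap", "vert")) {
  role <- match.arg(role)
  if (!label %in% names(ms$markers)) stopf("marker '%s' not present", label)
  ms$markers[[label]][, ms$axis_map[[role]]]
}

#' Validate that required marker labels are present
#'
#' @param ms A [marker_set()].
#' @param required Character vector of required labels.
#' @return `ms`, invisibly; errors naming any missing label.
#' @export
validate_markers <- function(ms, required = sf_required_markers()) {
  missing <- setdiff(required, names(ms$markers))
  if (length(missing))
    stopf("required marker label(s) missing: %s",
          paste(missing, collapse = ", "))
  invisible(ms)
}

#' Low-pass filter specification
#'
#' @param order Butterworth filter order (>= 1). Default 4.
#' @param cutoff_hz Low-pass cutoff in Hz. Default 6.
#' @param zero_phase Apply forward-backward (zero-phase)? Default `TRUE`.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(order = 4, cutoff_hz = 6, zero_phase = TRUE) {
  if (order < 1) stopf("filter order must be >= 1")
  if (cutoff_hz <= 0) stopf("cutoff must be positive")
  structure(list(order = order, cutoff_hz = cutoff_hz,
                 zero_phase = zero_phase), class = "filter_spec")
}

#' Read marker trajectories from a TRC or CSV file
#'
#' Two tabular formats are supported. The CSV dialect has a header row
#' `frame,time,<label>_x,<label>_y,<label>_z,...`; empty cells are missing
#' samples. TRC is the conventional tab-separated mocap format with a
#' `DataRate`/`NumFrames`/`Units` header. Positions declared in millimeters
#' are converted to meters.
#'
#' @param path File path.
#' @param axis_map Axis role assignment, see [marker_set()].
#' @param format `"auto"` (by extension), `"csv"` or `"trc"`.
#' @param rate_hz Sampling rate override for CSV files without a usable
#'   time column.
#' @param units `"m"` or `"mm"` for CSV files (TRC declares its own).
#' @param required Labels validated after reading; `NULL` to skip.
#' @return A [marker_set()].
#' @export
read_markers <- function(path, axis_map = c(ml = "x", ap = "y", vert = "z"),
                         format = c("auto", "csv", "trc"), rate_hz = NULL,
                         units = "m", required = sf_required_markers()) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.trc$", path, ignore.case = TRUE)) "trc" else "csv"
  ms <- switch(format,
               csv = read_markers_csv(path, axis_map, rate_hz, units),
               trc = read_markers_trc(path, axis_map))
  if (!is.null(required)) validate_markers(ms, required)
  ms
}

read_markers_csv <- function(path, axis_map, rate_hz, units) {
  df <- read.csv(path, check.names = FALSE)
  cn <- names(df)
  if (!all(c("frame", "time") %in% cn))
    stopf("CSV marker file must have 'frame' and 'time' columns: %s", path)
  coord_cols <- grep("_[xyz]$", cn, value = TRUE)
  bad <- setdiff(cn, c("frame", "time", coord_cols))
  if (length(bad))
    stopf("unrecognized column(s) in %s: %s", path, paste(bad, collapse = ", "))
  labels <- unique(sub("_[xyz]$", "", coord_cols))
  scale <- if (identical(units, "mm")) 1e-3 else 1
  markers <- lapply(labels, function(lab) {
    need <- paste0(lab, "_", c("x", "y", "z"))
    if (!all(need %in% cn))
      stopf("marker '%s' lacks one of %s in %s", lab,
            paste(need, collapse = "/"), path)
    as.matrix(df[, need]) * scale
  })
  names(markers) <- labels
  if (is.null(rate_hz)) {
    dt <- diff(df$time)
    if (length(dt) < 1 || any(dt <= 0))
      stopf("cannot infer sampling rate from time column in %s", path)
    rate_hz <- 1 / median(dt)
  }
  marker_set(markers, rate_hz = rate_hz, axis_map = axis_map)
}

#' Write marker trajectories to CSV or TRC
#'
#' Inverse of [read_markers()]; numeric content round-trips at full
#' precision for the CSV dialect.
#'
#' @param ms A [marker_set()].
#' @param path Output path.
#' @param format `"auto"`, `"csv"` or `"trc"`.
#' @param units Output units, `"m"` or `"mm"`.
#' @return `path`, invisibly.
#' @export
write_markers <- function(ms, path, format = c("auto", "csv", "trc"),
                          units = "m") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.trc$", path, ignore.case = TRUE)) "trc" else "csv"
  if (format == "csv") write_markers_csv(ms, path, units)
  else write_markers_trc(ms, path, units)
  invisible(path)
}

write_markers_csv <- function(ms, path, units) {
  scale <- if (identical(units, "mm")) 1e3 else 1
  n <- ms$frames
  out <- data.frame(frame = seq_len(n) - 1L,
                    time = (seq_len(n) - 1L) / ms$rate_hz)
  for (lab in names(ms$markers)) {
    m <- ms$markers[[lab]] * scale
    out[[paste0(lab, "_x")]] <- m[, "x"]
    out[[paste0(lab, "_y")]] <- m[, "y"]
    out[[paste0(lab, "_z")]] <- m[, "z"]
  }
  write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE, na = "")
}

read_markers_trc <- function(path, axis_map) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stopf("not a TRC file (too short): %s", path)
  hdr_keys <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  hdr_vals <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  hdr <- as.list(hdr_vals)
  names(hdr) <- hdr_keys[seq_along(hdr_vals)]
  rate_hz <- as.numeric(hdr[["DataRate"]])
  n_markers <- as.integer(hdr[["NumMarkers"]])
  units <- hdr[["Units"]] %||% "m"
  name_row <- strsplit(lines[4], "\t", fixed = TRUE)[[1]]
  labels <- name_row[-(1:2)]
  labels <- labels[labels != ""]
  if (length(labels) != n_markers)
    stopf("TRC header declares %d markers but names %d: %s",
          n_markers, length(labels), path)
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  scale <- if (tolower(units) == "mm") 1e-3 else 1
  rows <- lapply(seq_along(data_lines), function(i) {
    fields <- strsplit(data_lines[i], "\t", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(fields[-(1:2)]))
    length(vals) <- 3L * n_markers
    vals
  })
  dat <- do.call(rbind, rows)
  markers <- lapply(seq_len(n_markers), function(j) {
    dat[, (3 * j - 2):(3 * j), drop = FALSE] * scale
  })
  names(markers) <- labels
  marker_set(markers, rate_hz = rate_hz, axis_map = axis_map)
}

write_markers_trc <- function(ms, path, units = "mm") {
  scale <- if (identical(units, "mm")) 1e3 else 1
  labels <- names(ms$markers)
  n <- ms$frames
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
  writeLines(paste("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                   "Units", "OrigDataRate", "OrigDataStartFrame",
                   "OrigNumFrames", sep = "\t"), con)
  writeLines(sprintf("%g\t%g\t%d\t%d\t%s\t%g\t1\t%d",
                     ms$rate_hz, ms$rate_hz, n, length(labels), units,
                     ms$rate_hz, n), con)
  writeLines(paste(c("Frame#", "Time",
                     unlist(lapply(labels, function(l) c(l, "", "")))),
                   collapse = "\t"), con)
  writeLines(paste(c("", "",
                     unlist(lapply(seq_along(labels), function(j)
                       paste0(c("X", "Y", "Z"), j)))),
                   collapse = "\t"), con)
  num <- function(v) ifelse(is.na(v), "", format(v, digits = 17,
                                                 scientific = FALSE,
                                                 trim = TRUE))
  for (i in seq_len(n)) {
    vals <- unlist(lapply(labels, function(l) ms$markers[[l]][i, ] * scale))
    writeLines(paste(c(i, format((i - 1) / ms$rate_hz, digits = 10,
                                 trim = TRUE), num(vals)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

# forward-backward filtering with odd-reflection end padding, so that
# start-up transients fall in the discarded pad rather than the signal
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  p <- min(n - 1, 200L)
  if (p < 3) return(signal::filtfilt(bf, x))
  pre <- 2 * x[1] - x[(p + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - p)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[(p + 1):(p + n)]
}

#' Fill interior gaps in marker trajectories by cubic interpolation
#'
#' Interior runs of missing samples no longer than `max_gap_frames` are
#' filled per coordinate with a cubic spline through the observed samples.
#' Longer gaps, and missing samples before the first or after the last
#' observation of a marker, are left missing (never extrapolated); steps
#' overlapping them are excluded downstream.
#'
#' @param ms A [marker_set()].
#' @param max_gap_frames Longest gap (frames) that will be filled. Default
#'   10 frames (0.1 s at 100 Hz).
#' @return A [marker_set()] with short interior gaps filled.
#' @export
gap_fill <- function(ms, max_gap_frames = 10) {
  ms$markers <- lapply(ms$markers, function(m) {
    for (j in 1:3) m[, j] <- fill_gaps_vec(m[, j], max_gap_frames)
    m
  })
  ms
}

fill_gaps_vec <- function(x, max_gap) {
  obs <- which(!is.na(x))
  if (length(obs) < 2) return(x)
  lo <- obs[1]; hi <- obs[length(obs)]
  inner <- lo:hi
  nas <- inner[is.na(x[inner])]
  if (!length(nas)) return(x)
  runs <- split(nas, cumsum(c(1, diff(nas) != 1)))
  for (run in runs) {
    if (length(run) > max_gap) next
    x[run] <- spline(obs, x[obs], xout = run, method = "fmm")$y
  }
  x
}

#' Zero-phase Butterworth low-pass filtering of marker trajectories
#'
#' Each coordinate is filtered with a Butterworth low-pass of the given
#' order and cutoff; with `zero_phase = TRUE` the filter is applied
#' forward and backward (no phase lag, squared magnitude response).
#' Leading/trailing missing spans are preserved; unfilled interior gaps
#' are an error (filter requires contiguous samples).
#'
#' @param ms A [marker_set()].
#' @param spec A [filter_spec()]; defaults to 4th order, 6 Hz.
#' @return A filtered [marker_set()] of identical dimensions.
#' @export
lowpass_filter <- function(ms, spec = filter_spec()) {
  ny <- ms$rate_hz / 2
  if (spec$cutoff_hz >= ny)
    stopf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
          spec$cutoff_hz, ny)
  bf <- signal::butter(spec$order, spec$cutoff_hz / ny, type = "low")
  ms$markers <- mapply(function(m, lab) {
    for (j in 1:3) {
      x <- m[, j]
      obs <- which(!is.na(x))
      if (!length(obs)) next
      span <- obs[1]:obs[length(obs)]
      if (anyNA(x[span]))
        stopf("marker '%s' has unfilled interior gaps; run gap_fill() first",
              lab)
      seg <- x[span]
      x[span] <- if (isTRUE(spec$zero_phase)) filtfilt_padded(bf, seg)
                 else as.numeric(signal::filter(bf, seg))
      m[, j] <- x
    }
    m
  }, ms$markers, names(ms$markers), SIMPLIFY = FALSE)
  ms
}
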