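#' Detect gait events from foot-marker vertical trajectories
#'
#' Initial contact and foot-off are identified per side from the vertical
#' positions of the calcaneus and 5th-metatarsal markers. A swing excursion
#' is a contiguous run where the marker rises more than `tol` above its
#' stance baseline (the signal minimum). Foot-off is the last frame before
#' the excursion at which the 5th-metatarsal height has not yet left the
#' baseline (within `settle_tol`); initial contact is the first frame after
#' the excursion at which the calcaneus height has settled back to its
#' stride minimum (within `settle_tol`). Events within 50 ms of the record
#' boundary are flagged low-confidence.
#'
#' @param ms A [marker_set()] with gap-free foot markers.
#' @param tol Excursion tolerance above baseline, in meters. Default 5 mm.
#' @param settle_tol Settle tolerance used to refine event frames, in
#'   meters. Default 0.05 mm (suits low-noise / filtered data).
#' @param min_swing_frames Excursions shorter than this are ignored.
#' @param boundary_s Events closer than this to the record ends are flagged
#'   low-confidence. Default 0.05 s.
#' @return A `gait_events` data.frame with columns `side`, `type`
#'   (`initial_contact` / `foot_off`), `frame` (0-based), `time_s`,
#'   `confidence` (`"ok"` or `"low"`), ordered in time and alternating
#'   foot_off / initial_contact per side.
#' @export
detect_events <- function(ms, tol = 0.005, settle_tol = 5e-5,
                          min_swing_frames = 5, boundary_s = 0.05) {
  validate_markers(ms, SF_FOOT_MARKERS)
  sides <- list(left = c(heel = "LCAL", met = "LMT5"),
                right = c(heel = "RCAL", met = "RMT5"))
  evs <- list()
  for (side in names(sides)) {
    z_heel <- marker_axis(ms, sides[[side]][["heel"]], "vert")
    z_met <- marker_axis(ms, sides[[side]][["met"]], "vert")
    fo <- excursion_starts(z_met, tol, settle_tol, min_swing_frames)
    ic <- excursion_ends(z_heel, tol, settle_tol, min_swing_frames)
    if (length(fo))
      evs[[paste0(side, "_fo")]] <- data.frame(
        side = side, type = "foot_off", frame = fo)
    if (length(ic))
      evs[[paste0(side, "_ic")]] <- data.frame(
        side = side, type = "initial_contact", frame = ic)
  }
  ev <- do.call(rbind, evs)
  if (is.null(ev) || sum(ev$type == "initial_contact") < 3 ||
      sum(ev$type == "foot_off") < 3)
    stopf("insufficient data: fewer than 3 complete strides detected")
  # order in time; at a shared frame an initial contact precedes a foot-off
  ev <- ev[order(ev$frame, ev$type != "foot_off"), ]
  ev <- enforce_alternation(ev)
  n <- ms$frames
  bnd <- boundary_s * ms$rate_hz
  ev$time_s <- ev$frame / ms$rate_hz
  ev$confidence <- ifelse(ev$frame < bnd | ev$frame > (n - 1) - bnd,
                          "low", "ok")
  rownames(ev) <- NULL
  structure(ev[, c("side", "type", "frame", "time_s", "confidence")],
            class = c("gait_events", "data.frame"))
}

# frames (0-based) where each above-baseline excursion begins, refined back
# to the last frame still settled at the stance baseline
excursion_starts <- function(z, tol, settle_tol, min_len) {
  reg <- excursion_regions(z, tol, min_len)
  base <- min(z, na.rm = TRUE)
  out <- vapply(reg, function(r) {
    if (r[1] == 1) return(NA_real_)  # airborne at record start: no foot-off
    j <- r[1] - 1
    while (j > 1 && z[j] > base + settle_tol) j <- j - 1
    j - 1  # 0-based frame
  }, numeric(1))
  out[!is.na(out)]
}

# frames (0-based) where each excursion has settled back down
excursion_ends <- function(z, tol, settle_tol, min_len) {
  reg <- excursion_regions(z, tol, min_len)
  base <- min(z, na.rm = TRUE)
  n <- length(z)
  out <- vapply(reg, function(r) {
    if (r[2] == n) return(NA_real_)  # airborne at record end: no landing
    i <- r[2] + 1
    while (i < n && z[i] > base + settle_tol) i <- i + 1
    i - 1  # 0-based frame
  }, numeric(1))
  out[!is.na(out)]
}

# list of c(first, last) 1-based index pairs of contiguous frames above
# baseline + tol
excursion_regions <- function(z, tol, min_len) {
  if (all(is.na(z))) return(list())
  base <- min(z, na.rm = TRUE)
  up <- !is.na(z) & z > base + tol
  if (!any(up)) return(list())
  r <- rle(up)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_len
  mapply(function(s, e) c(s, e), starts[keep], ends[keep], SIMPLIFY = FALSE)
}

# keep, per side, a clean alternating foot_off -> initial_contact sequence
enforce_alternation <- function(ev) {
  keep <- rep(TRUE, nrow(ev))
  for (s in unique(ev$side)) {
    idx <- which(ev$side == s)
    expect <- "foot_off"
    for (i in idx) {
      if (ev$type[i] == expect) {
        expect <- if (expect == "foot_off") "initial_contact" else "foot_off"
      } else if (ev$type[i] == "initial_contact" && expect == "foot_off") {
        keep[i] <- FALSE  # leading IC without a preceding FO of this side
      } else {
        keep[i] <- FALSE
      }
    }
  }
  ev[keep, ]
}

#' Assemble swing segments from a gait event table
#'
#' One segment per foot-off / next same-side initial-contact pair. A
#' segment is excluded (with a reason) when the contralateral stance side
#' has no initial contact at or before the foot-off, or when either of its
#' events is flagged low-confidence.
#'
#' @param events A `gait_events` table from [detect_events()].
#' @return A `swing_table` data.frame: `swing_id`, `side`, `start_frame`,
#'   `end_frame`, `stance_side`, `stance_ic_frame`, `excluded`, `reason`.
#' @export
build_swings <- function(events) {
  ev <- as.data.frame(events)
  segs <- list()
  for (s in unique(ev$side)) {
    sv <- ev[ev$side == s, ]
    fo <- sv[sv$type == "foot_off", ]
    ic <- sv[sv$type == "initial_contact", ]
    for (i in seq_len(nrow(fo))) {
      nxt <- ic[ic$frame > fo$frame[i], ]
      if (!nrow(nxt)) next
      segs[[length(segs) + 1]] <- data.frame(
        side = s, start_frame = fo$frame[i], end_frame = nxt$frame[1],
        low_conf = fo$confidence[i] == "low" || nxt$confidence[1] == "low")
    }
  }
  if (!length(segs))
    return(structure(data.frame(swing_id = integer(), side = character(),
                                start_frame = numeric(), end_frame = numeric(),
                                stance_side = character(),
                                stance_ic_frame = numeric(),
                                excluded = logical(), reason = character()),
                     class = c("swing_table", "data.frame")))
  sw <- do.call(rbind, segs)
  sw <- sw[order(sw$end_frame, sw$start_frame), ]
  sw$stance_side <- ifelse(sw$side == "left", "right", "left")
  sw$stance_ic_frame <- NA_real_
  sw$excluded <- FALSE
  sw$reason <- ""
  for (i in seq_len(nrow(sw))) {
    stic <- ev$frame[ev$side == sw$stance_side[i] &
                     ev$type == "initial_contact" &
                     ev$frame <= sw$start_frame[i]]
    if (!length(stic)) {
      sw$excluded[i] <- TRUE
      sw$reason[i] <- "no stance reference"
    } else {
      sw$stance_ic_frame[i] <- max(stic)
    }
    if (!sw$excluded[i] && sw$low_conf[i]) {
      sw$excluded[i] <- TRUE
      sw$reason[i] <- "low confidence event"
    }
  }
  sw$low_conf <- NULL
  sw$swing_id <- seq_len(nrow(sw))
  rownames(sw) <- NULL
  structure(sw[, c("swing_id", "side", "start_frame", "end_frame",
                   "stance_side", "stance_ic_frame", "excluded", "reason")],
            class = c("swing_table", "data.frame"))
}

#' Keep only the last n valid steps of a trial
#'
#' Steps are counted jointly across sides in time order. If fewer than `n`
#' valid segments exist, all are returned with a warning.
#'
#' @param swings A `swing_table` from [build_swings()].
#' @param n Number of steps to keep. Default 50, the analysis convention
#'   that makes step-count-sensitive measures comparable across trials.
#' @return The trailing `n` non-excluded rows of `swings`.
#' @export
select_last_n_steps <- function(swings, n = 50) {
  ok <- swings[!swings$excluded, ]
  ok <- ok[order(ok$end_frame), ]
  if (nrow(ok) < n) {
    warnf("only %d valid steps available (requested %d); returning all",
          nrow(ok), n)
    return(ok)
  }
  ok[seq(nrow(ok) - n + 1, nrow(ok)), ]
}
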