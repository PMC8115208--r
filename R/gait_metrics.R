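#' Step widths from marker trajectories and gait events
#'
#' Step width is the mediolateral distance between the contacting foot's
#' calcaneus at its initial contact and the contralateral calcaneus at the
#' contralateral side's preceding initial contact, reported as a magnitude.
#' Each step is attributed to the limb contacting at that initial contact
#' (so a "paretic" step width belongs to the step terminated by paretic
#' initial contact).
#'
#' @param ms A [marker_set()].
#' @param events A `gait_events` table from [detect_events()].
#' @param labels Named character `c(left = ..., right = ...)` mapping sides
#'   to limb labels (`"paretic"`, `"non_paretic"`, `"control"`).
#' @param ic_frames Optional vector of initial-contact frames to keep
#'   (e.g. the `end_frame`s of the selected last-50 swings).
#' @return A `step_table` data.frame: `step_id`, `leading_side`, `frame`,
#'   `width_m`, `limb_label`. Steps without a preceding contralateral
#'   initial contact are skipped.
#' @export
compute_step_widths <- function(ms, events,
                                labels = c(left = "control", right = "control"),
                                ic_frames = NULL) {
  ev <- as.data.frame(events)
  ics <- ev[ev$type == "initial_contact", ]
  ics <- ics[order(ics$frame), ]
  heel <- c(left = "LCAL", right = "RCAL")
  out <- list()
  for (i in seq_len(nrow(ics))) {
    side <- ics$side[i]
    contra <- if (side == "left") "right" else "left"
    prev <- ics$frame[ics$side == contra & ics$frame < ics$frame[i]]
    if (!length(prev)) next
    w <- abs(marker_axis(ms, heel[[side]], "ml")[ics$frame[i] + 1] -
             marker_axis(ms, heel[[contra]], "ml")[max(prev) + 1])
    if (is.na(w)) next
    out[[length(out) + 1]] <- data.frame(
      leading_side = side, frame = ics$frame[i], width_m = w,
      limb_label = unname(labels[[side]]))
  }
  st <- if (length(out)) do.call(rbind, out) else
    data.frame(leading_side = character(), frame = numeric(),
               width_m = numeric(), limb_label = character())
  if (!is.null(ic_frames)) st <- st[st$frame %in% ic_frames, , drop = FALSE]
  st$step_id <- seq_len(nrow(st))
  rownames(st) <- NULL
  structure(st[, c("step_id", "leading_side", "frame", "width_m",
                   "limb_label")],
            class = c("step_table", "data.frame"))
}

#' Summarize step width per limb
#'
#' Mean and sample standard deviation (n - 1 denominator) of step width,
#' per limb label.
#'
#' @param records A `step_table` from [compute_step_widths()].
#' @param field Field condition label attached to the summary rows.
#' @return A data.frame `limb`, `field`, `mean_width_m`, `sd_width_m`,
#'   `n_steps`, `incomplete` (fewer than 2 steps).
#' @export
summarize_steps <- function(records, field = "null") {
  sp <- split(records, records$limb_label)
  out <- lapply(names(sp), function(lb) {
    w <- sp[[lb]]$width_m
    data.frame(limb = lb, field = field,
               mean_width_m = mean(w),
               sd_width_m = if (length(w) >= 2) sd(w) else NA_real_,
               n_steps = length(w),
               incomplete = length(w) < 2)
  })
  do.call(rbind, out)
}

#' Paired mean difference of a gait metric between two conditions
#'
#' Simple descriptive paired comparison (difference of per-subject values
#' and a paired t test); the full mixed-model treatment of step width is
#' out of scope here and can be run downstream on the exported summaries.
#'
#' @param a,b Per-subject metric values under the two conditions (equal
#'   length, matched order).
#' @return A list with `mean_diff`, `sd_diff`, `t`, `df`, `p`.
#' @export
paired_difference <- function(a, b) {
  d <- a - b
  n <- length(d)
  if (n < 2) stopf("need at least 2 paired values")
  tt <- stats::t.test(a, b, paired = TRUE)
  list(mean_diff = mean(d), sd_diff = sd(d),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
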