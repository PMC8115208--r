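#' Estimate the lateral COM state from the pelvis markers
#'
#' The COM proxy is the unweighted centroid of four pelvis markers
#' (bilateral iliac-spine and greater-trochanter markers by default);
#' lateral velocity is obtained by central finite differences at the
#' sampling rate (one-sided at the record ends).
#'
#' @param ms A [marker_set()].
#' @param com_markers The four pelvis marker labels averaged.
#' @return A data.frame with columns `frame` (0-based), `com_x` (absolute
#'   lateral COM position, m) and `com_v` (lateral COM velocity, m/s).
#' @export
estimate_com <- function(ms, com_markers = SF_COM_MARKERS) {
  validate_markers(ms, com_markers)
  lat <- vapply(com_markers, function(l) marker_axis(ms, l, "ml"),
                numeric(ms$frames))
  if (anyNA(lat))
    stopf("pelvis marker(s) have missing samples over the record")
  pos <- rowMeans(lat)
  n <- length(pos)
  vel <- numeric(n)
  if (n >= 3) {
    vel[2:(n - 1)] <- (pos[3:n] - pos[1:(n - 2)]) * ms$rate_hz / 2
    vel[1] <- (pos[2] - pos[1]) * ms$rate_hz
    vel[n] <- (pos[n] - pos[n - 1]) * ms$rate_hz
  }
  data.frame(frame = seq_len(n) - 1L, com_x = pos, com_v = vel)
}

#' Lateral direction of each side's foot relative to the other
#'
#' Used to pool left and right swings into one sign convention (positive =
#' directed laterally away from the stance foot, toward the swing side).
#'
#' @param ms A [marker_set()].
#' @return Named numeric `c(left = ±1, right = ∓1)`: the sign, on the
#'   mediolateral lab axis, of each side's heel relative to the other.
#' @export
side_directions <- function(ms) {
  dl <- sign(median(marker_axis(ms, "LCAL", "ml"), na.rm = TRUE) -
             median(marker_axis(ms, "RCAL", "ml"), na.rm = TRUE))
  if (dl == 0) stopf("cannot determine lateral side directions from heels")
  c(left = dl, right = -dl)
}

#' Resample one swing's COM state onto the 0-100% grid
#'
#' Position is expressed relative to the stance-side calcaneus at its own
#' initial contact and signed toward the swing side; velocity is the
#' (signed) lateral COM velocity. Both are linearly interpolated onto the
#' swing-phase grid (node 0 = foot-off sample, node 100 = initial-contact
#' sample).
#'
#' @param com Output of [estimate_com()].
#' @param segment One row of a `swing_table`.
#' @param stance_ref Stance calcaneus lateral position (m, absolute).
#' @param side_dir Lateral direction of the swing side (`+1`/`-1` on the
#'   ml axis), from [side_directions()].
#' @param grid_step Grid spacing in % of swing. Default 2 (51 nodes).
#' @return A data.frame `node_pct`, `com_x` (m, stance-relative, signed),
#'   `com_v` (m/s, signed), or `NULL` for segments shorter than 5 frames.
#' @export
resample_swing <- function(com, segment, stance_ref, side_dir,
                           grid_step = 2) {
  i0 <- segment$start_frame
  i1 <- segment$end_frame
  if (i1 - i0 + 1 < 5) return(NULL)
  idx <- com$frame >= i0 & com$frame <= i1
  fr <- com$frame[idx]
  if (length(fr) != (i1 - i0 + 1))
    stopf("COM series does not cover swing frames %d..%d", i0, i1)
  pct <- sf_grid(grid_step)
  at <- i0 + (i1 - i0) * pct / 100
  pos <- approx(fr, side_dir * (com$com_x[idx] - stance_ref), xout = at)$y
  vel <- approx(fr, side_dir * com$com_v[idx], xout = at)$y
  data.frame(node_pct = pct, com_x = pos, com_v = vel)
}

#' Lateral foot placement of one swing
#'
#' Placement is the swing-side calcaneus lateral position at initial
#' contact minus the stance-side calcaneus lateral position at the stance
#' side's own preceding initial contact, signed so that placements
#' directed laterally away from the stance foot are positive.
#'
#' @param ms A [marker_set()].
#' @param segment One row of a `swing_table` (not excluded).
#' @param side_dirs Output of [side_directions()].
#' @return A one-row data.frame `swing_id`, `side`, `fp_x` (m),
#'   `implausible` (|fp_x| > 1 m).
#' @export
extract_foot_placement <- function(ms, segment, side_dirs = side_directions(ms)) {
  swing_heel <- if (segment$side == "left") "LCAL" else "RCAL"
  stance_heel <- if (segment$side == "left") "RCAL" else "LCAL"
  if (is.na(segment$stance_ic_frame))
    stopf("swing %s has no stance reference", segment$swing_id)
  sw <- marker_axis(ms, swing_heel, "ml")[segment$end_frame + 1]
  st <- marker_axis(ms, stance_heel, "ml")[segment$stance_ic_frame + 1]
  if (is.na(sw) || is.na(st))
    stopf("heel marker missing at the frames needed for foot placement")
  fp <- unname(side_dirs[[segment$side]]) * (sw - st)
  data.frame(swing_id = segment$swing_id, side = segment$side,
             fp_x = fp, implausible = abs(fp) > 1)
}

#' Swing-level design matrices for the foot-placement regression
#'
#' Convenience assembly: for every non-excluded swing, the COM state on the
#' 51-node grid and the realized foot placement, in the pooled sign
#' convention.
#'
#' @param ms A [marker_set()].
#' @param swings A `swing_table` (typically after [select_last_n_steps()]).
#' @param com Optional precomputed [estimate_com()] output.
#' @param grid_step Grid spacing in % of swing.
#' @return A list with `com_x`, `com_v` (n_swings x n_nodes matrices),
#'   `fp` (length n_swings), `sides`, `swing_id`, and `node_pct`.
#' @export
swing_design <- function(ms, swings, com = estimate_com(ms), grid_step = 2) {
  sd_ <- side_directions(ms)
  sw <- swings[!swings$excluded, , drop = FALSE]
  pct <- sf_grid(grid_step)
  nx <- length(pct)
  comx <- comv <- matrix(NA_real_, nrow(sw), nx)
  fp <- numeric(nrow(sw))
  keep <- rep(TRUE, nrow(sw))
  for (i in seq_len(nrow(sw))) {
    seg <- sw[i, ]
    stance_heel <- if (seg$side == "left") "RCAL" else "LCAL"
    stance_ref <- marker_axis(ms, stance_heel, "ml")[seg$stance_ic_frame + 1]
    rs <- resample_swing(com, seg, stance_ref, sd_[[seg$side]], grid_step)
    if (is.null(rs) || anyNA(rs$com_x) || anyNA(rs$com_v)) {
      keep[i] <- FALSE
      next
    }
    comx[i, ] <- rs$com_x
    comv[i, ] <- rs$com_v
    fpi <- extract_foot_placement(ms, seg, sd_)
    fp[i] <- fpi$fp_x
    if (fpi$implausible) keep[i] <- FALSE
  }
  list(com_x = comx[keep, , drop = FALSE], com_v = comv[keep, , drop = FALSE],
       fp = fp[keep], sides = sw$side[keep], swing_id = sw$swing_id[keep],
       node_pct = pct)
}
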