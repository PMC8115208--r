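#' Walker simulator configuration
#'
#' Parameters of the frontal-plane walker: within each step the lateral COM
#' obeys linear-inverted-pendulum dynamics about the stance foot,
#' `x'' = omega^2 (x - u) - (b/m) x'`, where `omega^2 = g / leg_length` and
#' `b` is the gain of the velocity-damping force field (0 = Null field,
#' 50 N s/m = the Damping field). Foot placement follows a COM-state
#' feedback law issued at `control_node_pct` of the swing:
#' `FP = nominal_width + gain_pos (p - p_ref) + gain_vel (w - w_ref) + eps`,
#' with `(p, w)` the stance-relative COM position and velocity signed
#' toward the swing side, `(p_ref, w_ref)` the periodic-gait values at the
#' control node, and `eps` zero-mean placement noise.
#'
#' Step-to-step variability is driven by a velocity perturbation ("kick",
#' `state_noise_sd`) at each step transition and optional white
#' acceleration noise within the step (`process_noise_sd`); without them a
#' noise-free walk collapses onto the periodic orbit.
#'
#' The `control` profile uses near-dead-beat gains (the return map of the
#' lateral inverted pendulum is unstable without state feedback; dead-beat
#' is `gain_pos = 1`, `gain_vel = cosh(omega T) / (omega sinh(omega T))`).
#' The `stroke_like` profile walks slower with wider, noisier steps and a
#' halved position gain.
#'
#' @param profile `"control"` or `"stroke_like"` preset.
#' @param ... Overrides of any field: `mass` (kg), `leg_length` (m),
#'   `step_duration` (s), `nominal_width` (m), `gain_pos` (dimensionless),
#'   `gain_vel` (s), `placement_noise_sd` (m), `state_noise_sd` (m/s),
#'   `process_noise_sd` (m/s^2), `control_node_pct` (% of swing),
#'   `damping_gain` (N s/m), `rate_hz`, `n_steps`, `seed`, `n_substeps`.
#' @return An object of class `walker_config`.
#' @export
walker_config <- function(profile = c("control", "stroke_like"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    mass = 75, leg_length = 0.9,
    step_duration = 0.5, nominal_width = 0.12,
    gain_pos = 1.0, gain_vel = 0.33,
    placement_noise_sd = 0.004, state_noise_sd = 0.004,
    process_noise_sd = 0.03,
    control_node_pct = 100,
    damping_gain = 0,
    rate_hz = 100, n_steps = 60, seed = NULL, n_substeps = 5)
  if (profile == "stroke_like") {
    cfg$step_duration <- 0.7
    cfg$nominal_width <- 0.18
    cfg$gain_pos <- 0.5
    cfg$gain_vel <- 0.46
    cfg$placement_noise_sd <- 0.008
    cfg$state_noise_sd <- 0.002
    cfg$process_noise_sd <- 0.015
  }
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stopf("unknown walker_config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg$omega <- sqrt(9.81 / cfg$leg_length)
  stopifnot(cfg$step_duration > 0, cfg$damping_gain >= 0,
            cfg$control_node_pct >= 0, cfg$control_node_pct <= 100,
            cfg$rate_hz > 0)
  structure(cfg, class = "walker_config")
}

# closed-form state-transition matrix of x'' = omega^2 x - c x' over time T
# (relative coordinates; roots are real and distinct for all c >= 0)
lip_step_matrix <- function(omega, c_damp, T) {
  disc <- sqrt(c_damp^2 + 4 * omega^2)
  s1 <- (-c_damp + disc) / 2
  s2 <- (-c_damp - disc) / 2
  e1 <- exp(s1 * T); e2 <- exp(s2 * T)
  den <- s1 - s2
  matrix(c((-s2 * e1 + s1 * e2) / den, (e1 - e2) / den,
           s1 * s2 * (e2 - e1) / den, (s1 * e1 - s2 * e2) / den),
         2, 2, byrow = TRUE)
}

# periodic-gait references: start state z0 = (p, w) (signed toward the
# swing side), and the reference state at the control node
walker_refs <- function(cfg) {
  c_damp <- cfg$damping_gain / cfg$mass
  MT <- lip_step_matrix(cfg$omega, c_damp, cfg$step_duration)
  z0 <- solve(diag(2) + MT, c(cfg$nominal_width, 0))
  f <- cfg$control_node_pct / 100
  Mf <- lip_step_matrix(cfg$omega, c_damp, f * cfg$step_duration)
  list(z0 = z0, ref = as.vector(Mf %*% z0), MT = MT, Mf = Mf)
}

# spectral radius of the step-to-step return map linearized about the
# periodic gait (deviations in signed coordinates)
walker_spectral_radius <- function(cfg) {
  r <- walker_refs(cfg)
  J <- rbind(c(cfg$gain_pos, cfg$gain_vel) %*% r$Mf - c(1, 0) %*% r$MT,
             -c(0, 1) %*% r$MT)
  max(Mod(eigen(J, only.values = TRUE)$values))
}

# RK4 integration of one step in absolute coordinates.
# state = c(x, v); returns (spf+1) x 2 matrix of samples (row 1 = state).
# kick is added to v at sample 2 (so the transition sample and its central
# difference stay functions of the within-step state only); process noise
# is a white acceleration held constant within each sampling interval.
integrate_step <- function(state, u, cfg, kick = 0, accel_noise = NULL) {
  spf <- round(cfg$step_duration * cfg$rate_hz)
  dt <- 1 / cfg$rate_hz
  h <- dt / cfg$n_substeps
  c_damp <- cfg$damping_gain / cfg$mass
  omega2 <- cfg$omega^2
  out <- matrix(NA_real_, spf + 1, 2)
  out[1, ] <- state
  x <- state[1]; v <- state[2]
  if (is.null(accel_noise)) accel_noise <- numeric(spf)
  for (j in seq_len(spf)) {
    if (j == 2) v <- v + kick
    an <- accel_noise[j]
    for (s in seq_len(cfg$n_substeps)) {
      acc <- function(x_, v_) omega2 * (x_ - u) - c_damp * v_ + an
      k1x <- v;                 k1v <- acc(x, v)
      k2x <- v + h / 2 * k1v;   k2v <- acc(x + h / 2 * k1x, v + h / 2 * k1v)
      k3x <- v + h / 2 * k2v;   k3v <- acc(x + h / 2 * k2x, v + h / 2 * k2v)
      k4x <- v + h * k3v;       k4v <- acc(x + h * k3x, v + h * k3v)
      x <- x + h / 6 * (k1x + 2 * k2x + 2 * k3x + k4x)
      v <- v + h / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    }
    if (abs(x - u) > 1)
      stopf("simulation diverged: |COM - stance| = %.2f m at step sample %d",
            abs(x - u), j)
    out[j + 1, ] <- c(x, v)
  }
  out
}

#' Simulate one step of the frontal-plane walker
#'
#' Integrates the lateral COM over one step (stance foot fixed at
#' `stance_pos`) and issues the next foot-placement command from the COM
#' state at the configured control node.
#'
#' @param state Numeric `c(x, v)`: absolute lateral COM position (m) and
#'   velocity (m/s) at the step start.
#' @param stance_pos Absolute lateral position of the stance foot (m).
#' @param side_dir `+1` or `-1`: lateral direction from the stance foot
#'   toward the swing side.
#' @param config A [walker_config()].
#' @param kick Velocity perturbation (m/s) applied just after the step
#'   start.
#' @param placement_noise Additive placement noise (m) for this step.
#' @param accel_noise Optional length-`spf` vector of acceleration noise
#'   (m/s^2), one value per sampling interval.
#' @return A list: `traj` ((spf+1) x 2 matrix of `x`, `v` samples),
#'   `fp_cmd` (commanded placement, m, positive away from the stance
#'   foot), `ctrl_state` (`c(p, w)` signed state at the control node) and
#'   `next_stance` (absolute landing position).
#' @export
simulate_step <- function(state, stance_pos, side_dir = 1,
                          config = walker_config(), kick = 0,
                          placement_noise = 0, accel_noise = NULL) {
  refs <- walker_refs(config)
  traj <- integrate_step(state, stance_pos, config, kick, accel_noise)
  spf <- nrow(traj) - 1
  j_ctrl <- round(config$control_node_pct / 100 * spf) + 1
  p_ctrl <- side_dir * (traj[j_ctrl, 1] - stance_pos)
  w_ctrl <- side_dir * traj[j_ctrl, 2]
  fp_cmd <- config$nominal_width +
    config$gain_pos * (p_ctrl - refs$ref[1]) +
    config$gain_vel * (w_ctrl - refs$ref[2]) +
    placement_noise
  list(traj = traj, fp_cmd = fp_cmd, ctrl_state = c(p_ctrl, w_ctrl),
       next_stance = stance_pos + side_dir * fp_cmd)
}

#' Simulate a full walking trial with marker-level output
#'
#' Chains [simulate_step()] with alternating sides, starting on the
#' periodic gait. Emits a [marker_set()] (four COM pelvis markers plus
#' posterior iliac markers, rigidly offset from the simulated COM, and
#' calcaneus / 5th-metatarsal markers per foot whose vertical profile is a
#' smooth arc peaking mid-swing) together with ground-truth events,
#' placements, COM trajectory, and the configuration. Output is
#' bit-reproducible per seed.
#'
#' The swing-foot path between lift and landing is a cosmetic
#' interpolation whose endpoints are exact (the analysis only uses foot
#' markers during stance and at the landing sample); its lateral
#' coordinate settles on the commanded placement at 95% of the swing.
#'
#' @param config A [walker_config()].
#' @return An object of class `sim_trial`: list with `markers`,
#'   `truth_events` (a `gait_events`-shaped data.frame), `truth_placements`
#'   (per step: side, frames, commanded and realized placement, control
#'   state), `truth_com` (frame, x, v), and `config`.
#' @export
simulate_trial <- function(config = walker_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  spf <- round(config$step_duration * config$rate_hz)
  n_steps <- config$n_steps
  n_frames <- n_steps * spf + 1
  W <- config$nominal_width
  refs <- walker_refs(config)

  # initial stance: right foot; left foot one width to the left (+ml)
  foot_pos <- c(left = W, right = 0)
  stance_side <- "right"
  side_dir_of <- c(left = +1, right = -1)

  s_dir <- side_dir_of[["left"]]
  x <- foot_pos[["right"]] + s_dir * refs$z0[1]
  v <- s_dir * refs$z0[2]

  com <- matrix(NA_real_, n_frames, 2)
  foot_lat <- matrix(NA_real_, n_frames, 2,
                     dimnames = list(NULL, c("left", "right")))
  foot_z <- matrix(0, n_frames, 2, dimnames = list(NULL, c("left", "right")))
  events <- list(data.frame(side = "right", type = "initial_contact",
                            frame = 0),
                 data.frame(side = "left", type = "foot_off", frame = 0))
  placements <- vector("list", n_steps)

  kicks <- rnorm(n_steps, 0, config$state_noise_sd)
  p_noise <- rnorm(n_steps, 0, config$placement_noise_sd)
  tau <- (0:spf) / spf
  z_arc <- 0.05 * sin(pi * tau)^2
  lat_ramp <- smoothstep(tau / 0.95)

  for (k in seq_len(n_steps)) {
    swing_side <- if (stance_side == "right") "left" else "right"
    s_dir <- side_dir_of[[swing_side]]
    u <- foot_pos[[stance_side]]
    accel_noise <- if (config$process_noise_sd > 0)
      rnorm(spf, 0, config$process_noise_sd) else NULL
    st <- simulate_step(c(x, v), u, s_dir, config,
                        kick = kicks[k], placement_noise = p_noise[k],
                        accel_noise = accel_noise)
    rows <- ((k - 1) * spf + 1):(k * spf + 1)
    com[rows, ] <- st$traj
    # stance foot: fixed; swing foot: cosmetic arc to the landing point
    from <- foot_pos[[swing_side]]
    foot_lat[rows, stance_side] <- u
    foot_lat[rows, swing_side] <- from + (st$next_stance - from) * lat_ramp
    foot_z[rows, swing_side] <- z_arc
    foot_z[rows[length(rows)], swing_side] <- 0

    placements[[k]] <- data.frame(
      step = k, swing_side = swing_side,
      fo_frame = (k - 1) * spf, ic_frame = k * spf,
      fp_cmd = st$fp_cmd, fp_realized = st$fp_cmd,
      p_ctrl = st$ctrl_state[1], w_ctrl = st$ctrl_state[2],
      stance_pos = u, landing_pos = st$next_stance)
    events[[length(events) + 1]] <-
      data.frame(side = swing_side, type = "initial_contact",
                 frame = k * spf)
    if (k < n_steps)
      events[[length(events) + 1]] <-
        data.frame(side = stance_side, type = "foot_off", frame = k * spf)

    # transition: landing foot becomes stance
    foot_pos[[swing_side]] <- st$next_stance
    x <- st$traj[spf + 1, 1]
    v <- st$traj[spf + 1, 2]
    stance_side <- swing_side
  }

  ev <- do.call(rbind, events)
  ev <- ev[order(ev$frame, ev$type != "foot_off"), ]
  ev$time_s <- ev$frame / config$rate_hz
  ev$confidence <- "ok"
  rownames(ev) <- NULL

  markers <- build_sim_markers(com[, 1], foot_lat, foot_z)
  trial <- list(
    markers = marker_set(markers, rate_hz = config$rate_hz),
    truth_events = structure(ev, class = c("gait_events", "data.frame")),
    truth_placements = do.call(rbind, placements),
    truth_com = data.frame(frame = seq_len(n_frames) - 1L,
                           x = com[, 1], v = com[, 2]),
    config = config)
  class(trial) <- "sim_trial"
  trial
}

#' @export
print.sim_trial <- function(x, ...) {
  cat(sprintf("<sim_trial> %s profile, %d steps @ %g s, damping %g N s/m\n",
              x$config$profile, x$config$n_steps, x$config$step_duration,
              x$config$damping_gain))
  invisible(x)
}

# marker cloud: rigid pelvis offsets around the COM (lateral offsets of
# the four COM markers cancel, so their centroid equals the COM exactly)
build_sim_markers <- function(com_x, foot_lat, foot_z) {
  n <- length(com_x)
  pelvis <- list(
    LASIS = c(+0.12, +0.10, 1.00), RASIS = c(-0.12, +0.10, 1.00),
    LPSIS = c(+0.10, -0.10, 1.05), RPSIS = c(-0.10, -0.10, 1.05),
    LGT   = c(+0.15,  0.00, 0.90), RGT   = c(-0.15,  0.00, 0.90))
  markers <- lapply(pelvis, function(off)
    cbind(x = com_x + off[1], y = rep(off[2], n), z = rep(off[3], n)))
  feet <- list(
    LCAL = list(side = "left", dlat = 0, dap = -0.05),
    RCAL = list(side = "right", dlat = 0, dap = -0.05),
    LMT5 = list(side = "left", dlat = +0.02, dap = 0.12),
    RMT5 = list(side = "right", dlat = -0.02, dap = 0.12))
  for (lab in names(feet)) {
    f <- feet[[lab]]
    markers[[lab]] <- cbind(x = foot_lat[, f$side] + f$dlat,
                            y = rep(f$dap, n),
                            z = foot_z[, f$side])
  }
  markers
}

#' Simulate an ensemble of independently initialized steps
#'
#' Each step starts from the periodic-gait state plus an independent
#' perturbation and is integrated once; the placement law is evaluated at
#' the control node. Unlike [simulate_trial()], steps are not chained, so
#' the placement law's gains need not stabilize the walker: this is the
#' mode for coefficient-recovery experiments (e.g. with literature gains
#' that lie outside the return map's stability region).
#'
#' @param config A [walker_config()] (`n_steps` steps are drawn).
#' @param init_sd_pos,init_sd_vel Standard deviations of the
#'   initial-state perturbations (m, m/s).
#' @return A data.frame with one row per step: `p_ctrl`, `w_ctrl` (signed
#'   COM state at the control node) and `fp` (commanded placement, m).
#' @export
simulate_step_ensemble <- function(config = walker_config(),
                                   init_sd_pos = 0.01, init_sd_vel = 0.05) {
  if (!is.null(config$seed)) set.seed(config$seed)
  refs <- walker_refs(config)
  n <- config$n_steps
  dp <- rnorm(n, 0, init_sd_pos)
  dw <- rnorm(n, 0, init_sd_vel)
  eps <- rnorm(n, 0, config$placement_noise_sd)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    st <- simulate_step(c(refs$z0[1] + dp[k], refs$z0[2] + dw[k]),
                        stance_pos = 0, side_dir = 1, config,
                        placement_noise = eps[k])
    out[[k]] <- data.frame(p_ctrl = st$ctrl_state[1],
                           w_ctrl = st$ctrl_state[2], fp = st$fp_cmd)
  }
  do.call(rbind, out)
}

#' Simulate a two-group cohort of walking trials
#'
#' Emulates a study design of `n_per_group` control and `n_per_group`
#' stroke-like subjects, each walking one trial per field condition (Null
#' and Damping, gain 50 N s/m). Subject-level heterogeneity is
#' multiplicative log-normal jitter on gains, width, noise and step
#' duration; jitter on the feedback gains is shrunk (deterministically,
#' halving) toward the profile means whenever it would push the
#' step-to-step return map's spectral radius above 0.95 in either field.
#'
#' @param n_per_group Subjects per group. Default 9.
#' @param seed Integer seed; per-trial seeds are derived from it.
#' @param n_steps Steps per trial. Default 60 (>= 50 valid steps after
#'   boundary losses).
#' @param damping_gain Damping-field gain in N s/m. Default 50.
#' @param paretic_side Side labeled paretic for stroke-like subjects.
#' @param jitter_sd Named list of log-normal jitter SDs.
#' @return A list of trial records: `subject`, `group`, `field`,
#'   `limb_labels` (named `c(left=, right=)`), `trial` (a `sim_trial`).
#' @export
make_cohort <- function(n_per_group = 9, seed = 1, n_steps = 60,
                        damping_gain = 50, paretic_side = "left",
                        jitter_sd = list(gain_pos = 0.08, gain_vel = 0.05,
                                         nominal_width = 0.08,
                                         placement_noise_sd = 0.15,
                                         step_duration = 0.05)) {
  set.seed(seed)
  subjects <- c(sprintf("C%02d", seq_len(n_per_group)),
                sprintf("S%02d", seq_len(n_per_group)))
  groups <- rep(c("control", "stroke"), each = n_per_group)
  trials <- list()
  for (i in seq_along(subjects)) {
    profile <- if (groups[i] == "control") "control" else "stroke_like"
    base <- walker_config(profile)
    jit <- lapply(jitter_sd, function(s) exp(rnorm(1, 0, s)))
    for (fld in c("null", "damping")) {
      cfg <- walker_config(
        profile,
        gain_pos = base$gain_pos * jit$gain_pos,
        gain_vel = base$gain_vel * jit$gain_vel,
        nominal_width = base$nominal_width * jit$nominal_width,
        placement_noise_sd = base$placement_noise_sd * jit$placement_noise_sd,
        step_duration = base$step_duration * jit$step_duration,
        damping_gain = if (fld == "damping") damping_gain else 0,
        n_steps = n_steps,
        seed = (seed + 7919L * i + 101L * (fld == "damping")) %% .Machine$integer.max)
      cfg <- stabilize_gains(cfg, base)
      if (groups[i] == "stroke") {
        labels <- c(left = "non_paretic", right = "non_paretic")
        labels[paretic_side] <- "paretic"
      } else {
        labels <- c(left = "control", right = "control")
      }
      trials[[length(trials) + 1]] <- list(
        subject = subjects[i], group = groups[i], field = fld,
        limb_labels = labels, trial = simulate_trial(cfg))
    }
  }
  trials
}

# halve the gain jitter toward the profile means until the return map is
# comfortably stable in the trial's own field
stabilize_gains <- function(cfg, base) {
  for (iter in 1:20) {
    if (walker_spectral_radius(cfg) < 0.95) return(cfg)
    cfg$gain_pos <- base$gain_pos + (cfg$gain_pos - base$gain_pos) / 2
    cfg$gain_vel <- base$gain_vel + (cfg$gain_vel - base$gain_vel) / 2
  }
  cfg$gain_pos <- base$gain_pos
  cfg$gain_vel <- base$gain_vel
  cfg
}
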