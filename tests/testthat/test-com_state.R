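test_that("COM is the pelvis-marker centroid and is affine-equivariant", {
  n <- 20
  lat <- cbind(0.10, 0.12, 0.08, 0.10)
  mks <- lapply(1:4, function(j)
    cbind(x = rep(lat[j], n), y = rep(0, n), z = rep(1, n)))
  names(mks) <- c("LASIS", "RASIS", "LGT", "RGT")
  ms <- marker_set(mks, rate_hz = 100)
  com <- estimate_com(ms)
  expect_equal(com$com_x, rep(0.10, n))
  expect_equal(com$com_v, rep(0, n))

  shifted <- ms
  for (lab in names(shifted$markers))
    shifted$markers[[lab]][, "x"] <- shifted$markers[[lab]][, "x"] + 0.05
  com2 <- estimate_com(shifted)
  expect_equal(com2$com_x, com$com_x + 0.05)
  expect_equal(com2$com_v, com$com_v)
})

test_that("marker-derived COM matches the simulated COM to numerical precision", {
  tr <- simulate_trial(walker_config("control", seed = 9, n_steps = 10))
  com <- estimate_com(tr$markers)
  expect_lt(max(abs(com$com_x - tr$truth_com$x)), 1e-9)
})

test_that("a missing pelvis marker sample is an error", {
  tr <- simulate_trial(walker_config("control", seed = 9, n_steps = 5))
  ms <- tr$markers
  ms$markers$LGT[10, ] <- NA
  expect_error(estimate_com(ms), "missing")
})

test_that("swing resampling: identity, linearity and sine accuracy", {
  # a 51-frame swing resamples to exactly the raw samples
  n <- 200
  com <- data.frame(frame = 0:(n - 1), com_x = rnorm(n), com_v = rnorm(n))
  seg <- data.frame(swing_id = 1, side = "left", start_frame = 20,
                    end_frame = 70, stance_side = "right",
                    stance_ic_frame = 15, excluded = FALSE)
  rs <- resample_swing(com, seg, stance_ref = 0, side_dir = 1)
  expect_equal(nrow(rs), 51)
  expect_equal(rs$node_pct, seq(0, 100, 2))
  expect_equal(rs$com_x, com$com_x[21:71])
  expect_equal(rs$com_v, com$com_v[21:71])

  # linear-in-time position: interpolated nodes lie on the same line
  com2 <- data.frame(frame = 0:99, com_x = 0.002 * (0:99) + 0.1,
                     com_v = rep(0.2, 100))
  seg2 <- seg; seg2$end_frame <- 57  # 38 frames, not aligned with grid
  rs2 <- resample_swing(com2, seg2, stance_ref = 0.05, side_dir = 1)
  expected <- 0.002 * (20 + (57 - 20) * rs2$node_pct / 100) + 0.1 - 0.05
  expect_equal(rs2$com_x, expected, tolerance = 1e-12)

  # sinusoidal trajectory, 0.7 s swing at 100 Hz: interp error < 1e-4 m
  t <- (0:99) / 100
  com3 <- data.frame(frame = 0:99, com_x = 0.05 * sin(2 * pi * 0.9 * t),
                     com_v = 0.05 * 2 * pi * 0.9 * cos(2 * pi * 0.9 * t))
  seg3 <- seg; seg3$start_frame <- 10; seg3$end_frame <- 80
  rs3 <- resample_swing(com3, seg3, stance_ref = 0, side_dir = 1)
  tt <- (10 + 70 * rs3$node_pct / 100) / 100
  expect_lt(max(abs(rs3$com_x - 0.05 * sin(2 * pi * 0.9 * tt))), 1e-4)

  # segments shorter than 5 frames are dropped
  seg4 <- seg; seg4$end_frame <- seg4$start_frame + 3
  expect_null(resample_swing(com, seg4, 0, 1))
})

test_that("sign convention: swing-side direction flips pooled quantities", {
  com <- data.frame(frame = 0:99, com_x = seq(0, 0.1, length.out = 100),
                    com_v = rep(0.1, 100))
  seg <- data.frame(swing_id = 1, side = "right", start_frame = 10,
                    end_frame = 60, stance_side = "left",
                    stance_ic_frame = 5, excluded = FALSE)
  rs_pos <- resample_swing(com, seg, 0.02, side_dir = 1)
  rs_neg <- resample_swing(com, seg, 0.02, side_dir = -1)
  expect_equal(rs_neg$com_x, -rs_pos$com_x)
  expect_equal(rs_neg$com_v, -rs_pos$com_v)
})

test_that("stance-relative position at node 100 is bookkeeping-consistent", {
  tr <- simulate_trial(walker_config("control", seed = 13, n_steps = 20))
  ms <- tr$markers
  com <- estimate_com(ms)
  sw <- build_swings(detect_events(ms))
  sw <- sw[!sw$excluded, ]
  sdirs <- side_directions(ms)
  seg <- sw[5, ]
  stance_heel <- if (seg$side == "left") "RCAL" else "LCAL"
  ref <- stridefield:::marker_axis(ms, stance_heel, "ml")[seg$stance_ic_frame + 1]
  rs <- resample_swing(com, seg, ref, sdirs[[seg$side]])
  abs_at_ic <- com$com_x[com$frame == seg$end_frame]
  expect_equal(sdirs[[seg$side]] * (abs_at_ic - ref), rs$com_x[51],
               tolerance = 1e-12)
})

test_that("foot placement: direct subtraction, zero case, generator truth", {
  mk_flat <- function(xl, xr) {
    n <- 50
    mks <- list(
      LCAL = cbind(x = rep(xl, n), y = 0, z = 0),
      RCAL = cbind(x = rep(xr, n), y = 0, z = 0))
    marker_set(mks, rate_hz = 100)
  }
  seg <- data.frame(swing_id = 1, side = "left", start_frame = 10,
                    end_frame = 40, stance_side = "right",
                    stance_ic_frame = 8, excluded = FALSE)
  ms <- mk_flat(0.15, 0)
  fp <- extract_foot_placement(ms, seg, side_dirs = c(left = 1, right = -1))
  expect_equal(fp$fp_x, 0.15)
  ms0 <- mk_flat(0.1, 0.1)
  fp0 <- extract_foot_placement(ms0, seg, side_dirs = c(left = 1, right = -1))
  expect_equal(fp0$fp_x, 0)

  # noise-free simulation: extracted equals commanded within 1e-6 m
  tr <- simulate_trial(walker_config("control", seed = 14, n_steps = 20,
                                     placement_noise_sd = 0))
  a <- analyze_trial(tr, last_n = 15)
  tp <- tr$truth_placements
  for (i in seq_along(a$design$fp)) {
    endf <- a$swings$end_frame[a$swings$swing_id == a$design$swing_id[i]]
    truth <- tp$fp_cmd[tp$ic_frame == endf]
    expect_lt(abs(a$design$fp[i] - truth), 1e-6)
  }
})
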