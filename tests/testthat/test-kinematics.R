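angles_of <- function(trace) as.matrix(as.data.frame(trace))

test_that("the wrist frame is right-handed, orthonormal and well-posed", {
  mk <- static_markers(frames = 1)
  fr <- build_wrist_frame(mk[1, ], side = "right")
  M <- cbind(fr$x, fr$y, fr$z)
  expect_equal(crossprod(M), diag(3), tolerance = 1e-9)
  expect_lt(abs(det(M) - 1), 1e-9)
  # z points from the wrist toward the elbow (proximal)
  O <- fr$origin
  E <- c(mean(c(mk$MEP_x[1], mk$LEP_x[1])),
         mean(c(mk$MEP_y[1], mk$LEP_y[1])),
         mean(c(mk$MEP_z[1], mk$LEP_z[1])))
  expect_gt(sum(fr$z * (E - O)), 0)
})

test_that("degenerate marker configurations are rejected", {
  mk <- as.data.frame(static_markers(frames = 1))
  bad <- mk
  bad[c("STR_x", "STR_y", "STR_z")] <- bad[c("STU_x", "STU_y", "STU_z")]
  expect_error(build_wrist_frame(bad, "right"), "STR",
               class = "wristemg_contract_error")
  expect_error(build_wrist_frame(mk[setdiff(names(mk), "MEP_x")],
                                 "right"),
               class = "wristemg_contract_error")
})

test_that("neutral pose gives zero deviation angles and 90 deg rotation", {
  n <- 16
  neutral <- angle_trace(matrix(c(0, 0, 90), n, 3, byrow = TRUE), 256)
  for (side in c("left", "right")) {
    mk <- forward_markers(neutral, arm_geometry(side), "POS2")
    ang <- angles_of(compute_angles(mk))
    expect_equal(max(abs(ang[, "alpha1"])), 0, tolerance = 1e-9)
    expect_equal(max(abs(ang[, "alpha2"])), 0, tolerance = 1e-9)
    # omega perpendicular to l: prono-supination neutral
    expect_equal(ang[, "alpha3"], rep(90, n), tolerance = 1e-9)
  }
})

test_that("scripted angles round-trip through the forward model", {
  tr <- script_angles(7, duration_s = 8, seed = 21)
  for (side in c("left", "right")) {
    mk <- forward_markers(tr, arm_geometry(side), "POS1")
    rec <- angles_of(compute_angles(mk))
    expect_lt(max(abs(rec - angles_of(tr))), 1e-6)
  }
})

test_that("mirrored bilateral movement yields equal traces on both sides", {
  tr <- script_angles(3, duration_s = 6, seed = 5)
  left <- angles_of(compute_angles(
    forward_markers(tr, arm_geometry("left"), "POS2")))
  right <- angles_of(compute_angles(
    forward_markers(tr, arm_geometry("right"), "POS2")))
  expect_equal(left, right, tolerance = 1e-9)
})

test_that("angles are invariant to the global limb pose", {
  tr <- script_angles(5, duration_s = 6, seed = 9)
  recs <- lapply(c("POS1", "POS2", "POS3"), function(p) {
    angles_of(compute_angles(forward_markers(tr, arm_geometry("right"),
                                             p)))
  })
  expect_equal(recs[[1]], recs[[2]], tolerance = 1e-8)
  expect_equal(recs[[1]], recs[[3]], tolerance = 1e-8)
})

test_that("marker gaps are repaired up to the limit, flagged beyond it", {
  tr <- script_angles(1, duration_s = 4, seed = 2)
  mk <- forward_markers(tr, arm_geometry("right"), "POS1")
  co <- as.data.frame(mk)
  co[100:110, c("RMC_x", "RMC_y", "RMC_z")] <- NA      # 43 ms: repairable
  co[400:600, c("STR_x", "STR_y", "STR_z")] <- NA      # 0.78 s: too long
  mk2 <- marker_set(co, 256, side = "right")
  ang <- compute_angles(mk2)
  inv <- attr(ang, "invalid")
  expect_false(any(inv[100:110]))
  expect_true(all(inv[400:600]))
  expect_false(anyNA(angles_of(ang)[!inv, ]))
  expect_true(all(is.na(angles_of(ang)[inv, ])))
  # repaired frames stay close to the truth
  expect_lt(max(abs(angles_of(ang)[100:110, ] -
                      angles_of(tr)[100:110, ])), 0.5)
})

test_that("angle conditioning preserves slow content, rejects jitter", {
  n <- 2560  # 10 s at 256 Hz
  t <- (0:(n - 1)) / 256
  # constant trace survives untouched
  const <- angle_trace(matrix(c(30, -10, 120), n, 3, byrow = TRUE), 256)
  cc <- condition_angles(const)
  expect_equal(rate_hz(cc), 1024)
  expect_equal(nrow(cc), 4 * n)
  expect_equal(angles_of(cc)[, "alpha1"], rep(30, 4 * n),
               tolerance = 0.1 / 30)
  # 0.25 Hz movement passes with < 2% amplitude loss
  slow <- angle_trace(cbind(40 * sin(2 * pi * 0.25 * t), 0 * t,
                            90 + 0 * t), 256)
  cs <- condition_angles(slow)
  mid <- 2000:8000
  ref <- 40 * sin(2 * pi * 0.25 * (0:(nrow(cs) - 1)) / 1024)
  expect_equal(sqrt(mean(angles_of(cs)[mid, 1]^2)) /
                 sqrt(mean(ref[mid]^2)), 1, tolerance = 0.02)
  # 20 Hz jitter attenuated by > 15 dB
  fast <- angle_trace(cbind(5 * sin(2 * pi * 20 * t), 0 * t, 90 + 0 * t),
                      256)
  cf <- condition_angles(fast)
  att <- sqrt(mean(angles_of(cf)[mid, 1]^2)) / sqrt(mean((5 / sqrt(2))^2))
  expect_lt(att, 10^(-15 / 20))
})

test_that("window targets average angles over the feature windows", {
  spec <- window_spec(100, 60, 1024)
  n <- 4096
  const <- angle_trace(matrix(30, n, 3), 1024)
  wt <- window_targets(const, spec)
  expect_equal(wt$alpha1, rep(30, nrow(wt)))
  # a linear ramp averages to its window-midpoint value
  slope <- 0.01
  ramp <- angle_trace(cbind(slope * (0:(n - 1)), rep(0, n), rep(90, n)),
                      1024)
  wt2 <- window_targets(ramp, spec)
  midpoints <- slope * (wt2$start - 1 + (spec$length_smp - 1) / 2)
  expect_equal(wt2$alpha1, midpoints, tolerance = 1e-9)
  # row count equals the feature row count for the same stream length
  emg <- tiny_emg(n = n, rate = 1024)
  expect_equal(nrow(wt), nrow(extract_features(emg, spec)))
})
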