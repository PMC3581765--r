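test_that("scripted runs honour the movement protocol", {
  # run 1: DoF1 sinusoidal, DoF2 held near max, DoF3 neutral
  tr1 <- script_angles(1, duration_s = 10, seed = 1)
  a <- as.matrix(as.data.frame(tr1))
  expect_gt(sd(a[, "alpha1"]), 5)
  expect_equal(unique(a[, "alpha2"]), 0.9 * 60)
  expect_equal(unique(a[, "alpha3"]), 90)
  # run 4: DoF3 sinusoidal, DoF1 held, DoF2 neutral
  tr4 <- script_angles(4, duration_s = 10, seed = 1)
  a4 <- as.matrix(as.data.frame(tr4))
  expect_gt(sd(a4[, "alpha3"]), 5)
  expect_equal(unique(a4[, "alpha1"]), 0.9 * 60)
  expect_equal(unique(a4[, "alpha2"]), 0)
  # run 7 articulates all three
  tr7 <- script_angles(7, duration_s = 10, seed = 1)
  a7 <- as.matrix(as.data.frame(tr7))
  expect_true(all(apply(a7, 2, sd) > 5))
  # ranges stay inside the conventions
  for (tr in list(tr1, tr4, tr7)) {
    m <- as.matrix(as.data.frame(tr))
    expect_true(all(abs(m[, "alpha1"]) <= 90))
    expect_true(all(abs(m[, "alpha2"]) <= 90))
    expect_true(all(m[, "alpha3"] >= 0 & m[, "alpha3"] <= 180))
  }
  # determinism and seed sensitivity
  expect_identical(as.data.frame(script_angles(7, 5, seed = 3)),
                   as.data.frame(script_angles(7, 5, seed = 3)))
  expect_false(identical(as.data.frame(script_angles(7, 5, seed = 3)),
                         as.data.frame(script_angles(7, 5, seed = 4))))
  expect_error(script_angles(8), class = "wristemg_contract_error")
})

test_that("cycle half-periods fall in the 1-2 s protocol band", {
  tr <- script_angles(1, duration_s = 60, seed = 6)
  a1 <- tr$alpha1
  # zero runs between excursions bound each half-cycle
  nz <- abs(a1) > 1e-9
  runs <- rle(nz)
  durs <- runs$lengths[runs$values] / 256
  durs <- durs[-length(durs)]  # last may be truncated at the run end
  expect_true(all(durs > 0.97 & durs < 2.03))
})

test_that("marker noise propagates to about the expected angle error", {
  tr <- script_angles(2, duration_s = 10, seed = 3)
  mk <- forward_markers(tr, arm_geometry("left"), "POS2",
                        noise_sd_mm = 0.5, seed = 8)
  rec <- as.matrix(as.data.frame(compute_angles(mk)))
  err <- rec - as.matrix(as.data.frame(tr))
  expect_lt(sqrt(mean(err^2)), 1)   # < 1 deg RMS at 0.5 mm noise
  expect_gt(sqrt(mean(err^2)), 0.1) # but clearly nonzero
})

test_that("synthetic EMG envelope follows the gain model", {
  n <- 5 * 256
  neutral <- angle_trace(matrix(c(0, 0, 90), n, 3, byrow = TRUE), 256)
  # zero gains: pure noise floor; MAV of a Gaussian carrier is
  # floor * sqrt(2/pi)
  floor_ <- 0.5
  cfg0 <- emg_synth_config(gains = matrix(0, 7, 6), noise_floor = floor_)
  emg0 <- synthesize_emg(neutral, cfg0, seed = 9)
  f0 <- extract_features(resample_emg(emg0, 1024),
                         window_spec(rate_hz = 1024))
  expect_equal(mean(f0$ch1_mav), floor_ * sqrt(2 / pi), tolerance = 0.05)
  # doubling one channel's gain doubles its MAV (same carrier seed)
  tr <- script_angles(1, duration_s = 5, seed = 2)
  G <- default_gain_matrix()
  G2 <- G
  G2[3, ] <- 2 * G[3, ]
  cfg1 <- emg_synth_config(gains = G, noise_floor = 0)
  cfg2 <- emg_synth_config(gains = G2, noise_floor = 0)
  e1 <- synthesize_emg(tr, cfg1, seed = 4)
  e2 <- synthesize_emg(tr, cfg2, seed = 4)
  expect_equal(mean(abs(e2[[3]])), 2 * mean(abs(e1[[3]])),
               tolerance = 1e-9)
  expect_equal(mean(abs(e2[[1]])), mean(abs(e1[[1]])), tolerance = 1e-9)
})

test_that("the position effect rescales channels multiplicatively", {
  tr <- script_angles(1, duration_s = 4, seed = 2)
  cfg <- with_position_effect(emg_synth_config(), sigma_g = 0.3,
                              seed = 31)
  expect_true(all(cfg$position_gain > 0))
  expect_false(all(cfg$position_gain == 1))
  e1 <- synthesize_emg(tr, cfg, "POS1", seed = 4)
  e2 <- synthesize_emg(tr, cfg, "POS2", seed = 4)
  # same carrier, different per-channel scale and baseline
  expect_false(isTRUE(all.equal(mean(abs(e1[[1]])), mean(abs(e2[[1]])))))
  # the null configuration leaves positions statistically identical
  null <- emg_synth_config()
  n1 <- synthesize_emg(tr, null, "POS1", seed = 4)
  n2 <- synthesize_emg(tr, null, "POS2", seed = 4)
  expect_equal(as.matrix(as.data.frame(n1)), as.matrix(as.data.frame(n2)))
})

test_that("session generation writes a complete, valid, reproducible set", {
  dir1 <- withr::local_tempdir()
  m <- generate_session(dir1, master_seed = 5, duration_s = 2,
                        marker_noise_sd = 0.2)
  expect_length(list.files(dir1, pattern = "^emg_"), 42)
  expect_length(list.files(dir1, pattern = "^markers_"), 42)
  expect_true(validate_manifest(m, dir = dir1))
  back <- read_manifest(file.path(dir1, "manifest.tsv"))
  expect_true(validate_manifest(back, dir = dir1))
  # generated files pass the readers' validation
  emg <- read_emg_tsv(file.path(dir1, m$runs$emg_file[1]))
  expect_equal(ncol(emg), 7)
  expect_equal(rate_hz(emg), 2048)
  expect_false(is.null(attr(emg, "sync")))
  mk <- read_markers_tsv(file.path(dir1, m$runs$marker_file[1]))
  expect_false(any(gap_mask(mk)))
  # determinism: a second generation is byte-identical
  dir2 <- withr::local_tempdir()
  generate_session(dir2, master_seed = 5, duration_s = 2,
                   marker_noise_sd = 0.2)
  for (f in c("manifest.tsv", m$runs$emg_file[10],
              m$runs$marker_file[10])) {
    expect_identical(readLines(file.path(dir2, f)),
                     readLines(file.path(dir1, f)))
  }
})

test_that("a loaded session reprocesses like the in-memory one", {
  dir <- withr::local_tempdir()
  generate_session(dir, master_seed = 9, duration_s = 2,
                   positions = "POS1", runs = 1:2)
  suppressWarnings(m <- read_manifest(file.path(dir, "manifest.tsv")))
  ses <- load_session(m, dir, control_side = "right")
  expect_s3_class(ses, "emg_session")
  expect_equal(nrow(ses$runs), 2)
  dat <- process_session(ses)
  expect_true(all(c("position", "run", "alpha1") %in% names(dat)))
  expect_equal(length(feature_cols(dat)), 70)
  expect_gt(nrow(dat), 0)
})

test_that("amputee mode flattens the control side's channel tuning", {
  cfg <- emg_synth_config(channel_mix = 0.5)
  G <- default_gain_matrix()
  flat <- matrix(colMeans(G), 7, 6, byrow = TRUE)
  expect_equal(cfg$gains, 0.5 * G + 0.5 * flat, ignore_attr = TRUE)
  ses <- simulate_session(master_seed = 1, duration_s = 2,
                          positions = "POS1", runs = 1,
                          group = "amputee")
  expect_equal(ses$params$group, "amputee")
})
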