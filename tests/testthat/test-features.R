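test_that("MAV matches its definition and the analytic sinusoid mean", {
  expect_equal(mav(rep(-2, 50)), 2)
  expect_equal(mav(c(1, -1, 1, -1)), 1)
  # mean |sin| over full periods = 2/pi
  t <- seq(0, 1, length.out = 10001)[-10001]
  expect_equal(mav(sin(2 * pi * 5 * t)), 2 / pi, tolerance = 0.01)
  expect_error(mav(numeric(0)), class = "wristemg_contract_error")
})

test_that("MAV slope is the forward difference with a zero tail", {
  expect_equal(mavs(c(2, 2, 2, 2)), c(0, 0, 0, 0))
  expect_equal(mavs(c(1, 2, 4, 7)), c(1, 2, 3, 0))
  expect_message(res <- mavs(5), "single")
  expect_equal(res, 0)
})

test_that("ZC and SSC match enumeration on the stated examples", {
  expect_equal(zero_crossings(c(1, -1, 1, -1), 0), 3)
  expect_equal(zero_crossings(c(2, 1, 3, 0.5), 0), 0)
  expect_equal(slope_sign_changes(1:10, 0), 0)
  expect_equal(slope_sign_changes(c(0, 1, 0, 1, 0), 0), 3)
  # dense k-period sinusoid: 2k crossings and 2k extrema, +/- 1
  k <- 7
  x <- sin(2 * pi * k * seq(0, 1, length.out = 2000))
  expect_lte(abs(zero_crossings(x, 0) - 2 * k), 1)
  expect_lte(abs(slope_sign_changes(x, 0) - 2 * k), 1)
})

test_that("ZC and SSC agree with brute-force oracles on random windows", {
  withr::with_seed(11, {
    for (i in 1:200) {
      n <- sample(10:120, 1)
      x <- rnorm(n)
      eps <- sample(c(0, 0.1, 0.5, 1.5), 1)
      expect_identical(zero_crossings(x, eps), oracle_zc(x, eps))
      expect_identical(slope_sign_changes(x, eps), oracle_ssc(x, eps))
      expect_equal(mav(x), oracle_mav(x))
    }
  })
})

test_that("ZC and SSC are non-increasing in the dead-zone threshold", {
  withr::with_seed(4, {
    for (i in 1:25) {
      x <- rnorm(80)
      epss <- sort(runif(6, 0, 2))
      zc <- vapply(epss, function(e) zero_crossings(x, e), numeric(1))
      ssc <- vapply(epss, function(e) slope_sign_changes(x, e),
                    numeric(1))
      expect_true(all(diff(zc) <= 0))
      expect_true(all(diff(ssc) <= 0))
    }
  })
})

test_that("LMS predictor recovers AR structure and rejects divergence", {
  # white noise: no structure, coefficients near zero
  w <- withr::with_seed(42, rnorm(2048))
  expect_lt(sqrt(sum(ar_coefficients_lms(w)^2)), 0.15)
  # AR(2) embedded in the 6-coefficient predictor
  truth <- c(0.5, -0.25, 0, 0, 0, 0)
  for (s in c(7, 8, 101)) {
    x <- ar_process(c(0.5, -0.25), 2048, seed = s)
    expect_lt(max(abs(ar_coefficients_lms(x) - truth)), 0.1)
  }
  # constant window: no adaptation
  expect_equal(ar_coefficients_lms(rep(0, 200)), rep(0, 6))
  # an unstable step size is reported, not returned
  expect_error(
    ar_coefficients_lms(withr::with_seed(1, rnorm(500)), step_size = 2),
    "step_size", class = "wristemg_data_error")
})

test_that("feature extraction has the documented window layout", {
  spec <- window_spec(100, 60, 1024)
  expect_equal(spec$length_smp, 102L)
  expect_equal(spec$step_smp, 41L)
  # 65 s at 1024 Hz
  expect_equal(n_windows(66560, spec), 1621L)
  emg <- tiny_emg(n = 4096, rate = 1024, seed = 2)
  fm <- extract_features(emg, spec)
  expect_equal(nrow(fm), n_windows(4096, spec))
  expect_equal(length(feature_cols(fm)), 70)
  expect_false(anyNA(fm))
  expect_true(all(fm$ch1_mav >= 0))
  expect_true(all(fm$ch3_zc >= 0 & fm$ch3_zc <= spec$length_smp))
  # single window
  one <- extract_features(tiny_emg(n = 102, rate = 1024), spec)
  expect_equal(nrow(one), 1)
  expect_error(extract_features(tiny_emg(n = 50, rate = 1024), spec),
               class = "wristemg_contract_error")
})

test_that("window counts hold for randomized stream lengths", {
  withr::with_seed(9, {
    for (i in 1:40) {
      len <- sample(20:200, 1)
      ov <- sample(0:(len - 1), 1)
      spec <- window_spec(len, ov, 1024)
      n <- sample(spec$length_smp:20000, 1)
      expect_equal(n_windows(n, spec),
                   floor((n - spec$length_smp) / spec$step_smp) + 1)
      # last window fits inside the stream
      starts <- (n_windows(n, spec) - 1) * spec$step_smp + 1
      expect_lte(starts + spec$length_smp - 1, n)
    }
  })
})

test_that("features obey scale equivariance", {
  emg <- tiny_emg(n = 1024, rate = 1024, seed = 3)
  c_ <- 3.7
  scaled <- emg_recording(as.matrix(as.data.frame(emg)) * c_, 1024)
  spec <- window_spec(rate_hz = 1024)
  f1 <- extract_features(emg, spec, eps_amp = 0)
  f2 <- extract_features(scaled, spec, eps_amp = 0)
  for (ch in c("ch1", "ch5")) {
    expect_equal(f2[[paste0(ch, "_mav")]], c_ * f1[[paste0(ch, "_mav")]])
    expect_equal(f2[[paste0(ch, "_mavs")]],
                 c_ * f1[[paste0(ch, "_mavs")]])
    expect_equal(f2[[paste0(ch, "_zc")]], f1[[paste0(ch, "_zc")]])
    expect_equal(f2[[paste0(ch, "_ssc")]], f1[[paste0(ch, "_ssc")]])
    # AR coefficients are computed on unit-variance windows: exact
    for (k in 1:6) {
      expect_equal(f2[[paste0(ch, "_ar", k)]],
                   f1[[paste0(ch, "_ar", k)]], tolerance = 1e-12)
    }
  }
})

test_that("ramp-modulated noise yields a positive mean MAV slope", {
  n <- 8 * 1024
  env <- seq(0.2, 2, length.out = n)
  x <- withr::with_seed(5, rnorm(n)) * env
  emg <- emg_recording(matrix(x, ncol = 1), 1024)
  fm <- extract_features(emg, window_spec(rate_hz = 1024))
  slopes <- fm$ch1_mavs[-nrow(fm)]  # last window carries the 0 sentinel
  expect_gt(mean(slopes), 0)
  # MAV itself tracks the ramp: strongly increasing across the stream
  expect_gt(cor(fm$ch1_mav, seq_len(nrow(fm))), 0.95)
})
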