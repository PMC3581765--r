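# Shared fixtures, built in code.

# A small EMG recording of seeded white noise.
tiny_emg <- function(n = 2048, channels = 7, rate = 2048, seed = 1,
                     sync = NULL) {
  m <- withr::with_seed(seed, matrix(rnorm(n * channels), n, channels))
  emg_recording(m, rate, side = "right", run = 1L, position = "POS1",
                sync = sync)
}

# A marker set at one repeated static pose (straight arm along +z).
static_markers <- function(frames = 10, rate = 256, side = "right") {
  tr <- angle_trace(matrix(c(0, 0, 90), frames, 3, byrow = TRUE), rate)
  forward_markers(tr, arm_geometry(side), "POS1")
}

# 20 Hz square wave helper mirroring the generator's convention.
square <- function(n, rate, t0 = 0, freq = 20, amp = 5) {
  t <- (seq_len(n) - 1) / rate + t0
  ifelse(((t * freq) %% 1) < 0.5, amp, -amp)
}

# Brute-force TD feature oracles (independent loop implementations).
oracle_mav <- function(x) {
  s <- 0
  for (v in x) s <- s + abs(v)
  s / length(x)
}

oracle_zc <- function(x, eps = 0) {
  cnt <- 0L
  for (i in seq_len(length(x) - 1)) {
    opposite <- (x[i] > 0 && x[i + 1] < 0) || (x[i] < 0 && x[i + 1] > 0)
    if (opposite && abs(x[i] - x[i + 1]) > eps) cnt <- cnt + 1L
  }
  cnt
}

oracle_ssc <- function(x, eps = 0) {
  cnt <- 0L
  for (i in 2:(length(x) - 1)) {
    d1 <- x[i] - x[i - 1]
    d2 <- x[i] - x[i + 1]
    if (d1 * d2 > 0 && abs(d1) > eps && abs(d2) > eps) cnt <- cnt + 1L
  }
  cnt
}

# Brute-force double-sum multivariate R^2 (independent of the package's
# vectorized implementation).
oracle_r2 <- function(est, tgt) {
  est <- as.matrix(est)
  tgt <- as.matrix(tgt)
  num <- 0
  den <- 0
  for (i in seq_len(ncol(tgt))) {
    m <- 0
    for (t in seq_len(nrow(tgt))) m <- m + tgt[t, i]
    m <- m / nrow(tgt)
    for (t in seq_len(nrow(tgt))) {
      num <- num + (est[t, i] - tgt[t, i])^2
      den <- den + (tgt[t, i] - m)^2
    }
  }
  1 - num / den
}

# Synthetic AR process driven by seeded Gaussian noise.
ar_process <- function(coefs, n, seed, burn = 200) {
  p <- length(coefs)
  e <- withr::with_seed(seed, rnorm(n + burn))
  x <- numeric(n + burn)
  for (t in seq_len(n + burn)) {
    past <- 0
    for (k in seq_len(min(p, t - 1))) past <- past + coefs[k] * x[t - k]
    x[t] <- past + e[t]
  }
  x[(burn + 1):(burn + n)]
}
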