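# Synthetic recording sessions.
#
# The generator emulates one recording session of the study protocol:
# 3 arm positions x 7 movement runs of bilateral mirrored wrist
# articulation, with per-run scripted angle trajectories, a rigid-segment
# forward model placing the 7 anatomical markers (so the kinematics module
# recovers the scripted angles exactly in the noiseless case), and
# amplitude-modulated band-limited noise as surface EMG, driven by the
# rectified angular excursions through a per-channel gain matrix. A
# parametric arm-position effect (per-position multiplicative channel
# gains plus an additive baseline shift) emulates electrode-muscle
# geometry changes across arm positions.

#' The seven-run movement protocol
#'
#' Runs 1-6 articulate one DoF sinusoidally while holding a second DoF
#' near its maximal range; run 7 articulates DoF1 and DoF2 cyclically
#' while alternating the direction of DoF3.
#'
#' @return a tibble with columns `run`, `sin_dofs` (list), `held_dof`
#'   (NA for run 7), `active_dofs` (list) and `active_dofs_label`.
#' @export
run_table <- function() {
  tibble(
    run = 1:7,
    sin_dofs = list(1L, 2L, 1L, 3L, 2L, 3L, c(1L, 2L, 3L)),
    held_dof = c(2L, 1L, 3L, 1L, 3L, 2L, NA_integer_),
    active_dofs = list(c(1L, 2L), c(1L, 2L), c(1L, 3L), c(1L, 3L),
                       c(2L, 3L), c(2L, 3L), c(1L, 2L, 3L)),
    active_dofs_label = c("1+2", "1+2", "1+3", "1+3", "2+3", "2+3",
                          "1+2+3"))
}

#' Rigid-segment arm geometry for the marker forward model
#'
#' Segment lengths and marker-pair widths in mm; defaults are adult-scale.
#'
#' @param side `"left"` or `"right"`.
#' @param upper_arm_mm,forearm_mm,hand_mm segment lengths (shoulder-elbow,
#'   elbow-wrist, wrist to metacarpal heads).
#' @param elbow_width_mm MEP-LEP distance.
#' @param wrist_width_mm STU-STR distance.
#' @param hand_width_mm UMC-RMC distance.
#' @return an `arm_geometry` list.
#' @export
arm_geometry <- function(side = "right", upper_arm_mm = 300,
                         forearm_mm = 260, hand_mm = 80,
                         elbow_width_mm = 70, wrist_width_mm = 55,
                         hand_width_mm = 80) {
  lens <- c(upper_arm_mm, forearm_mm, hand_mm, elbow_width_mm,
            wrist_width_mm, hand_width_mm)
  if (any(lens <= 0)) stop_contract("geometry lengths must be positive")
  structure(list(side = side, upper_arm_mm = upper_arm_mm,
                 forearm_mm = forearm_mm, hand_mm = hand_mm,
                 elbow_width_mm = elbow_width_mm,
                 wrist_width_mm = wrist_width_mm,
                 hand_width_mm = hand_width_mm),
            class = "arm_geometry")
}

# One neutral-extreme-neutral excursion lasts 1-2 s (drawn per cycle);
# consecutive excursions alternate direction. The sin^2 bump is C1 at the
# neutral joins.
scripted_dof <- function(kind, n, rate, amplitude, hold_frac = 0.9) {
  if (kind == "off") return(rep(0, n))
  if (kind == "hold") return(rep(hold_frac * amplitude, n))
  out <- numeric(n)
  i <- 1L
  sgn <- 1
  while (i <= n) {
    T_half <- runif(1, 1, 2)
    m <- max(1L, as.integer(round(T_half * rate)))
    j <- min(n, i + m - 1L)
    tt <- (seq(i, j) - i) / m
    out[i:j] <- sgn * amplitude * sin(pi * tt)^2
    sgn <- -sgn
    i <- j + 1L
  }
  out
}

#' Script the wrist angle trajectories of one run
#'
#' Produces the (shared, mirrored) angle trace both arms follow during a
#' run: the run's sinusoidal DoFs articulate in alternating-direction
#' neutral-extreme-neutral cycles whose half-period is drawn uniformly
#' from 1-2 s per cycle; a held DoF stays near its maximal range; inactive
#' DoFs stay neutral (0 deg, or 90 deg for forearm rotation).
#'
#' @param run run index 1..7 (see [run_table()]).
#' @param duration_s run duration in seconds (default 65).
#' @param rate_hz kinematic sampling rate (default 256).
#' @param amplitude_deg excursion amplitudes for the three DoFs, degrees.
#' @param hold_frac fraction of the amplitude used by held DoFs.
#' @param seed RNG seed (cycle periods are random).
#' @return an [angle_trace()] at `rate_hz`; both sides of the mirrored
#'   movement share this trace.
#' @export
script_angles <- function(run, duration_s = 65, rate_hz = 256,
                          amplitude_deg = c(60, 60, 60), hold_frac = 0.9,
                          seed = 1) {
  if (!run %in% 1:7) stop_contract("run must be in 1..7")
  rt <- run_table()
  sin_dofs <- rt$sin_dofs[[run]]
  held <- rt$held_dof[run]
  n <- as.integer(round(duration_s * rate_hz))
  withr::with_seed(seed, {
    delta <- vapply(1:3, function(d) {
      kind <- if (d %in% sin_dofs) "sin"
      else if (!is.na(held) && d == held) "hold"
      else "off"
      scripted_dof(kind, n, rate_hz, amplitude_deg[d], hold_frac)
    }, numeric(n))
  })
  alpha <- cbind(alpha1 = delta[, 1], alpha2 = delta[, 2],
                 alpha3 = 90 + delta[, 3])
  angle_trace(alpha, rate_hz)
}

rot_x <- function(a) {
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rot_z <- function(a) {
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# Global limb poses for the three arm positions: rigid rotations and
# translations of the whole marker cloud (a rigid pose change leaves the
# wrist angles invariant; it stands in for the shoulder/elbow
# configuration differences between positions).
position_pose <- function(position) {
  switch(position,
         POS1 = list(R = diag(3), t = c(0, 0, 1000)),
         POS2 = list(R = rot_z(40 * pi / 180) %*% rot_x(15 * pi / 180),
                     t = c(100, 50, 950)),
         POS3 = list(R = rot_x(80 * pi / 180), t = c(0, 200, 1100)),
         stop_contract("position must be POS1, POS2 or POS3"))
}

#' Forward-model marker trajectories from a wrist angle trace
#'
#' Places the 7 anatomical markers of one arm frame by frame so that
#' [compute_angles()] recovers the scripted angles exactly in the
#' noiseless case. The arm position applies a global rigid pose to the
#' whole marker cloud; the left arm is the mirror image of the right
#' (mirrored bilateral movement). Optional isotropic Gaussian marker
#' noise emulates the motion-capture error.
#'
#' @param trace an [angle_trace()] (the scripted wrist angles).
#' @param geometry an [arm_geometry()]; its `side` selects the arm.
#' @param position `"POS1"`, `"POS2"` or `"POS3"`.
#' @param noise_sd_mm isotropic marker noise standard deviation (mm).
#' @param seed RNG seed for the noise.
#' @return a [marker_set()] at the trace rate.
#' @export
forward_markers <- function(trace, geometry = arm_geometry(),
                            position = "POS1", noise_sd_mm = 0,
                            seed = 1) {
  stopifnot(is_angle_trace(trace), inherits(geometry, "arm_geometry"))
  n <- nrow(trace)
  rad <- pi / 180
  a1 <- trace$alpha1 * rad
  a2 <- trace$alpha2 * rad
  a3 <- trace$alpha3 * rad
  Lf <- geometry$forearm_mm
  Lh <- geometry$hand_mm
  Lu <- geometry$upper_arm_mm
  we <- geometry$elbow_width_mm
  ww <- geometry$wrist_width_mm
  wh <- geometry$hand_width_mm
  # canonical right-arm construction: O at origin, forearm axis +z
  omega <- cbind(cos(a3), sin(a3), 0)           # inter-styloid direction
  y_m <- cbind(-sin(a3), cos(a3), 0)            # z cross omega
  h <- cbind(tan(a2) * omega[, 1] + tan(a1) * y_m[, 1],
             tan(a2) * omega[, 2] + tan(a1) * y_m[, 2],
             rep(-1, n))
  h <- h / sqrt(rowSums(h^2))
  H <- Lh * h
  # hand mediolateral axis: omega orthogonalized against the hand axis
  u <- omega - rowSums(omega * h) * h
  u <- u / sqrt(rowSums(u^2))
  E <- matrix(rep(c(0, 0, Lf), each = n), n)
  mk <- list(
    SHO = E + matrix(rep(Lu * c(0.2, -0.3, 0.933), each = n), n),
    MEP = E - matrix(rep(we / 2 * c(1, 0, 0), each = n), n),
    LEP = E + matrix(rep(we / 2 * c(1, 0, 0), each = n), n),
    STU = -ww / 2 * omega,
    STR = ww / 2 * omega,
    RMC = H + wh / 2 * u,
    UMC = H - wh / 2 * u)
  pose <- position_pose(position)
  mirror <- identical(geometry$side, "left")
  co <- matrix(NA_real_, n, 21)
  colnames(co) <- marker_cols()
  for (name in MARKER_NAMES) {
    p <- mk[[name]]
    if (mirror) p[, 1] <- -p[, 1]
    p <- p %*% t(pose$R)
    tt <- if (mirror) pose$t * c(-1, 1, 1) else pose$t
    p <- sweep(p, 2, tt, `+`)
    co[, paste(name, c("x", "y", "z"), sep = "_")] <- p
  }
  if (noise_sd_mm > 0) {
    withr::with_seed(seed, {
      co <- co + matrix(rnorm(length(co), 0, noise_sd_mm), nrow = n)
    })
  }
  marker_set(co, rate_hz(trace), side = geometry$side)
}

default_gain_matrix <- function(n_channels = 7, kappa = 2, g_max = 1) {
  theta <- 2 * pi * (0:5) / 6       # direction preferred angles
  phi <- 2 * pi * (seq_len(n_channels) - 1) / n_channels
  G <- outer(phi, theta, function(p, t) g_max * exp(kappa * (cos(p - t) - 1)))
  dimnames(G) <- list(paste0("ch", seq_len(n_channels)),
                      c("flex", "ext", "rad", "uln", "pro", "sup"))
  G
}

#' Synthetic-EMG configuration
#'
#' The EMG model is amplitude-modulated band-limited noise: per channel,
#' an envelope `noise_floor + sum_d gains[c, d] * excursion_d(t)` over the
#' six DoF directions (flexion, extension, radial, ulnar, pronation,
#' supination; excursions rectified and normalized by 90 deg), multiplied
#' by a unit-variance carrier band-limited to `carrier_band`. The
#' arm-position effect applies a per-position multiplicative channel gain
#' vector and an additive baseline shift to the envelope.
#'
#' @param n_channels number of EMG channels (7).
#' @param gains `n_channels x 6` non-negative gain matrix; the default is
#'   a smooth circular tuning of the channels around the forearm.
#' @param carrier `"noise"` (band-limited Gaussian, the realistic choice)
#'   or `"deterministic"` (a fixed multi-sine in the same band, for
#'   noise-free end-to-end checks).
#' @param carrier_band carrier band in Hz.
#' @param noise_floor envelope at rest.
#' @param rate_hz EMG sampling rate (2048).
#' @param position_gain `3 x n_channels` multiplicative position gains
#'   (rows POS1..POS3); all 1 = no position effect.
#' @param position_baseline `3 x n_channels` additive envelope shifts.
#' @param channel_mix in `[0, 1]`: blends each channel's direction tuning
#'   toward the across-channel mean, reducing channel specificity
#'   (emulates recording from a residual limb).
#' @return an `emg_synth_config` list.
#' @export
emg_synth_config <- function(n_channels = 7, gains = NULL,
                             carrier = c("noise", "deterministic"),
                             carrier_band = c(20, 350), noise_floor = 0.02,
                             rate_hz = 2048, position_gain = NULL,
                             position_baseline = NULL, channel_mix = 0) {
  carrier <- match.arg(carrier)
  if (is.null(gains)) gains <- default_gain_matrix(n_channels)
  gains <- as.matrix(gains)
  if (!all(dim(gains) == c(n_channels, 6)) || any(gains < 0)) {
    stop_contract("gains must be a non-negative n_channels x 6 matrix")
  }
  if (channel_mix < 0 || channel_mix > 1) {
    stop_contract("channel_mix must be in [0, 1]")
  }
  if (channel_mix > 0) {
    flat <- matrix(colMeans(gains), n_channels, 6, byrow = TRUE)
    gains <- (1 - channel_mix) * gains + channel_mix * flat
  }
  if (is.null(position_gain)) position_gain <- matrix(1, 3, n_channels)
  if (is.null(position_baseline)) {
    position_baseline <- matrix(0, 3, n_channels)
  }
  position_gain <- as.matrix(position_gain)
  position_baseline <- as.matrix(position_baseline)
  if (!all(dim(position_gain) == c(3, n_channels)) ||
      any(position_gain <= 0)) {
    stop_contract("position_gain must be a positive 3 x n_channels matrix")
  }
  if (!all(dim(position_baseline) == c(3, n_channels))) {
    stop_contract("position_baseline must be 3 x n_channels")
  }
  if (carrier_band[1] <= 0 || carrier_band[2] >= rate_hz / 2 ||
      carrier_band[1] >= carrier_band[2]) {
    stop_contract("carrier band must lie strictly inside (0, rate/2)")
  }
  structure(list(n_channels = n_channels, gains = gains, carrier = carrier,
                 carrier_band = carrier_band, noise_floor = noise_floor,
                 rate_hz = rate_hz, position_gain = position_gain,
                 position_baseline = position_baseline),
            class = "emg_synth_config")
}

#' Add a random arm-position effect to a synthetic-EMG configuration
#'
#' Draws independent log-normal channel gains (sd `sigma_g` on the log
#' scale) and small additive baseline shifts for each of the three arm
#' positions, emulating electrode-muscle geometry changes when the arm
#' posture changes. `sigma_g = 0` reproduces the no-effect null.
#'
#' @param config an [emg_synth_config()].
#' @param sigma_g standard deviation of the log channel gains.
#' @param seed RNG seed.
#' @return the modified configuration.
#' @export
with_position_effect <- function(config, sigma_g = 0.3, seed = 1) {
  stopifnot(inherits(config, "emg_synth_config"))
  if (sigma_g < 0) stop_contract("sigma_g must be non-negative")
  nc <- config$n_channels
  withr::with_seed(seed, {
    config$position_gain <- matrix(exp(rnorm(3 * nc, 0, sigma_g)), 3, nc)
    config$position_baseline <-
      matrix(abs(rnorm(3 * nc, 0, sigma_g)) * config$noise_floor, 3, nc)
  })
  config
}

square_wave <- function(n, rate_hz, freq = 20, amp = 5, t0 = 0) {
  t <- (seq_len(n) - 1) / rate_hz + t0
  ifelse(((t * freq) %% 1) < 0.5, amp, -amp)
}

dof_excursions <- function(trace) {
  cbind(flex = pmax(trace$alpha1, 0) / 90,
        ext = pmax(-trace$alpha1, 0) / 90,
        rad = pmax(trace$alpha2, 0) / 90,
        uln = pmax(-trace$alpha2, 0) / 90,
        pro = pmax(trace$alpha3 - 90, 0) / 90,
        sup = pmax(90 - trace$alpha3, 0) / 90)
}

make_carrier <- function(kind, n, rate_hz, band, channel, seed) {
  if (kind == "noise") {
    bf <- signal::butter(4, band / (rate_hz / 2), type = "pass")
    x <- withr::with_seed(seed, rnorm(n))
    x <- as.numeric(signal::filter(bf, x))
  } else {
    freqs <- c(53.1, 97.7, 151.3, 229.9)
    phases <- 2 * pi * channel / 7 + c(0.3, 1.1, 2.0, 2.9)
    t <- (seq_len(n) - 1) / rate_hz
    x <- rowSums(vapply(seq_along(freqs), function(k) {
      sin(2 * pi * freqs[k] * t + phases[k])
    }, numeric(n)))
  }
  x / sd(x)
}

#' Synthesize a multichannel EMG recording from a wrist angle trace
#'
#' Implements the envelope-times-carrier EMG model of
#' [emg_synth_config()], including the configured arm-position effect,
#' and attaches the 20 Hz synchronization square wave sampled on the EMG
#' time base.
#'
#' @param trace the scripted [angle_trace()] (kinematic rate).
#' @param config an [emg_synth_config()].
#' @param position `"POS1"`..`"POS3"`; selects the position-effect row.
#' @param side side label for the recording.
#' @param run run label.
#' @param seed RNG seed for the carrier noise.
#' @return an [emg_recording()] at `config$rate_hz` with a `sync`
#'   attribute.
#' @export
synthesize_emg <- function(trace, config = emg_synth_config(),
                           position = "POS1", side = "right", run = NA,
                           seed = 1) {
  stopifnot(is_angle_trace(trace), inherits(config, "emg_synth_config"))
  if (!position %in% POSITIONS) {
    stop_contract("position must be POS1, POS2 or POS3")
  }
  fs <- config$rate_hz
  n_in <- nrow(trace)
  fs_in <- rate_hz(trace)
  n <- as.integer(round(n_in / fs_in * fs))
  t_in <- (seq_len(n_in) - 1) / fs_in
  t_out <- (seq_len(n) - 1) / fs
  R <- dof_excursions(trace)
  Rup <- vapply(seq_len(ncol(R)), function(j) {
    approx(t_in, R[, j], xout = t_out, rule = 2)$y
  }, numeric(n))
  env <- Rup %*% t(config$gains) + config$noise_floor
  p <- match(position, POSITIONS)
  env <- sweep(env, 2, config$position_gain[p, ], `*`)
  env <- sweep(env, 2, config$position_baseline[p, ], `+`)
  sig <- vapply(seq_len(config$n_channels), function(c) {
    carrier <- make_carrier(config$carrier, n, fs, config$carrier_band, c,
                            derive_seed(seed, c))
    env[, c] * carrier
  }, numeric(n))
  colnames(sig) <- paste0("ch", seq_len(config$n_channels))
  emg_recording(sig, fs, side = side, run = run, position = position,
                sync = square_wave(n, fs))
}

simulate_run <- function(run, position, duration_s, config, geometry,
                         marker_noise_sd, sync_offset_s, seed) {
  trace <- script_angles(run, duration_s, seed = derive_seed(seed, 11))
  emg <- synthesize_emg(trace, config, position,
                        side = setdiff(c("left", "right"), geometry$side),
                        run = run, seed = derive_seed(seed, 13))
  markers <- forward_markers(trace, geometry, position, marker_noise_sd,
                             seed = derive_seed(seed, 17))
  fs_kin <- rate_hz(trace)
  n_pre <- as.integer(round(sync_offset_s * fs_kin))
  if (n_pre > 0) {
    pad <- markers[rep(1L, n_pre), , drop = FALSE]
    co <- rbind(as.data.frame(pad), as.data.frame(markers))
    markers <- marker_set(co, fs_kin, side = geometry$side)
  }
  attr(markers, "sync") <- sync_trace(
    square_wave(nrow(markers), fs_kin, t0 = -sync_offset_s), fs_kin)
  attr(markers, "run") <- run
  attr(markers, "position") <- position
  list(emg = emg, markers = markers, angles = trace)
}

#' Simulate a full recording session in memory
#'
#' Generates, for every requested (position, run) combination, the shared
#' mirrored angle trace, the control-side EMG (the side whose features
#' drive the regression) and the contralateral side's marker trajectories
#' (the side whose measured angles are the regression targets). The
#' motion-capture stream starts `sync_offset_s` before the EMG stream, so
#' the synchronization step is exercised for real.
#'
#' @param master_seed seed from which all per-run seeds are derived.
#' @param duration_s run duration in seconds (study protocol: ~65 s).
#' @param positions arm positions to simulate.
#' @param runs runs to simulate (1..7).
#' @param config an [emg_synth_config()].
#' @param control_side the side providing EMG (`"right"` by default);
#'   markers are generated for the opposite side.
#' @param marker_noise_sd motion-capture noise, mm (0.5 is the stated
#'   calibration error of the capture system).
#' @param sync_offset_s head start of the kinematic stream, seconds.
#' @param subject_id,group manifest labels; `group = "amputee"` flattens
#'   the control side's channel tuning (reduced channel specificity, see
#'   [emg_synth_config()]'s `channel_mix`).
#' @return an `emg_session`: list with a `runs` tibble (list-columns
#'   `emg`, `markers`, `angles`) and the generation parameters.
#' @export
simulate_session <- function(master_seed = 1, duration_s = 65,
                             positions = POSITIONS, runs = 1:7,
                             config = emg_synth_config(),
                             control_side = "right",
                             marker_noise_sd = 0.5, sync_offset_s = 0.015625,
                             subject_id = "SYN01",
                             group = "able_bodied") {
  group <- match.arg(group, c("able_bodied", "amputee"))
  if (group == "amputee") {
    config <- emg_synth_config(
      n_channels = config$n_channels, gains = config$gains,
      carrier = config$carrier, carrier_band = config$carrier_band,
      noise_floor = config$noise_floor, rate_hz = config$rate_hz,
      position_gain = config$position_gain,
      position_baseline = config$position_baseline, channel_mix = 0.5)
  }
  target_side <- setdiff(c("left", "right"), control_side)
  geometry <- arm_geometry(side = target_side)
  grid <- expand.grid(run = runs, position = positions,
                      stringsAsFactors = FALSE)
  sims <- purrr::pmap(grid, function(run, position) {
    simulate_run(run, position, duration_s, config, geometry,
                 marker_noise_sd, sync_offset_s,
                 derive_seed(master_seed,
                             match(position, POSITIONS) * 100 + run))
  })
  structure(list(
    runs = tibble(position = grid$position, run = grid$run,
                  emg = purrr::map(sims, "emg"),
                  markers = purrr::map(sims, "markers"),
                  angles = purrr::map(sims, "angles")),
    params = list(master_seed = master_seed, duration_s = duration_s,
                  config = config, control_side = control_side,
                  marker_noise_sd = marker_noise_sd,
                  sync_offset_s = sync_offset_s, subject_id = subject_id,
                  group = group)),
    class = "emg_session")
}

#' @export
print.emg_session <- function(x, ...) {
  cat(sprintf(
    "<emg_session> %d (position, run) pairs, %.0f s each, seed %s\n",
    nrow(x$runs), x$params$duration_s, x$params$master_seed))
  invisible(x)
}

#' Generate a synthetic session on disk
#'
#' Writes the complete dataset of one session - for every (position, run)
#' combination the EMG and marker TSV files of both sides (each with its
#' own synchronization channel) - plus the session manifest. All per-run
#' seeds derive from `master_seed`, so two calls with the same seed write
#' identical numeric content.
#'
#' @param dir output directory (created if needed).
#' @inheritParams simulate_session
#' @return the [session_manifest()], invisibly; the manifest file is
#'   `manifest.tsv` in `dir`.
#' @export
generate_session <- function(dir, master_seed = 1, duration_s = 65,
                             positions = POSITIONS, runs = 1:7,
                             config = emg_synth_config(),
                             control_side = "right",
                             marker_noise_sd = 0.5, sync_offset_s = 0.015625,
                             subject_id = "SYN01",
                             group = "able_bodied") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rt <- run_table()
  rows <- list()
  for (position in positions) {
    for (run in runs) {
      seed0 <- derive_seed(master_seed, match(position, POSITIONS) * 100 + run)
      trace <- script_angles(run, duration_s, seed = derive_seed(seed0, 11))
      for (side in c("left", "right")) {
        cfg <- config
        if (group == "amputee" && side == control_side) {
          cfg <- emg_synth_config(
            n_channels = config$n_channels, gains = config$gains,
            carrier = config$carrier, carrier_band = config$carrier_band,
            noise_floor = config$noise_floor, rate_hz = config$rate_hz,
            position_gain = config$position_gain,
            position_baseline = config$position_baseline,
            channel_mix = 0.5)
        }
        sseed <- derive_seed(seed0, if (side == "left") 13 else 14)
        emg <- synthesize_emg(trace, cfg, position, side = side, run = run,
                              seed = sseed)
        geometry <- arm_geometry(side = side)
        markers <- forward_markers(trace, geometry, position,
                                   marker_noise_sd,
                                   seed = derive_seed(seed0,
                                                      if (side == "left")
                                                        17 else 18))
        fs_kin <- rate_hz(trace)
        n_pre <- as.integer(round(sync_offset_s * fs_kin))
        if (n_pre > 0) {
          co <- rbind(as.data.frame(markers[rep(1L, n_pre), ,
                                            drop = FALSE]),
                      as.data.frame(markers))
          markers <- marker_set(co, fs_kin, side = side)
        }
        attr(markers, "sync") <- sync_trace(
          square_wave(nrow(markers), fs_kin, t0 = -sync_offset_s), fs_kin)
        attr(markers, "run") <- run
        attr(markers, "position") <- position
        emg_file <- sprintf("emg_%s_run%d_%s.tsv", position, run, side)
        mk_file <- sprintf("markers_%s_run%d_%s.tsv", position, run, side)
        write_emg_tsv(emg, file.path(dir, emg_file))
        write_markers_tsv(markers, file.path(dir, mk_file))
        rows[[length(rows) + 1L]] <- tibble(
          run = run, position = position, side = side,
          duration_s = duration_s,
          active_dofs = rt$active_dofs_label[run],
          emg_file = emg_file, marker_file = mk_file)
      }
    }
  }
  manifest <- session_manifest(subject_id, group, dplyr::bind_rows(rows))
  write_manifest(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}

#' Load a session from disk into memory
#'
#' Reads the stream pairs named by a manifest back into an `emg_session`
#' usable by [process_session()]: the control side's EMG and the opposite
#' side's markers.
#'
#' @param manifest a [session_manifest()] (or path to one).
#' @param dir directory holding the files.
#' @param control_side the side whose EMG drives the regression.
#' @return an `emg_session`.
#' @export
load_session <- function(manifest, dir, control_side = "right") {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "session_manifest"))
  target_side <- setdiff(c("left", "right"), control_side)
  r <- manifest$runs
  ctrl <- r[r$side == control_side, ]
  tgt <- r[r$side == target_side, c("run", "position", "marker_file")]
  runs <- dplyr::inner_join(
    ctrl[c("run", "position", "emg_file", "duration_s")], tgt,
    by = c("run", "position"))
  runs <- dplyr::arrange(runs, .data$position, .data$run)
  structure(list(
    runs = tibble(
      position = runs$position, run = runs$run,
      emg = purrr::map(runs$emg_file,
                       ~read_emg_tsv(file.path(dir, .x))),
      markers = purrr::map(runs$marker_file,
                           ~read_markers_tsv(file.path(dir, .x))),
      angles = vector("list", nrow(runs))),
    params = list(control_side = control_side,
                  subject_id = manifest$subject_id,
                  group = manifest$group)),
    class = "emg_session")
}
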