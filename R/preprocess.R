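# EMG conditioning and stream alignment.
#
# Raw EMG (2048 Hz) is band-pass filtered 10-450 Hz with a second-order
# Butterworth filter and decimated to the common 1024 Hz analysis rate.
# The motion-capture stream is aligned to the EMG stream through the shared
# 20 Hz synchronization square wave; offsets are integer sample counts on
# each stream's own time base, so no float time axis is carried around.

#' Band-pass filter an EMG recording
#'
#' Second-order Butterworth band-pass (default 10-450 Hz), applied per
#' channel. The default is a causal forward pass, matching what an online
#' myoelectric controller could compute; set `zero_phase = TRUE` for
#' offline forward-backward filtering.
#'
#' @param emg an [emg_recording()].
#' @param low_hz,high_hz band edges in Hz.
#' @param order filter order (of the underlying low/high-pass prototype).
#' @param zero_phase if `TRUE` use zero-phase forward-backward filtering.
#' @return the filtered [emg_recording()] (same shape, rate and labels).
#' @export
bandpass_emg <- function(emg, low_hz = 10, high_hz = 450, order = 2,
                         zero_phase = FALSE) {
  stopifnot(is_emg_recording(emg))
  fs <- rate_hz(emg)
  if (fs <= 2 * high_hz) {
    stop_contract(sprintf(
      "sampling rate %g Hz is too low for a %g Hz band edge", fs, high_hz))
  }
  if (low_hz <= 0 || low_hz >= high_hz) {
    stop_contract("band edges must satisfy 0 < low_hz < high_hz")
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  app <- if (zero_phase) {
    function(x) signal::filtfilt(bf, x)
  } else {
    function(x) as.numeric(signal::filter(bf, x))
  }
  out <- emg
  for (j in seq_along(out)) out[[j]] <- app(emg[[j]])
  out
}

#' Resample an EMG recording to the analysis rate
#'
#' Integer-factor decimation with an anti-aliasing low-pass applied before
#' downsampling (via [signal::decimate()]). Only integer rate ratios are
#' supported; the target rate must not exceed the input rate.
#'
#' @param emg an [emg_recording()].
#' @param target_hz target sampling rate (default 1024 Hz).
#' @return the resampled [emg_recording()]. Any raw-stream `sync` attribute
#'   is dropped: synchronization happens before resampling.
#' @export
resample_emg <- function(emg, target_hz = 1024) {
  stopifnot(is_emg_recording(emg))
  fs <- rate_hz(emg)
  if (target_hz > fs) {
    stop_contract("target rate exceeds the recording rate")
  }
  if (fs == target_hz) return(emg)
  q <- fs / target_hz
  if (abs(q - round(q)) > 1e-9) {
    stop_contract(sprintf(
      "unsupported rate ratio %g/%g: only integer decimation factors",
      fs, target_hz))
  }
  q <- as.integer(round(q))
  # zero-phase 8th-order Butterworth anti-alias low-pass at 0.8x the new
  # Nyquist, then subsampling; filtering the deviation from the first
  # sample keeps DC exact despite the filter's startup transient
  bf <- signal::butter(8, 0.8 / q, type = "low")
  cols <- lapply(as.data.frame(emg), function(x) {
    y <- signal::filtfilt(bf, x - x[1]) + x[1]
    y[seq(1, length(x), by = q)]
  })
  emg_recording(as.data.frame(cols), target_hz,
                side = attr(emg, "side"), run = attr(emg, "run"),
                position = attr(emg, "position"))
}

# Rising-edge indices of a square-ish wave by hysteresis thresholding at
# one third / two thirds of the signal range (robust to amplitude scaling).
rising_edges <- function(x) {
  r <- range(x, finite = TRUE)
  if (!all(is.finite(r)) || diff(r) <= 0) return(integer(0))
  lo <- r[1] + diff(r) / 3
  hi <- r[1] + 2 * diff(r) / 3
  state <- ifelse(x >= hi, 1L, ifelse(x <= lo, 0L, NA_integer_))
  # carry the last decided state through the hysteresis band
  known <- !is.na(state)
  if (!any(known)) return(integer(0))
  filled <- state[known][cumsum(known)]
  lead_na <- which(known)[1] - 1L
  if (lead_na > 0) filled <- c(rep(filled[1], lead_na), filled)
  which(diff(filled) == 1L) + 1L
}

#' Align two streams through their synchronization traces
#'
#' Detects rising edges of the shared square wave in both traces and
#' returns the integer number of leading samples to drop from each stream
#' so that corresponding edges coincide. Because the synchronization wave
#' is periodic, the relative offset is only identifiable modulo its
#' period: the recordings must have started within half a period
#' (nominally 25 ms) of each other, which is the operating condition of a
#' shared free-running sync generator with jointly triggered recordings.
#' The offsets are normalized so at least one is zero; the residual
#' edge-time mismatch after trimming is below half a sample period of the
#' coarser stream.
#'
#' @param sync_a,sync_b [sync_trace()] objects (any rates).
#' @param min_edges minimum number of rising edges each trace must contain
#'   (the nominal 20 Hz wave gives one per 50 ms).
#' @return a list with `offset_a`, `offset_b` (samples to drop) and
#'   `residual_s` (remaining edge-time mismatch in seconds).
#' @export
align_by_sync <- function(sync_a, sync_b, min_edges = 5) {
  ea <- rising_edges(as.numeric(sync_a))
  eb <- rising_edges(as.numeric(sync_b))
  if (length(ea) < min_edges || length(eb) < min_edges) {
    abort(sprintf(
      "synchronization failed: %d/%d rising edges detected (need >= %d)",
      length(ea), length(eb), min_edges),
      class = "wristemg_sync_error")
  }
  ra <- rate_hz(sync_a)
  rb <- rate_hz(sync_b)
  P <- 1 / (attr(sync_a, "nominal_hz") %||% 20)
  ta <- (ea[1] - 1) / ra
  tb <- (eb[1] - 1) / rb
  # reduce the edge-time difference into (-P/2, P/2]
  d <- ta - tb
  d <- ((d + P / 2) %% P) - P / 2
  if (d >= 0) {
    off_a <- as.integer(round(d * ra))
    off_b <- 0L
  } else {
    off_a <- 0L
    off_b <- as.integer(round(-d * rb))
  }
  residual <- (ta - off_a / ra) - (tb - off_b / rb)
  residual <- abs(((residual + P / 2) %% P) - P / 2)
  list(offset_a = off_a, offset_b = off_b, residual_s = residual)
}

# Drop n leading rows/samples from a stream object, preserving attributes.
drop_head <- function(x, n) {
  if (n <= 0) return(x)
  if (is.data.frame(x)) {
    at <- attributes(x)
    out <- x[-seq_len(n), , drop = FALSE]
    for (a in setdiff(names(at), c("row.names", "names", "dim"))) {
      attr(out, a) <- at[[a]]
    }
    inv <- attr(x, "invalid")
    if (!is.null(inv)) attr(out, "invalid") <- inv[-seq_len(n)]
    sy <- attr(x, "sync")
    if (!is.null(sy)) attr(out, "sync") <- sync_trace(
      as.numeric(sy)[-seq_len(n)], rate_hz(sy), attr(sy, "nominal_hz"))
    out
  } else {
    structure(unclass(x)[-seq_len(n)], rate_hz = rate_hz(x),
              nominal_hz = attr(x, "nominal_hz"), class = class(x))
  }
}

#' Align an EMG recording and a marker set on a common start
#'
#' Applies [align_by_sync()] to the two streams' synchronization traces
#' (the EMG recording's `sync` attribute and `kin_sync`) and trims the
#' leading samples of both streams accordingly.
#'
#' @param emg an [emg_recording()] carrying a `sync` attribute.
#' @param markers a [marker_set()].
#' @param kin_sync the motion-capture-side [sync_trace()]; defaults to the
#'   marker set's own `sync` attribute.
#' @return list with trimmed `emg`, `markers` and the `offsets` used.
#' @export
align_streams <- function(emg, markers, kin_sync = attr(markers, "sync")) {
  emg_sync <- attr(emg, "sync")
  if (is.null(emg_sync) || is.null(kin_sync)) {
    stop_contract("both streams must carry a synchronization trace")
  }
  off <- align_by_sync(emg_sync, kin_sync)
  list(emg = drop_head(emg, off$offset_a),
       markers = drop_head(markers, off$offset_b),
       offsets = off)
}
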