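#' Multichannel surface EMG recording
#'
#' A tibble-backed container for a multichannel EMG stream. Columns are
#' channels (`ch1`, `ch2`, ...), rows are samples; the sampling rate and
#' session labels travel as attributes so the object still behaves as an
#' ordinary tibble in dplyr pipelines.
#'
#' @param samples a numeric matrix or data frame, one column per channel,
#'   one row per sample.
#' @param rate_hz sampling rate in Hz.
#' @param side recording side, `"left"` or `"right"` (optional).
#' @param run run index within the session (optional).
#' @param position arm-position label, `"POS1"`..`"POS3"` (optional).
#' @param sync optional synchronization channel sampled alongside the EMG
#'   (same length as `samples`), stored as a [sync_trace()].
#' @return an `emg_recording`: a tibble of channel samples with `rate_hz`,
#'   `side`, `run`, `position` and `sync` attributes.
#' @export
emg_recording <- function(samples, rate_hz, side = NA_character_,
                          run = NA_integer_, position = NA_character_,
                          sync = NULL) {
  samples <- as.data.frame(samples)
  if (!all(vapply(samples, is.numeric, logical(1)))) {
    stop_data("EMG samples must be numeric")
  }
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    stop_contract("`rate_hz` must be a single positive number")
  }
  if (is.null(names(samples)) || any(names(samples) == "")) {
    names(samples) <- paste0("ch", seq_along(samples))
  }
  x <- as_tibble(samples)
  if (!is.null(sync)) {
    if (length(sync) != nrow(x)) {
      stop_contract("sync channel length must match the number of samples")
    }
    sync <- sync_trace(as.numeric(sync), rate_hz)
  }
  structure(x,
            rate_hz = as.numeric(rate_hz), side = side,
            run = run, position = position, sync = sync,
            class = c("emg_recording", class(x)))
}

#' @rdname emg_recording
#' @param x an object.
#' @export
is_emg_recording <- function(x) inherits(x, "emg_recording")

#' Sampling rate of a stream object
#'
#' @param x an [emg_recording()], [marker_set()], [angle_trace()] or
#'   [sync_trace()].
#' @return the sampling rate in Hz.
#' @export
rate_hz <- function(x) attr(x, "rate_hz")

#' Duration of a stream object in seconds
#'
#' @inheritParams rate_hz
#' @return duration in seconds (`n_samples / rate_hz`).
#' @export
duration_s <- function(x) {
  n <- if (is.data.frame(x)) nrow(x) else length(x)
  n / rate_hz(x)
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channels, %d samples @ %g Hz (%.2f s)\n",
              ncol(x), nrow(x), rate_hz(x), duration_s(x)))
  cat(sprintf("  side=%s run=%s position=%s sync=%s\n",
              attr(x, "side"), attr(x, "run"), attr(x, "position"),
              if (is.null(attr(x, "sync"))) "no" else "yes"))
  NextMethod()
}

#' Synchronization square-wave trace
#'
#' The shared synchronization signal (nominally a 20 Hz square wave)
#' recorded on both the EMG and the motion-capture stream, used to align
#' the two time bases.
#'
#' @param samples numeric vector of samples.
#' @param rate_hz sampling rate in Hz.
#' @param nominal_hz nominal square-wave frequency (default 20 Hz).
#' @return a `sync_trace` (numeric vector with rate attributes).
#' @export
sync_trace <- function(samples, rate_hz, nominal_hz = 20) {
  if (!is.numeric(samples)) stop_data("sync samples must be numeric")
  structure(as.numeric(samples), rate_hz = as.numeric(rate_hz),
            nominal_hz = nominal_hz, class = "sync_trace")
}

#' @export
print.sync_trace <- function(x, ...) {
  cat(sprintf("<sync_trace> %d samples @ %g Hz, nominal %g Hz\n",
              length(x), rate_hz(x), attr(x, "nominal_hz")))
  invisible(x)
}

#' Named 3-D marker trajectories
#'
#' Trajectories of the seven per-arm anatomical markers (SHO, MEP, LEP,
#' STU, STR, RMC, UMC), one row per motion-capture frame, three columns
#' (`_x`, `_y`, `_z`, in mm) per marker. Missing samples (marker gaps) are
#' encoded as `NA`.
#'
#' @param coords data frame or matrix with 21 columns named
#'   `SHO_x, SHO_y, SHO_z, ..., UMC_z`.
#' @param rate_hz frame rate in Hz.
#' @param side recording side, `"left"` or `"right"`.
#' @return a `marker_set` tibble with `rate_hz` and `side` attributes.
#' @export
marker_set <- function(coords, rate_hz, side = NA_character_) {
  coords <- as.data.frame(coords)
  want <- marker_cols()
  missing <- setdiff(want, names(coords))
  extra <- setdiff(names(coords), want)
  if (length(missing) || length(extra)) {
    stop_format(c(
      "marker columns must be exactly the 7-marker set",
      if (length(missing)) paste("missing:", paste(missing, collapse = ", ")),
      if (length(extra)) paste("extra:", paste(extra, collapse = ", "))))
  }
  x <- as_tibble(coords[want])
  structure(x, rate_hz = as.numeric(rate_hz), side = side,
            class = c("marker_set", class(x)))
}

#' @rdname marker_set
#' @param x an object.
#' @export
is_marker_set <- function(x) inherits(x, "marker_set")

#' Per-frame, per-marker gap mask of a marker set
#'
#' @param markers a [marker_set()].
#' @return a logical frames-by-7 matrix, `TRUE` where the marker is gapped
#'   (any of its three coordinates missing) at that frame.
#' @export
gap_mask <- function(markers) {
  stopifnot(is_marker_set(markers))
  m <- sapply(MARKER_NAMES, function(mk) {
    cols <- paste(mk, c("x", "y", "z"), sep = "_")
    rowSums(is.na(as.matrix(markers[cols]))) > 0
  })
  matrix(m, ncol = length(MARKER_NAMES),
         dimnames = list(NULL, MARKER_NAMES))
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> 7 markers, %d frames @ %g Hz (%.2f s), side=%s\n",
              nrow(x), rate_hz(x), duration_s(x), attr(x, "side")))
  NextMethod()
}

#' Wrist joint-angle time series
#'
#' Time series of the three wrist degrees of freedom, in degrees:
#' `alpha1` flexion(+)/extension(-), range ±90°; `alpha2` radial(+)/
#' ulnar(-) deviation, range ±90°; `alpha3` forearm rotation, range
#' 0–180° with 90° the prono-supination neutral (>90° pronation).
#'
#' @param alpha data frame or matrix with columns `alpha1`, `alpha2`,
#'   `alpha3` (degrees).
#' @param rate_hz sampling rate in Hz.
#' @param side side label.
#' @param invalid optional logical vector flagging frames whose source
#'   markers were gapped beyond repair.
#' @return an `angle_trace` tibble with stream attributes.
#' @export
angle_trace <- function(alpha, rate_hz, side = NA_character_,
                        invalid = NULL) {
  alpha <- as.data.frame(alpha)
  if (!all(c("alpha1", "alpha2", "alpha3") %in% names(alpha))) {
    names(alpha) <- c("alpha1", "alpha2", "alpha3")[seq_along(alpha)]
  }
  x <- as_tibble(alpha[c("alpha1", "alpha2", "alpha3")])
  if (is.null(invalid)) invalid <- rep(FALSE, nrow(x))
  structure(x, rate_hz = as.numeric(rate_hz), side = side,
            invalid = invalid,
            class = c("angle_trace", class(x)))
}

#' @rdname angle_trace
#' @param x an object.
#' @export
is_angle_trace <- function(x) inherits(x, "angle_trace")

#' @export
print.angle_trace <- function(x, ...) {
  cat(sprintf("<angle_trace> %d samples @ %g Hz (%.2f s), side=%s\n",
              nrow(x), rate_hz(x), duration_s(x), attr(x, "side")))
  NextMethod()
}
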