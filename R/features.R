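# TDAR feature extraction on sliding analysis windows.
#
# Per channel and window: mean absolute value (MAV), MAV slope (difference
# of MAV between consecutive windows), zero crossings (ZC) and slope sign
# changes (SSC) with an amplitude dead zone, and a 6th-order autoregressive
# coefficient set estimated by an LMS adaptive linear predictor.

#' Sliding analysis-window specification
#'
#' The analysis windows are 100 ms long with 60 ms overlap (40 ms step).
#' At the 1024 Hz analysis rate these durations are not integral sample
#' counts; the window length is truncated (102 samples) and the step
#' rounded (41 samples), fixed here once for reproducibility.
#'
#' @param length_ms window duration in ms.
#' @param overlap_ms overlap between consecutive windows in ms (must be
#'   shorter than the window).
#' @param rate_hz sampling rate the windows will be applied at.
#' @return a `window_spec` with `length_smp` and `step_smp` fields.
#' @export
window_spec <- function(length_ms = 100, overlap_ms = 60, rate_hz = 1024) {
  if (overlap_ms < 0 || overlap_ms >= length_ms) {
    stop_contract("need 0 <= overlap_ms < length_ms")
  }
  len <- max(1L, as.integer(floor(length_ms * rate_hz / 1000)))
  step <- max(1L, as.integer(round((length_ms - overlap_ms) *
                                     rate_hz / 1000)))
  structure(list(length_ms = length_ms, overlap_ms = overlap_ms,
                 rate_hz = rate_hz, length_smp = len, step_smp = step),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf(
    "<window_spec> %g ms / %g ms overlap @ %g Hz -> %d samples, step %d\n",
    x$length_ms, x$overlap_ms, x$rate_hz, x$length_smp, x$step_smp))
  invisible(x)
}

#' Number of analysis windows fitting in a stream
#'
#' `floor((n_samples - length_smp) / step_smp) + 1`, or 0 when the stream
#' is shorter than one window.
#'
#' @param n_samples stream length in samples.
#' @param spec a [window_spec()].
#' @return integer window count.
#' @export
n_windows <- function(n_samples, spec) {
  if (n_samples < spec$length_smp) return(0L)
  as.integer((n_samples - spec$length_smp) %/% spec$step_smp + 1L)
}

window_starts <- function(n_samples, spec) {
  w <- n_windows(n_samples, spec)
  if (w == 0L) integer(0) else (seq_len(w) - 1L) * spec$step_smp + 1L
}

#' Mean absolute value of a window
#'
#' @param window numeric sample vector.
#' @return the mean of the absolute sample values (non-negative).
#' @export
mav <- function(window) {
  if (!length(window)) stop_contract("empty analysis window")
  mean(abs(window))
}

#' Mean-absolute-value slope over consecutive windows
#'
#' Forward difference of the per-window MAV sequence: element `w` is
#' `MAV(w + 1) - MAV(w)`; the final window carries 0.
#'
#' @param mav_sequence numeric vector of per-window MAV values.
#' @return numeric vector of the same length.
#' @export
mavs <- function(mav_sequence) {
  n <- length(mav_sequence)
  if (!n) stop_contract("empty MAV sequence")
  if (n == 1L) {
    inform("single analysis window: MAV slope degenerates to 0")
    return(0)
  }
  c(diff(mav_sequence), 0)
}

#' Zero-crossing count of a window
#'
#' Counts consecutive-sample pairs of strictly opposite sign whose
#' amplitude step exceeds the dead-zone threshold `eps_amp`.
#'
#' @param window numeric sample vector.
#' @param eps_amp non-negative amplitude dead zone.
#' @return integer count in `[0, length(window) - 1]`.
#' @export
zero_crossings <- function(window, eps_amp = 0) {
  if (eps_amp < 0) stop_contract("eps_amp must be non-negative")
  if (length(window) < 2L) return(0L)
  a <- window[-length(window)]
  b <- window[-1]
  sum(a * b < 0 & abs(a - b) > eps_amp)
}

#' Slope-sign-change count of a window
#'
#' Counts interior samples that are a local extremum (both neighbour
#' differences of the same sign relative to the sample) with both
#' differences exceeding the dead zone `eps_amp`.
#'
#' @inheritParams zero_crossings
#' @return integer count in `[0, length(window) - 2]`.
#' @export
slope_sign_changes <- function(window, eps_amp = 0) {
  if (eps_amp < 0) stop_contract("eps_amp must be non-negative")
  if (length(window) < 3L) stop_contract("window must have >= 3 samples")
  n <- length(window)
  d1 <- window[2:(n - 1)] - window[1:(n - 2)]
  d2 <- window[2:(n - 1)] - window[3:n]
  sum(d1 * d2 > 0 & abs(d1) > eps_amp & abs(d2) > eps_amp)
}

#' LMS configuration for the autoregressive features
#'
#' The AR coefficients are estimated by a least-mean-squares adaptive
#' linear predictor run over the (unit-variance normalized) window:
#' zero-initialized weights, fixed step size, a small number of sweeps,
#' and tail averaging of the weight trajectory over the final sweep to
#' suppress steady-state gradient noise.
#'
#' @param order predictor order (6 coefficients per channel).
#' @param step_size LMS adaptation step on the normalized window.
#' @param n_passes number of sweeps through the window.
#' @param average average the weights over the final sweep (recommended).
#' @return an `lms_config` list.
#' @export
lms_config <- function(order = 6, step_size = 0.01, n_passes = 3,
                       average = TRUE) {
  if (step_size <= 0) stop_contract("step_size must be positive")
  if (order < 1 || n_passes < 1) {
    stop_contract("order and n_passes must be >= 1")
  }
  structure(list(order = as.integer(order), step_size = step_size,
                 n_passes = as.integer(n_passes), average = isTRUE(average)),
            class = "lms_config")
}

#' Autoregressive coefficients by LMS adaptive prediction
#'
#' Coefficients of the order-`order` linear predictor
#' `xhat[n] = sum_k a_k x[n - k]` adapted by LMS over the window. The
#' window is normalized to unit variance internally, so the coefficients
#' are invariant to amplitude scaling; an all-zero (constant) window yields
#' zero coefficients.
#'
#' @param window numeric sample vector, much longer than `order`.
#' @param order predictor order.
#' @param step_size LMS step size (see [lms_config()]).
#' @param n_passes sweeps through the window.
#' @param average tail-average the final sweep.
#' @return numeric vector `a_1 .. a_order`.
#' @export
ar_coefficients_lms <- function(window, order = 6, step_size = 0.01,
                                n_passes = 3, average = TRUE) {
  if (length(window) <= order) {
    stop_contract("window must be longer than the AR order")
  }
  out <- lms_ar_cpp(as.numeric(window), as.integer(order), step_size,
                    as.integer(n_passes), isTRUE(average))
  if (isTRUE(attr(out, "diverged"))) {
    stop_data(paste("LMS adaptation diverged;",
                    "try a smaller step_size"))
  }
  attr(out, "diverged") <- NULL
  out
}

feature_names <- function(order = 6) {
  c("mav", "mavs", "zc", "ssc", paste0("ar", seq_len(order)))
}

#' Columns of a feature matrix holding features
#'
#' @param data a data frame produced by [extract_features()] (possibly
#'   with extra label columns).
#' @return character vector of feature column names (`ch<k>_<feature>`).
#' @export
feature_cols <- function(data) {
  grep("^ch[0-9]+_", names(data), value = TRUE)
}

#' Extract the TDAR feature set on sliding windows
#'
#' Window `w` covers samples `[(w-1) * step + 1, (w-1) * step + len]`; the
#' row count is `floor((n - len) / step) + 1`. Per channel the features
#' are MAV, MAVS, ZC, SSC and `order` AR coefficients, i.e. 10 features
#' per channel at the default order, 70 columns for 7 channels.
#'
#' @param emg an [emg_recording()] at the analysis rate.
#' @param spec a [window_spec()]; defaults to 100 ms / 60 ms overlap at
#'   the recording's rate.
#' @param eps_amp dead-zone threshold for ZC/SSC. Default `NULL` uses
#'   0.01 x the per-channel RMS of the recording, a small noise-relative
#'   dead zone.
#' @param lms an [lms_config()].
#' @return a `feature_matrix` tibble: `window`, `start` (first sample of
#'   the window) and one column per channel/feature.
#' @export
extract_features <- function(emg, spec = NULL, eps_amp = NULL,
                             lms = lms_config()) {
  stopifnot(is_emg_recording(emg))
  if (is.null(spec)) spec <- window_spec(rate_hz = rate_hz(emg))
  if (abs(spec$rate_hz - rate_hz(emg)) > 1e-9) {
    stop_contract("window spec and recording rates differ")
  }
  n <- nrow(emg)
  if (n < spec$length_smp) {
    stop_contract("recording shorter than one analysis window")
  }
  starts <- window_starts(n, spec)
  W <- length(starts)
  len <- spec$length_smp
  idx <- outer(seq_len(len) - 1L, starts, `+`)
  chans <- as.data.frame(emg)
  if (anyNA(chans)) stop_data("EMG contains NAs; condition it first")
  out <- vector("list", length(chans))
  for (j in seq_along(chans)) {
    x <- chans[[j]]
    eps <- if (is.null(eps_amp)) 0.01 * sqrt(mean(x^2)) else eps_amp
    M <- matrix(x[idx], nrow = len)
    mav_w <- colMeans(abs(M))
    mavs_w <- if (W == 1L) 0 else c(diff(mav_w), 0)
    A <- M[-len, , drop = FALSE]
    B <- M[-1, , drop = FALSE]
    zc_w <- colSums(A * B < 0 & abs(A - B) > eps)
    Mid <- M[2:(len - 1), , drop = FALSE]
    D1 <- Mid - M[1:(len - 2), , drop = FALSE]
    D2 <- Mid - M[3:len, , drop = FALSE]
    ssc_w <- colSums(D1 * D2 > 0 & abs(D1) > eps & abs(D2) > eps)
    ar <- lms_ar_matrix_cpp(M, lms$order, lms$step_size, lms$n_passes,
                            lms$average)
    if (isTRUE(attr(ar, "diverged"))) {
      stop_data("LMS adaptation diverged; try a smaller step_size")
    }
    f <- cbind(mav_w, mavs_w, zc_w, ssc_w, t(ar))
    colnames(f) <- paste0("ch", j, "_", feature_names(lms$order))
    out[[j]] <- f
  }
  res <- as_tibble(as.data.frame(do.call(cbind, out)))
  res <- dplyr::bind_cols(tibble(window = seq_len(W), start = starts), res)
  structure(res, window_spec = spec,
            class = c("feature_matrix", class(res)))
}
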