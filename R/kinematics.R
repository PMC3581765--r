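# Marker-based wrist joint angles.
#
# The wrist-centered frame is built per frame from the anatomical markers:
# origin O midway between the styloid markers (STR, STU); z-axis toward E,
# midway between the humeral epicondyle markers (MEP, LEP), i.e. along the
# forearm axis, positive proximal; x-axis the mediolateral axis, obtained
# by orthogonalizing the inter-styloid vector (STR - STU, radial direction,
# lateral on both sides) against z; y-axis completes the right-handed
# frame (dorsopalmar axis). Because a right-handed frame cannot mirror, the
# palmar direction is +y on the right arm and -y on the left; the
# flexion sign convention is applied in the angle computation so mirrored
# bilateral movements produce identical angle traces on both sides.
#
# With H the midpoint of the metacarpal markers (RMC, UMC) and
# (Hx, Hy, Hz) its components on (x, palmar axis, distal axis -z):
#   alpha1 = atan(Hy / Hz)   flexion(+) / extension(-)
#   alpha2 = atan(Hx / Hz)   radial(+) / ulnar(-) deviation
#   alpha3 = angle(STR - STU, LEP - MEP)   0..180 deg, 90 deg neutral.

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-9) stop_contract("degenerate marker geometry (zero-length axis)")
  v / n
}

palmar_sign <- function(side) {
  if (is.na(side)) stop_contract("side must be 'left' or 'right'")
  switch(side, right = 1, left = -1,
         stop_contract("side must be 'left' or 'right'"))
}

#' Build the wrist-centered coordinate frame at one frame
#'
#' @param markers named list (or single-row data frame from a
#'   [marker_set()]) giving 3-vectors for at least `MEP`, `LEP`, `STU`,
#'   `STR`.
#' @param side `"left"` or `"right"`; stored for the downstream angle
#'   sign convention.
#' @return a `wrist_frame`: list with `origin`, orthonormal right-handed
#'   axes `x`, `y`, `z` (z proximal along the forearm), and `side`.
#' @export
build_wrist_frame <- function(markers, side = "right") {
  get3 <- function(name) {
    if (!is.null(markers[[name]])) return(as.numeric(markers[[name]]))
    cols <- paste(name, c("x", "y", "z"), sep = "_")
    if (all(cols %in% names(markers))) {
      return(as.numeric(unlist(markers[cols])))
    }
    stop_contract(sprintf("marker %s not found", name))
  }
  STR <- get3("STR"); STU <- get3("STU")
  MEP <- get3("MEP"); LEP <- get3("LEP")
  if (sqrt(sum((STR - STU)^2)) < 1e-9) {
    stop_contract("degenerate markers: STR and STU coincide")
  }
  if (sqrt(sum((MEP - LEP)^2)) < 1e-9) {
    stop_contract("degenerate markers: MEP and LEP coincide")
  }
  O <- (STR + STU) / 2
  E <- (MEP + LEP) / 2
  z <- unit3(E - O)
  w <- STR - STU
  x0 <- w - sum(w * z) * z
  x <- unit3(x0)
  y <- c(z[2] * x[3] - z[3] * x[2], # z cross x
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  structure(list(origin = O, x = x, y = y, z = z, side = side),
            class = "wrist_frame")
}

#' @export
print.wrist_frame <- function(x, ...) {
  cat("<wrist_frame> side =", x$side, "\n")
  m <- rbind(origin = x$origin, x = x$x, y = x$y, z = x$z)
  colnames(m) <- c("X", "Y", "Z")
  print(round(m, 4))
  invisible(x)
}

# Linear-interpolate marker gaps up to max_gap_s; returns the repaired
# coordinate matrix plus a per-frame invalid flag for longer gaps.
fill_gaps <- function(coords, rate, max_gap_s = 0.25) {
  max_gap <- as.integer(round(max_gap_s * rate))
  n <- nrow(coords)
  invalid <- rep(FALSE, n)
  for (j in seq_len(ncol(coords))) {
    x <- coords[, j]
    if (!anyNA(x)) next
    na <- is.na(x)
    if (all(na)) {
      invalid[] <- TRUE
      next
    }
    runs <- rle(na)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    long <- which(runs$values & runs$lengths > max_gap)
    for (k in long) invalid[starts[k]:ends[k]] <- TRUE
    # boundary gaps cannot be interpolated
    if (runs$values[1]) invalid[1:ends[1]] <- TRUE
    if (runs$values[length(runs$values)]) {
      invalid[starts[length(runs$values)]:n] <- TRUE
    }
    coords[, j] <- approx(which(!na), x[!na], xout = seq_len(n),
                          rule = 2)$y
  }
  list(coords = coords, invalid = invalid)
}

#' Compute the wrist angle trace from marker trajectories
#'
#' Vectorized per-frame evaluation of the wrist frame and the three DoF
#' angles. Marker gaps are linearly interpolated up to `max_gap_s`;
#' frames inside longer gaps are flagged invalid and their angles set to
#' `NA` (downstream windowing drops them jointly from features and
#' targets).
#'
#' @param markers a [marker_set()].
#' @param side `"left"` or `"right"`; defaults to the marker set's side.
#' @param max_gap_s longest marker gap repaired by interpolation, seconds.
#' @return an [angle_trace()] at the marker rate with an `invalid`
#'   attribute.
#' @export
compute_angles <- function(markers, side = attr(markers, "side"),
                           max_gap_s = 0.25) {
  stopifnot(is_marker_set(markers))
  s <- palmar_sign(side)
  co <- as.matrix(as.data.frame(markers))
  fg <- fill_gaps(co, rate_hz(markers), max_gap_s)
  co <- fg$coords
  g <- function(mk) co[, paste(mk, c("x", "y", "z"), sep = "_"),
                       drop = FALSE]
  O <- (g("STR") + g("STU")) / 2
  E <- (g("MEP") + g("LEP")) / 2
  H <- (g("RMC") + g("UMC")) / 2
  rnorm3 <- function(m) sqrt(rowSums(m^2))
  zv <- E - O
  zn <- rnorm3(zv)
  if (any(zn < 1e-9, na.rm = TRUE)) {
    stop_contract("degenerate markers: wrist and elbow centers coincide")
  }
  z <- zv / zn
  w <- g("STR") - g("STU")
  x0 <- w - rowSums(w * z) * z
  xn <- rnorm3(x0)
  if (any(xn < 1e-9, na.rm = TRUE)) {
    stop_contract("degenerate markers: inter-styloid axis collinear with forearm")
  }
  x <- x0 / xn
  y <- cbind(z[, 2] * x[, 3] - z[, 3] * x[, 2],
             z[, 3] * x[, 1] - z[, 1] * x[, 3],
             z[, 1] * x[, 2] - z[, 2] * x[, 1])
  hv <- H - O
  Hx <- rowSums(hv * x)
  Hy <- rowSums(hv * y)
  Hz <- rowSums(hv * -z)  # distal axis, positive toward the hand
  deg <- 180 / pi
  tol <- 1e-9
  sing <- abs(Hz) < tol
  Hzs <- ifelse(sing, tol, Hz)
  a1 <- s * atan(Hy / Hzs) * deg
  a2 <- atan(Hx / Hzs) * deg
  a1[sing] <- sign(s * Hy[sing]) * 90
  a2[sing] <- sign(Hx[sing]) * 90
  l <- g("LEP") - g("MEP")
  cosa <- rowSums(w * l) / (rnorm3(w) * rnorm3(l))
  a3 <- acos(pmin(1, pmax(-1, cosa))) * deg
  a1 <- pmin(90, pmax(-90, a1))
  a2 <- pmin(90, pmax(-90, a2))
  alpha <- cbind(alpha1 = a1, alpha2 = a2, alpha3 = a3)
  alpha[fg$invalid, ] <- NA_real_
  angle_trace(alpha, rate_hz(markers), side = side, invalid = fg$invalid)
}

#' Low-pass filter and resample an angle trace to the analysis rate
#'
#' Second-order Butterworth low-pass (default 6 Hz, zero-phase so the
#' targets stay aligned with the EMG features), then upsampling to the
#' common analysis rate by linear interpolation. The DoF range invariants
#' are re-imposed after filtering.
#'
#' @param trace an [angle_trace()] (typically at the 256 Hz capture rate).
#' @param target_hz analysis rate, default 1024 Hz.
#' @param cutoff_hz low-pass cutoff in Hz.
#' @param order filter order.
#' @return an [angle_trace()] at `target_hz`.
#' @export
condition_angles <- function(trace, target_hz = 1024, cutoff_hz = 6,
                             order = 2) {
  stopifnot(is_angle_trace(trace))
  fs <- rate_hz(trace)
  if (cutoff_hz >= fs / 2) stop_contract("cutoff must be below Nyquist")
  invalid <- attr(trace, "invalid") %||% rep(FALSE, nrow(trace))
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  n <- nrow(trace)
  m <- as.integer(floor(n * target_hz / fs))
  t_in <- (seq_len(n) - 1) / fs
  t_out <- (seq_len(m) - 1) / target_hz
  cols <- lapply(as.data.frame(trace), function(xc) {
    filled <- xc
    if (anyNA(filled)) {
      ok <- !is.na(filled)
      if (!any(ok)) return(rep(NA_real_, m))
      filled <- approx(which(ok), filled[ok], xout = seq_len(n),
                       rule = 2)$y
    }
    # filter the deviation from the initial value so the zero-state
    # startup transient does not bend the trace ends
    f <- signal::filtfilt(bf, filled - filled[1]) + filled[1]
    approx(t_in, f, xout = t_out, rule = 2)$y
  })
  out <- as.data.frame(cols)
  out$alpha1 <- pmin(90, pmax(-90, out$alpha1))
  out$alpha2 <- pmin(90, pmax(-90, out$alpha2))
  out$alpha3 <- pmin(180, pmax(0, out$alpha3))
  inv_out <- approx(t_in, as.numeric(invalid), xout = t_out,
                    rule = 2)$y > 0
  out[inv_out, ] <- NA_real_
  angle_trace(out, target_hz, side = attr(trace, "side"),
              invalid = inv_out)
}

#' Per-window mean-angle regression targets
#'
#' Window `w` spans the same sample range as the corresponding feature
#' window; its target is the arithmetic mean of each angle over that span.
#' Windows touching invalid (gap-flagged) samples are marked not `valid`.
#'
#' @param trace an [angle_trace()] at the analysis rate, aligned with the
#'   EMG stream.
#' @param spec the [window_spec()] shared with [extract_features()].
#' @return a tibble: `window`, `start`, `alpha1..3` means and `valid`.
#' @export
window_targets <- function(trace, spec) {
  stopifnot(is_angle_trace(trace), inherits(spec, "window_spec"))
  if (abs(spec$rate_hz - rate_hz(trace)) > 1e-9) {
    stop_contract("window spec and trace rates differ")
  }
  n <- nrow(trace)
  if (n < spec$length_smp) {
    stop_contract("trace shorter than one analysis window")
  }
  starts <- window_starts(n, spec)
  idx <- outer(seq_len(spec$length_smp) - 1L, starts, `+`)
  invalid <- attr(trace, "invalid") %||% rep(FALSE, n)
  means <- lapply(as.data.frame(trace), function(xc) {
    colMeans(matrix(xc[idx], nrow = spec$length_smp))
  })
  valid <- colSums(matrix(invalid[idx], nrow = spec$length_smp)) == 0
  dplyr::bind_cols(
    tibble(window = seq_along(starts), start = starts),
    as_tibble(as.data.frame(means)),
    tibble(valid = valid))
}
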