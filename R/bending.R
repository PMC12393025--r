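# Signed bend-angle traces and the metrics derived from them.

#' Signed bend angle at one marker
#'
#' The bend at marker i (1-11) is measured relative to the straight line
#' through the two subsequent markers i+1 and i+2: the magnitude is the
#' angle between the vector (marker i - marker i+1) and that line's
#' direction (marker i+1 - marker i+2); collinear markers give 0 degrees.
#' The sign is positive on the ventral side: with orientation
#' `"ventral-right"` the raw cross-product sign is kept, with
#' `"ventral-left"` it is negated, and with `"unknown"` the raw sign is
#' kept but the result is undifferentiated (dorsal/ventral not assigned).
#'
#' @param markers 13 x 2 matrix of marker positions (head first)
#' @param i marker index 1-11
#' @param orientation `"ventral-right"`, `"ventral-left"` or `"unknown"`
#' @return signed angle in degrees, in (-180, 180)
#' @export
bendAngle <- function(markers, i, orientation = "unknown") {
  stopifnot(i >= 1L, i <= 11L)
  p1 <- markers[i, ]; p2 <- markers[i + 1L, ]; p3 <- markers[i + 2L, ]
  v <- p1 - p2
  d <- p2 - p3
  if (all(v == 0) || all(d == 0)) stop("coincident markers at index ", i)
  mag <- .vecAngleDeg(v, d)
  cr <- d[1] * v[2] - d[2] * v[1]
  s <- if (cr > 0) 1 else if (cr < 0) -1 else 0
  if (orientation == "ventral-left") s <- -s
  s * mag
}

#' Bend-angle trace for a whole track
#'
#' Builds the 11 x T matrix of signed bend angles over time. Frames whose
#' spline fit failed are `NA` columns (gaps) and are excluded from the RMS
#' sample count downstream.
#'
#' @param track a [SplineTrack-class] or [WorldTrack-class]
#' @param orientation sign convention (see [bendAngle()]); defaults to
#'   `"unknown"`
#' @param fs sampling rate of the trace in frames/s; defaults to the
#'   track's effective rate when available, else estimated from timestamps
#' @param time_s optional per-frame timestamps (required for a
#'   [SplineTrack-class] when `fs` is not given)
#' @return a [BendTrace-class]
#' @export
bendTrace <- function(track, orientation = "unknown", fs = NULL,
                      time_s = NULL) {
  mk <- markers(track)
  t <- nrow(mk$x)
  if (t < 2L) stop("need at least 2 frames")
  if (is.null(time_s)) {
    time_s <- if (is(track, "WorldTrack")) track@time_s
              else (seq_len(t) - 1) / (fs %||% 1)
  }
  if (is.null(fs)) {
    dtf <- diff(time_s)
    fs <- if (is(track, "WorldTrack")) track@fpsEffective
          else 1 / stats::median(dtf)
  }
  ang <- matrix(NA_real_, 11L, t)
  for (f in seq_len(t)) {
    if (is.na(mk$x[f, 1])) next
    m <- cbind(mk$x[f, ], mk$y[f, ])
    for (i in 1:11) ang[i, f] <- bendAngle(m, i, orientation)
  }
  new("BendTrace", angles = ang, time_s = time_s, fs = fs,
      orientation = orientation)
}

#' RMS bend and sum of all bends
#'
#' `rmsBend()` evaluates sqrt(sum(x_i^2) / n) over the n non-missing
#' bend-angle samples of marker i — a nonnegative quantity by construction;
#' the displayed value is this absolute magnitude. `sumOfAllBends()` totals
#' the 11 per-marker RMS values.
#'
#' @param trace a [BendTrace-class]
#' @param i marker index 1-11
#' @return degrees
#' @export
rmsBend <- function(trace, i) {
  x <- trace@angles[i, ]
  x <- x[!is.na(x)]
  if (!length(x)) stop("no bend samples at marker ", i)
  sqrt(sum(x^2) / length(x))
}

#' @rdname rmsBend
#' @export
sumOfAllBends <- function(trace) {
  sum(vapply(1:11, function(i) rmsBend(trace, i), numeric(1)))
}

#' Dominant bending frequency by Fourier transform
#'
#' Mean-subtracts marker i's bend trace (gaps linearly interpolated to
#' restore uniform sampling), takes the magnitude spectrum, and returns the
#' frequency bin with the largest magnitude excluding DC. The frequency
#' resolution fs/n is returned alongside the spectrum.
#'
#' @param trace a [BendTrace-class]
#' @param i marker index 1-11
#' @param window `"none"` (default, a plain transform of the trace) or
#'   `"hann"`
#' @return list with `frequency_hz`, `resolution_hz`, and `spectrum`
#'   (data.frame frequency_hz, magnitude)
#' @export
dominantFrequency <- function(trace, i, window = c("none", "hann")) {
  window <- match.arg(window)
  x <- trace@angles[i, ]
  if (anyNA(x)) {
    idx <- seq_along(x)
    ok <- !is.na(x)
    if (sum(ok) < 2L) stop("too few samples to interpolate gaps")
    x <- stats::approx(idx[ok], x[ok], xout = idx, rule = 2)$y
  }
  n <- length(x)
  if (n < 16L) stop("need at least 16 samples for a spectrum, got ", n)
  x <- x - mean(x)
  if (window == "hann") x <- x * (0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1)))
  mag <- Mod(stats::fft(x))
  nb <- floor(n / 2)
  freqs <- (1:nb) * trace@fs / n
  mg <- mag[2:(nb + 1)]
  k <- which.max(mg)
  list(frequency_hz = freqs[k], resolution_hz = trace@fs / n,
       spectrum = data.frame(frequency_hz = freqs, magnitude = mg))
}

#' Maximum bend from alternating peaks and troughs
#'
#' Finds local maxima of at least `minAngle` degrees (ventral peaks) and
#' local minima of at most `-minAngle` (dorsal troughs) in marker i's bend
#' trace, enforces alternation by merging consecutive same-sign extrema
#' (keeping the larger magnitude), and returns the difference between the
#' average ventral peak and the average dorsal trough — the batch-mode
#' equivalent of clicking alternating peaks and troughs with a 20-degree
#' qualification gate.
#'
#' @param trace a [BendTrace-class]
#' @param i marker index 1-11
#' @param minAngle qualification threshold in degrees (default 20)
#' @return degrees (positive span), or `NA` with attribute `reason` when
#'   either side has no qualifying extremum
#' @export
maximumBend <- function(trace, i, minAngle = 20) {
  x <- trace@angles[i, ]
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) stop("trace too short for extrema detection")
  # interior local extrema by sign change of the finite difference
  ext <- integer(0); isMax <- logical(0)
  for (j in 2:(n - 1)) {
    dl <- x[j] - x[j - 1]; dr <- x[j + 1] - x[j]
    if (dl > 0 && dr <= 0) { ext <- c(ext, j); isMax <- c(isMax, TRUE) }
    else if (dl < 0 && dr >= 0) { ext <- c(ext, j); isMax <- c(isMax, FALSE) }
  }
  vals <- x[ext]
  qual <- (isMax & vals >= minAngle) | (!isMax & vals <= -minAngle)
  ext <- ext[qual]; vals <- vals[qual]
  if (!length(ext)) {
    out <- NA_real_; attr(out, "reason") <- "no qualifying extrema"
    return(out)
  }
  # merge consecutive same-sign extrema, keeping the larger magnitude
  keep <- logical(length(vals))
  cur <- 1L
  for (j in seq_along(vals)[-1]) {
    if (sign(vals[j]) == sign(vals[cur])) {
      if (abs(vals[j]) > abs(vals[cur])) cur <- j
    } else {
      keep[cur] <- TRUE
      cur <- j
    }
  }
  keep[cur] <- TRUE
  vals <- vals[keep]
  peaks <- vals[vals > 0]; troughs <- vals[vals < 0]
  if (!length(peaks) || !length(troughs)) {
    out <- NA_real_
    attr(out, "reason") <- "qualifying extrema on one side only"
    return(out)
  }
  mean(peaks) - mean(troughs)
}
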