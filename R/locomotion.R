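# Stage-corrected tracks and locomotion metrics.

#' Merge a spline track with the stage log into world coordinates
#'
#' World position = stage position at the latest stage entry at or before
#' the frame time, plus the pixel position scaled by `umPerPx`. A
#' compensating stage move therefore produces no spurious worm
#' displacement. Stage-free bundles get zero offsets.
#'
#' @param track a [SplineTrack-class]
#' @param rec the [WormRecording-class] the track was fitted from (supplies
#'   stage log, frame times, calibration and frame rate)
#' @return a [WorldTrack-class]
#' @export
toWorld <- function(track, rec) {
  t <- nFrames(track)
  times <- rec@frameTimes$time_s[seq_len(t)]
  sx <- numeric(t); sy <- numeric(t)
  if (!rec@stageFree && nrow(rec@stageLog)) {
    pos <- findInterval(times, rec@stageLog$time_s)
    pos[pos < 1L] <- 1L  # frames before the first entry use the nearest one
    sx <- rec@stageLog$x_um[pos]
    sy <- rec@stageLog$y_um[pos]
  }
  new("WorldTrack",
      time_s = times,
      mx = track@mx * rec@umPerPx + sx,
      my = track@my * rec@umPerPx + sy,
      lengthUm = track@lengthPx * rec@umPerPx,
      umPerPx = rec@umPerPx, fpsNominal = rec@fps,
      fpsEffective = if (rec@fps == 15) 3 else rec@fps)
}

#' Reduce a track to its effective analysis frame rate
#'
#' Movement metrics are computed on the actual frames for 1, 3 and 5 FPS
#' recordings but at 3 FPS for 15 FPS recordings: every 5th frame is kept,
#' starting at frame 1 (frames 1, 6, 11, ...).
#'
#' @param track a [WorldTrack-class]
#' @return the decimated (or unchanged) [WorldTrack-class]
#' @export
effectiveFrames <- function(track) {
  fps <- track@fpsNominal
  if (!fps %in% c(1, 3, 5, 15))
    stop("unsupported frame rate ", fps,
         "; resample the recording explicitly to 1, 3, 5 or 15 FPS")
  if (fps != 15) return(track)
  keep <- seq(1L, nFrames(track), by = 5L)
  new("WorldTrack", time_s = track@time_s[keep],
      mx = track@mx[keep, , drop = FALSE], my = track@my[keep, , drop = FALSE],
      lengthUm = track@lengthUm[keep], umPerPx = track@umPerPx,
      fpsNominal = track@fpsNominal, fpsEffective = 3)
}

#' Classify one locomotion step as forward or backward
#'
#' Compares the velocity vector (previous to current centroid) with the
#' head vector (current centroid to current head tip): a positive
#' projection of the head vector onto the velocity vector means forward,
#' otherwise backward (a zero dot product counts as backward). A zero-length
#' velocity is labeled stationary.
#'
#' @param prevCentroid,centroid,headTip length-2 numeric (x, y) positions
#' @return `"forward"`, `"backward"` or `"stationary"`
#' @export
classifyDirection <- function(prevCentroid, centroid, headTip) {
  v <- centroid - prevCentroid
  if (all(v == 0)) return("stationary")
  h <- headTip - centroid
  if (sum(v * h) > 0) "forward" else "backward"
}

# Per-step direction labels for a track (steps 2..T).
.stepDirections <- function(track, marker) {
  cen <- centroids(track)
  head <- cbind(track@mx[, 1], track@my[, 1])
  t <- nFrames(track)
  vapply(2:t, function(i) {
    if (anyNA(cen[(i - 1):i, ]) || anyNA(head[i, ])) return(NA_character_)
    classifyDirection(cen[i - 1, ], cen[i, ], head[i, ])
  }, character(1))
}

# Positions of the tracked point (a marker index or the centroid).
.trackPoint <- function(track, marker) {
  if (identical(marker, "centroid")) centroids(track)
  else cbind(track@mx[, marker], track@my[, marker])
}

#' Movement summary for one recording
#'
#' Computes average speed, total and net distance, the forward/backward
#' partition of distance, speed and time (per-step labels from
#' [classifyDirection()]), mean and maximum undulation amplitude, worm
#' length, and the A/L ratio. Distances are summed over the chosen marker
#' (or centroid); elapsed time comes from the time log. Steps touching
#' unfitted frames are skipped.
#'
#' @param track a [WorldTrack-class] (pass through [effectiveFrames()]
#'   first; this function does so defensively)
#' @param marker marker index 1-13 or `"centroid"` (default)
#' @return one-row data.frame with units in the column names
#' @export
movementMetrics <- function(track, marker = "centroid") {
  track <- effectiveFrames(track)
  p <- .trackPoint(track, marker)
  okf <- !is.na(p[, 1])
  if (sum(okf) < 2L) stop("need at least 2 fitted frames")
  t <- nFrames(track)
  dirs <- .stepDirections(track)
  step <- rep(NA_real_, t - 1L); dtime <- rep(NA_real_, t - 1L)
  for (i in 2:t) {
    if (okf[i - 1] && okf[i]) {
      step[i - 1L] <- sqrt(sum((p[i, ] - p[i - 1, ])^2))
      dtime[i - 1L] <- track@time_s[i] - track@time_s[i - 1]
    }
  }
  use <- !is.na(step)
  total <- sum(step[use])
  elapsed <- sum(dtime[use])
  firstI <- which(okf)[1]; lastI <- which(okf)[sum(okf)]
  net <- sqrt(sum((p[lastI, ] - p[firstI, ])^2))
  fwd <- use & dirs == "forward" & !is.na(dirs)
  bwd <- use & dirs == "backward" & !is.na(dirs)
  fdist <- sum(step[fwd]); bdist <- sum(step[bwd])
  ftime <- sum(dtime[fwd]); btime <- sum(dtime[bwd])
  amp <- .amplitudeSeries(track)
  L <- mean(track@lengthUm[okf], na.rm = TRUE)
  data.frame(
    avg_speed_um_s = total / elapsed,
    total_distance_um = total,
    net_distance_um = net,
    forward_distance_um = fdist,
    backward_distance_um = bdist,
    forward_speed_um_s = if (ftime > 0) fdist / ftime else 0,
    backward_speed_um_s = if (btime > 0) bdist / btime else 0,
    forward_time_fraction = if (elapsed > 0) ftime / elapsed else 0,
    backward_time_fraction = if (elapsed > 0) btime / elapsed else 0,
    amplitude_mean_um = mean(amp, na.rm = TRUE),
    amplitude_max_um = if (all(is.na(amp))) NA_real_ else max(amp, na.rm = TRUE),
    length_um = L,
    a_over_l = mean(amp, na.rm = TRUE) / L)
}

#' Undulation amplitude from the velocity-aligned bounding rectangle
#'
#' The amplitude is the width of the smallest rectangle parallel to the
#' velocity vector that encloses all 13 spline markers: markers are rotated
#' into the velocity frame and A is the extent of the perpendicular
#' coordinate. L is the worm length (straightened midline).
#'
#' @param markers 13 x 2 matrix of marker positions (um)
#' @param velocity length-2 numeric velocity vector (must be nonzero)
#' @param lengthUm worm length (um)
#' @return named numeric: `A_um`, `L_um`, `A_over_L`
#' @export
amplitudeAndLength <- function(markers, velocity, lengthUm) {
  nv <- sqrt(sum(velocity^2))
  if (nv == 0) stop("zero velocity: amplitude undefined for this frame")
  u <- velocity / nv
  perp <- markers[, 2] * u[1] - markers[, 1] * u[2]
  A <- max(perp) - min(perp)
  c(A_um = A, L_um = lengthUm, A_over_L = A / lengthUm)
}

# Per-frame amplitude using the step ending at each frame as the velocity.
.amplitudeSeries <- function(track) {
  cen <- centroids(track)
  t <- nFrames(track)
  amp <- rep(NA_real_, t)
  for (i in 2:t) {
    v <- cen[i, ] - cen[i - 1, ]
    if (anyNA(v) || all(v == 0) || is.na(track@mx[i, 1])) next
    amp[i] <- amplitudeAndLength(cbind(track@mx[i, ], track@my[i, ]),
                                 v, track@lengthUm[i])[["A_um"]]
  }
  amp
}

#' Reconstruct the travel path and speed series
#'
#' Returns the path of the chosen marker (or centroid) at the effective
#' frame rate, with per-step speed and forward/backward labels, optionally
#' averaged into fixed-width time bins.
#'
#' @param track a [WorldTrack-class]
#' @param marker marker index 1-13 or `"centroid"`
#' @param binSeconds optional bin width (s) for the speed series
#' @return list with `path` (data.frame time_s, x_um, y_um) and `speed`
#'   (data.frame time_s, speed_um_s, direction; binned when requested)
#' @export
travelPath <- function(track, marker = "centroid", binSeconds = NULL) {
  track <- effectiveFrames(track)
  p <- .trackPoint(track, marker)
  t <- nFrames(track)
  if (t < 2L) stop("need at least 2 frames")
  dirs <- .stepDirections(track)
  sp <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-t, , drop = FALSE])^2)) /
    diff(track@time_s)
  speed <- data.frame(time_s = track@time_s[-1], speed_um_s = sp,
                      direction = dirs)
  if (!is.null(binSeconds)) {
    bin <- floor((speed$time_s - track@time_s[1]) / binSeconds)
    agg <- stats::aggregate(speed$speed_um_s, list(bin = bin), mean,
                            na.rm = TRUE)
    speed <- data.frame(time_s = track@time_s[1] + (agg$bin + 0.5) * binSeconds,
                        speed_um_s = agg$x, direction = NA_character_)
  }
  list(path = data.frame(time_s = track@time_s, x_um = p[, 1], y_um = p[, 2]),
       speed = speed)
}

#' Pixel-to-micrometer calibration
#'
#' @param knownDistanceUm physical distance of a calibration target (um)
#' @param pixelDistance the same distance measured in pixels
#' @return micrometers per pixel
#' @export
calibrate <- function(knownDistanceUm, pixelDistance) {
  if (!is.finite(knownDistanceUm) || knownDistanceUm <= 0 ||
      !is.finite(pixelDistance) || pixelDistance <= 0)
    stop("calibration distances must be positive")
  knownDistanceUm / pixelDistance
}
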