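#' @import methods
NULL

#' WormRecording: one recording bundle on disk
#'
#' Container tying together the frame images of a single-worm recording with
#' its companion stage log (absolute motorized-stage positions), time log
#' (per-frame timestamps and stage-movement times), calibration and
#' ventral/dorsal orientation. Built by [resolveRecording()].
#'
#' Coordinates follow a single convention everywhere in the package: pixel
#' coordinates are 1-based with the origin at the top-left corner, x
#' increasing rightward and y increasing downward; stage/world coordinates
#' are in micrometers with y increasing in the same direction as image y.
#'
#' @slot name recording identifier, e.g. `"wt1"` (orientation prefix stripped)
#' @slot imageFiles ordered character vector of frame file paths
#' @slot stageLog data.frame with columns `time_s`, `x_um`, `y_um`
#' @slot frameTimes data.frame with columns `frame`, `time_s`
#' @slot moveTimes numeric vector of stage-movement timestamps (s)
#' @slot orientation `"ventral-right"`, `"ventral-left"` or `"unknown"`
#' @slot umPerPx micrometers per pixel (> 0)
#' @slot fps nominal acquisition frame rate; one of 1, 3, 5, 15
#' @slot splineFile path of a discovered spline file, or `NA_character_`
#' @slot stageFree `TRUE` when no stage/time logs were found (offsets zero)
#' @export
setClass("WormRecording", representation(
  name = "character", imageFiles = "character", stageLog = "data.frame",
  frameTimes = "data.frame", moveTimes = "numeric", orientation = "character",
  umPerPx = "numeric", fps = "numeric", splineFile = "character",
  stageFree = "logical"))

setValidity("WormRecording", function(object) {
  msg <- character()
  if (!object@orientation %in% c("ventral-right", "ventral-left", "unknown"))
    msg <- c(msg, "orientation must be ventral-right, ventral-left or unknown")
  if (length(object@umPerPx) != 1L || object@umPerPx <= 0)
    msg <- c(msg, "umPerPx must be a single positive number")
  if (!object@fps %in% c(1, 3, 5, 15))
    msg <- c(msg, "fps must be one of 1, 3, 5, 15")
  if (nrow(object@stageLog) > 1 && any(diff(object@stageLog$time_s) <= 0))
    msg <- c(msg, "stage log timestamps must be strictly increasing")
  if (nrow(object@frameTimes) > 1 && any(diff(object@frameTimes$time_s) < 0))
    msg <- c(msg, "frame timestamps must be nondecreasing")
  if (length(msg)) msg else TRUE
})

#' Spline13: a fitted 13-marker midline pose for one frame
#'
#' The universal unit of worm pose: 13 ordered markers at equal arc-length
#' intervals along the midline, marker 1 at the head tip and marker 13 at the
#' tail tip, plus the dense midline they were sampled from.
#'
#' @slot markers 13 x 2 matrix of (x, y) pixel positions, head first
#' @slot dense n x 2 matrix, the dense smoothed midline (head to tail)
#' @slot lengthPx arc length of the dense midline, in pixels
#' @export
setClass("Spline13", representation(
  markers = "matrix", dense = "matrix", lengthPx = "numeric"))

setValidity("Spline13", function(object) {
  msg <- character()
  if (!all(dim(object@markers) == c(13L, 2L)))
    msg <- c(msg, "markers must be a 13 x 2 matrix")
  if (anyNA(object@markers)) msg <- c(msg, "markers must be finite")
  if (length(object@lengthPx) != 1L || object@lengthPx <= 0)
    msg <- c(msg, "lengthPx must be a single positive number")
  # equal arc spacing within 2% (marker arc positions by projection onto
  # the dense midline)
  if (nrow(object@dense) >= 13L && !anyNA(object@dense) &&
      !anyNA(object@markers)) {
    pos <- vapply(seq_len(13L), function(i)
      .arcPositionOf(object@dense, object@markers[i, ]), numeric(1))
    gaps <- diff(pos)
    if (any(gaps <= 0) ||
        any(abs(gaps - mean(gaps)) > 0.02 * mean(gaps) + 1e-9))
      msg <- c(msg, "inter-marker arc spacing not equal within 2%")
  }
  if (length(msg)) msg else TRUE
})

#' SplineTrack: per-frame spline fits for a whole recording
#'
#' Row-per-frame container for midline fits: marker coordinate matrices with
#' one row per frame and 13 columns, the fit status, and the brightness
#' threshold and retry count used by automatic fitting. Failed frames carry
#' `NA` coordinates and keep their place so timestamps stay aligned.
#'
#' @slot frame integer frame indices (contiguous from 1)
#' @slot status character, `"ok"` or `"fail"` per frame
#' @slot threshold brightness threshold used per frame
#' @slot attempts number of thresholds tried per frame
#' @slot mx,my T x 13 matrices of marker pixel coordinates
#' @slot lengthPx per-frame dense-midline arc length (pixels)
#' @export
setClass("SplineTrack", representation(
  frame = "integer", status = "character", threshold = "numeric",
  attempts = "integer", mx = "matrix", my = "matrix", lengthPx = "numeric"))

setValidity("SplineTrack", function(object) {
  t <- length(object@frame)
  ok <- all(dim(object@mx) == c(t, 13L)) && all(dim(object@my) == c(t, 13L)) &&
    length(object@status) == t && length(object@lengthPx) == t
  if (!ok) return("slot dimensions inconsistent (need T frames x 13 markers)")
  fitted <- object@status == "ok"
  if (any(fitted) && anyNA(object@mx[fitted, , drop = FALSE]))
    return("fitted frames must have 13 finite marker pairs")
  TRUE
})

#' WorldTrack: stage-corrected pose time series in micrometers
#'
#' Marker positions per frame in absolute (stage-corrected) micrometer
#' coordinates, with timestamps from the time log. Produced by [toWorld()];
#' [effectiveFrames()] reduces 15 FPS recordings to the 3 FPS analysis rate.
#'
#' @slot time_s per-frame timestamps (s)
#' @slot mx,my T x 13 matrices of marker positions (um)
#' @slot lengthUm per-frame worm length (um)
#' @slot umPerPx calibration used
#' @slot fpsNominal acquisition frame rate
#' @slot fpsEffective analysis frame rate (3 for 15 FPS input)
#' @export
setClass("WorldTrack", representation(
  time_s = "numeric", mx = "matrix", my = "matrix", lengthUm = "numeric",
  umPerPx = "numeric", fpsNominal = "numeric", fpsEffective = "numeric"))

setValidity("WorldTrack", function(object) {
  t <- length(object@time_s)
  if (!all(dim(object@mx) == c(t, 13L)) || !all(dim(object@my) == c(t, 13L)))
    return("marker matrices must be T x 13")
  TRUE
})

#' BendTrace: signed bend angles at markers 1-11 over time
#'
#' An 11 x T matrix of signed bend angles in degrees (ventral positive when
#' the recording orientation is known), the substrate for RMS bend, the
#' dominant undulation frequency and the maximum bend. Frames whose spline
#' fit failed are `NA` columns.
#'
#' @slot angles 11 x T matrix of bend angles (degrees)
#' @slot time_s T timestamps (s)
#' @slot fs sampling rate of the trace (frames/s)
#' @slot orientation orientation the signs refer to; `"unknown"` means the
#'   sign follows the package's fixed cross-product convention
#'   (undifferentiated ventral/dorsal)
#' @export
setClass("BendTrace", representation(
  angles = "matrix", time_s = "numeric", fs = "numeric",
  orientation = "character"))

setValidity("BendTrace", function(object) {
  if (nrow(object@angles) != 11L) return("angles must have 11 rows")
  if (ncol(object@angles) != length(object@time_s))
    return("angles columns must match timestamps")
  if (any(abs(object@angles) >= 180, na.rm = TRUE))
    return("bend angles must satisfy |angle| < 180")
  TRUE
})

#' VoltageTrace: a uniformly sampled current-clamp voltage trace
#'
#' @slot v membrane potential samples (mV)
#' @slot dt sampling interval (s); 1e-4 for the nominal 10 kHz
#' @slot meta list of source metadata (file, sweep, channel)
#' @export
setClass("VoltageTrace", representation(
  v = "numeric", dt = "numeric", meta = "list"))

setValidity("VoltageTrace", function(object) {
  if (length(object@dt) != 1L || object@dt <= 0) return("dt must be > 0")
  if (length(object@v) < 2L) return("trace needs at least 2 samples")
  TRUE
})

## show methods ---------------------------------------------------------------

setMethod("show", "WormRecording", function(object) {
  cat("WormRecording '", object@name, "': ", length(object@imageFiles),
      " frames @ ", object@fps, " fps, ", object@umPerPx, " um/px, ",
      object@orientation,
      if (object@stageFree) " (stage-free)" else "", "\n", sep = "")
})

setMethod("show", "Spline13", function(object) {
  cat("Spline13: 13 markers, length", round(object@lengthPx, 1), "px\n")
})

setMethod("show", "SplineTrack", function(object) {
  cat("SplineTrack:", length(object@frame), "frames (",
      sum(object@status == "ok"), "fitted )\n")
})

setMethod("show", "WorldTrack", function(object) {
  cat("WorldTrack:", length(object@time_s), "frames,",
      object@fpsEffective, "fps effective\n")
})

setMethod("show", "BendTrace", function(object) {
  cat("BendTrace: 11 x", ncol(object@angles), "at", object@fs, "fps (",
      object@orientation, ")\n")
})

setMethod("show", "VoltageTrace", function(object) {
  cat("VoltageTrace:", length(object@v), "samples @",
      round(1 / object@dt), "Hz\n")
})
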