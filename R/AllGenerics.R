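#' Accessors for NemaTrack containers
#'
#' `markers()` returns marker coordinates; `centroids()` the per-frame
#' centroid (arithmetic mean of the 13 markers); `nFrames()` the frame
#' count; `wormLengths()` per-frame worm lengths; `fitStatus()` the
#' per-frame fit status of a [SplineTrack-class].
#'
#' @param x a NemaTrack container
#' @param ... ignored
#' @return `markers()`: a 13 x 2 matrix for [Spline13-class]; for track
#'   classes a list with elements `x` and `y`, each T x 13. `centroids()`:
#'   a T x 2 (or 1 x 2) matrix. `nFrames()`: integer. `wormLengths()`:
#'   numeric vector. `fitStatus()`: character vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("markers", function(x, ...) standardGeneric("markers"))

#' @rdname accessors
#' @export
setGeneric("centroids", function(x, ...) standardGeneric("centroids"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("wormLengths", function(x) standardGeneric("wormLengths"))

#' @rdname accessors
#' @export
setGeneric("fitStatus", function(x) standardGeneric("fitStatus"))

#' @rdname accessors
#' @export
setMethod("markers", "Spline13", function(x, ...) x@markers)

#' @rdname accessors
#' @export
setMethod("markers", "SplineTrack", function(x, ...) list(x = x@mx, y = x@my))

#' @rdname accessors
#' @export
setMethod("markers", "WorldTrack", function(x, ...) list(x = x@mx, y = x@my))

#' @rdname accessors
#' @export
setMethod("centroids", "Spline13", function(x, ...)
  matrix(colMeans(x@markers), 1L, 2L, dimnames = list(NULL, c("x", "y"))))

#' @rdname accessors
#' @export
setMethod("centroids", "SplineTrack", function(x, ...)
  cbind(x = rowMeans(x@mx), y = rowMeans(x@my)))

#' @rdname accessors
#' @export
setMethod("centroids", "WorldTrack", function(x, ...)
  cbind(x = rowMeans(x@mx), y = rowMeans(x@my)))

#' @rdname accessors
#' @export
setMethod("nFrames", "SplineTrack", function(x) length(x@frame))

#' @rdname accessors
#' @export
setMethod("nFrames", "WorldTrack", function(x) length(x@time_s))

#' @rdname accessors
#' @export
setMethod("wormLengths", "SplineTrack", function(x) x@lengthPx)

#' @rdname accessors
#' @export
setMethod("wormLengths", "WorldTrack", function(x) x@lengthUm)

#' @rdname accessors
#' @export
setMethod("fitStatus", "SplineTrack", function(x) x@status)
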