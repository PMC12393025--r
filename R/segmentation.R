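# Frame -> binary mask -> outline -> head/tail -> 13-marker midline.

#' Threshold a grayscale frame into a binary worm mask
#'
#' With `polarity = "worm-dark"` (transmitted light, the usual case) the
#' foreground is every pixel strictly below the brightness threshold; with
#' `"worm-bright"` the complement. An all-foreground or all-background
#' result is returned but flagged unusable via `attr(mask, "usable")`.
#'
#' @param image numeric intensity matrix (0-255 scale), indexed `[x, y]`
#' @param threshold brightness threshold on the image's intensity scale
#' @param polarity `"worm-dark"` or `"worm-bright"`
#' @return integer 0/1 matrix with attribute `usable` (logical)
#' @export
binarize <- function(image, threshold, polarity = c("worm-dark", "worm-bright")) {
  polarity <- match.arg(polarity)
  mask <- if (polarity == "worm-dark") (image < threshold) else (image >= threshold)
  storage.mode(mask) <- "integer"
  n1 <- sum(mask)
  attr(mask, "usable") <- n1 > 0L && n1 < length(mask)
  mask
}

# 8-connectivity labeling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged afterwards with a union-find pass.
.label8 <- function(mask) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(m))
  k <- max(lab)
  if (k <= 1L) return(lab)
  nx <- nrow(lab); ny <- ncol(lab)
  a1 <- lab[-nx, -ny]; b1 <- lab[-1, -1]    # \ diagonal neighbors
  a2 <- lab[-nx, -1];  b2 <- lab[-1, -ny]   # / diagonal neighbors
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(k), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Remove small connected components (debris filter)
#'
#' Deletes every 8-connected foreground component whose pixel area is below
#' `minArea`; 3,000 px is the conventional cutoff separating a worm body
#' from debris at typical magnification. An empty result is flagged
#' unusable.
#'
#' @param mask 0/1 matrix from [binarize()]
#' @param minArea minimum component area in pixels (default 3000)
#' @return filtered 0/1 matrix with attribute `usable`
#' @export
removeDebris <- function(mask, minArea = 3000) {
  lab <- .label8(mask)
  out <- mask
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = max(lab))
    small <- which(areas < minArea)
    if (length(small)) out[lab %in% small] <- 0L
  }
  attr(out, "usable") <- sum(out) > 0L
  attr(out, "nComponents") <- sum(tabulate(lab[lab > 0L],
                                           nbins = max(lab, 1L)) >= minArea)
  out
}

#' Trace and smooth the worm outline
#'
#' Traces the boundary of the largest foreground component, smooths the
#' vertex coordinates with a circular moving average, and orients the
#' polygon counterclockwise (positive shoelace area in image coordinates).
#' With more than one component the largest is used with a warning.
#'
#' @param mask 0/1 matrix (after [removeDebris()])
#' @param smoothWindow moving-average window in vertices (default 5)
#' @return list with `xy` (n x 2 matrix of 1-based pixel coordinates),
#'   `perimeter` (px)
#' @export
extractOutline <- function(mask, smoothWindow = 5) {
  lab <- .label8(mask)
  k <- max(lab)
  if (k == 0L) stop("empty mask: no component to outline")
  areas <- tabulate(lab[lab > 0L], nbins = k)
  if (k > 1L) warning("multiple components; using the largest")
  big <- matrix(as.numeric(lab == which.max(areas)), nrow(lab), ncol(lab))
  oc <- EBImage::ocontour(big)[[1]]
  if (nrow(oc) < 40L)
    stop("outline too small (", nrow(oc), " vertices); not a worm body")
  raw <- oc + 1  # ocontour is 0-based
  xy <- cbind(.movAvgCircular(raw[, 1], smoothWindow),
              .movAvgCircular(raw[, 2], smoothWindow))
  area2 <- sum(xy[, 1] * c(xy[-1, 2], xy[1, 2]) -
               c(xy[-1, 1], xy[1, 1]) * xy[, 2])
  if (area2 < 0) {
    xy <- xy[nrow(xy):1, , drop = FALSE]
    raw <- raw[nrow(raw):1, , drop = FALSE]
  }
  d <- diff(rbind(xy, xy[1, , drop = FALSE]))
  list(xy = xy, raw = raw, perimeter = sum(sqrt(rowSums(d^2))))
}

# Corner sharpness per outline vertex: the angle (radians) subtended at
# vertex i by the vertices k steps away on either side. Sharper = smaller.
.cornerAngles <- function(xy, k = 15) {
  n <- nrow(xy)
  k <- min(k, floor((n - 1) / 2))
  im <- ((seq_len(n) - 1 - k) %% n) + 1
  ip <- ((seq_len(n) - 1 + k) %% n) + 1
  ax <- xy[im, 1] - xy[, 1]; ay <- xy[im, 2] - xy[, 2]
  bx <- xy[ip, 1] - xy[, 1]; by <- xy[ip, 2] - xy[, 2]
  cosang <- (ax * bx + ay * by) /
    pmax(sqrt(ax^2 + ay^2) * sqrt(bx^2 + by^2), .Machine$double.eps)
  acos(pmin(1, pmax(-1, cosang)))
}

#' Locate head and tail on the outline by corner sharpness
#'
#' Scores every outline vertex by the angle subtended over a `k`-vertex
#' span; the sharpest corner is the tail candidate and the second-sharpest
#' (at least 10% of the perimeter away) the head candidate. With a previous
#' head position the candidate nearer to it becomes the head and the
#' assignment is confirmed; without one (first frame) the sharper corner is
#' labeled tail and the result flagged unconfirmed for user confirmation.
#' Two candidates of indistinguishable sharpness with no previous head (a
#' symmetric silhouette) raise an ambiguity error.
#'
#' @param outline list from [extractOutline()]
#' @param prevHead length-2 numeric (x, y) of the previous frame's head, or
#'   `NULL`
#' @param k half-span, in vertices, of the corner-sharpness probe
#'   (default 15)
#' @param ambiguityDeg sharpness difference (degrees) below which two
#'   candidates are considered tied (default 4)
#' @return list with `head`, `tail` (each length-2 numeric), `headIdx`,
#'   `tailIdx` (vertex indices), `confirmed` (logical)
#' @export
detectHeadTail <- function(outline, prevHead = NULL, k = 15, ambiguityDeg = 4) {
  xy <- outline$xy
  n <- nrow(xy)
  ang <- .cornerAngles(xy, k)
  i1 <- which.min(ang)
  minSep <- ceiling(0.10 * n)
  sep <- pmin(abs(seq_len(n) - i1), n - abs(seq_len(n) - i1))
  far <- which(sep >= minSep)
  if (!length(far)) stop("ambiguity: no second corner candidate on outline")
  i2 <- far[which.min(ang[far])]
  if (is.null(prevHead)) {
    if (abs(ang[i1] - ang[i2]) * 180 / pi < ambiguityDeg)
      stop("ambiguity: head and tail corners equally sharp; ",
           "supply a head seed for the first frame")
    tailIdx <- i1; headIdx <- i2; confirmed <- FALSE
  } else {
    d1 <- sum((xy[i1, ] - prevHead)^2)
    d2 <- sum((xy[i2, ] - prevHead)^2)
    headIdx <- if (d1 < d2) i1 else i2
    tailIdx <- if (d1 < d2) i2 else i1
    confirmed <- TRUE
  }
  list(head = xy[headIdx, ], tail = xy[tailIdx, ],
       headIdx = headIdx, tailIdx = tailIdx, confirmed = confirmed)
}

#' Fit the 13-marker midline between head and tail
#'
#' Splits the outline at the head and tail vertices into two flanks,
#' pairs flank points by normalized arc length, takes their midpoints as
#' the raw midline, smooths it, interpolates a dense cubic curve, and
#' places 13 markers at equal arc-length intervals with marker 1 at the
#' head. A self-intersecting midline (an omega posture) signals fit
#' failure.
#'
#' @param outline list from [extractOutline()]
#' @param headIdx,tailIdx outline vertex indices from [detectHeadTail()]
#' @param nDense number of dense midline points (default 100)
#' @return a [Spline13-class], or an error of class `nematrackFitError`
#'   for an omega posture
#' @export
fitMidline <- function(outline, headIdx, tailIdx, nDense = 100) {
  xy <- outline$xy
  n <- nrow(xy)
  if (headIdx == tailIdx) stop("head and tail coincide")
  idxA <- if (headIdx < tailIdx) headIdx:tailIdx
          else c(headIdx:n, 1:tailIdx)
  idxB <- if (headIdx < tailIdx) c(headIdx:1, n:tailIdx)
          else headIdx:tailIdx
  npair <- max(40L, nDense)
  a <- .resampleArc(xy[idxA, , drop = FALSE], npair)
  b <- .resampleArc(xy[idxB, , drop = FALSE], 3L * npair)
  # pair each point of one flank with its closest point on the other:
  # robust to the inner/outer flank length mismatch on bends
  mid <- a
  for (i in seq_len(npair)) {
    d2 <- (b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2
    mid[i, ] <- (a[i, ] + b[which.min(d2), ]) / 2
  }
  mid <- cbind(.movAvgOpen(mid[, 1], 5), .movAvgOpen(mid[, 2], 5))
  # anchor the midline ends to the unsmoothed tip positions: boundary and
  # midline smoothing erode sharp tips, shortening the recovered body
  if (!is.null(outline$raw)) {
    mid[1L, ] <- outline$raw[headIdx, ]
    mid[npair, ] <- outline$raw[tailIdx, ]
  }
  # cubic interpolation through thinned control points -> smooth dense curve
  ctrl <- mid[unique(round(seq(1, npair, length.out = 25))), , drop = FALSE]
  s <- .cumArc(ctrl)
  si <- seq(0, s[length(s)], length.out = nDense * 2L)
  dense <- cbind(stats::spline(s, ctrl[, 1], xout = si)$y,
                 stats::spline(s, ctrl[, 2], xout = si)$y)
  dense <- .resampleArc(dense, nDense)
  if (.selfIntersects(dense)) {
    e <- simpleError("midline self-intersects (omega posture); fit failed")
    class(e) <- c("nematrackFitError", class(e))
    stop(e)
  }
  mk <- .resampleArc(dense, 13L)
  new("Spline13", markers = mk, dense = dense, lengthPx = .arcLength(dense))
}

#' Fit one frame with automatic threshold retry
#'
#' Runs the full chain binarize -> debris filter -> outline -> head/tail ->
#' midline. On failure the brightness threshold is adjusted in an
#' alternating pattern (+step, -step, +2 step, -2 step, ...) for up to
#' `maxRetries` additional attempts.
#'
#' @param image intensity matrix (0-255), as from [loadFrame()]
#' @param config list of fitting parameters: `threshold` (required),
#'   `polarity` (default `"worm-dark"`), `minArea` (3000), `step` (5
#'   intensity levels), `maxRetries` (10), `cornerK` (15), `smoothWindow`
#'   (5), `nDense` (100), `headSeed` (optional (x, y) for frame 1)
#' @param prev previous frame's result from `fitFrame()` (supplies the head
#'   reference), or `NULL`
#' @return list with `spline` ([Spline13-class] or `NULL`), `ok`,
#'   `thresholdUsed`, `attempts`, `headConfirmed`, `head`, `error` (last
#'   failure message when `ok` is `FALSE`)
#' @export
fitFrame <- function(image, config, prev = NULL) {
  stopifnot(!is.null(config$threshold))
  polarity <- config$polarity %||% "worm-dark"
  minArea <- config$minArea %||% 3000
  step <- config$step %||% 5
  maxRetries <- config$maxRetries %||% 10
  prevHead <- if (!is.null(prev) && isTRUE(prev$ok)) prev$head
              else config$headSeed
  offs <- c(0, as.vector(rbind(seq_len(maxRetries), -seq_len(maxRetries))))
  offs <- offs[seq_len(1L + maxRetries)]
  lastErr <- "unknown"
  for (i in seq_along(offs)) {
    thr <- config$threshold + offs[i] * step
    res <- tryCatch({
      mask <- binarize(image, thr, polarity)
      if (!attr(mask, "usable")) stop("degenerate mask at threshold ", thr)
      mask <- removeDebris(mask, minArea)
      if (!attr(mask, "usable")) stop("no component >= minArea at threshold ", thr)
      # a self-contacting (omega) body closes a hole in its own mask
      filled <- EBImage::imageData(EBImage::fillHull(
        matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))))
      if (sum(filled) > sum(mask > 0) + 25) {
        e <- simpleError("mask encloses a hole (omega posture); fit failed")
        class(e) <- c("nematrackFitError", class(e))
        stop(e)
      }
      outline <- extractOutline(mask, config$smoothWindow %||% 5)
      ht <- detectHeadTail(outline, prevHead, config$cornerK %||% 15)
      sp <- fitMidline(outline, ht$headIdx, ht$tailIdx, config$nDense %||% 100)
      list(spline = sp, ok = TRUE, thresholdUsed = thr, attempts = i,
           headConfirmed = ht$confirmed, head = as.numeric(sp@markers[1, ]),
           error = NA_character_)
    }, error = function(e) e)
    if (!inherits(res, "error")) return(res)
    lastErr <- conditionMessage(res)
  }
  list(spline = NULL, ok = FALSE, thresholdUsed = config$threshold,
       attempts = length(offs), headConfirmed = FALSE, head = NULL,
       error = lastErr)
}

#' Fit every frame of a recording into a SplineTrack
#'
#' Iterates [fitFrame()] over the recording's frames, propagating the head
#' position from the previous successful fit. For the first frame either
#' supply `config$headSeed` or accept the corner-sharpness assignment
#' (flagged unconfirmed in the fit log).
#'
#' @param rec a [WormRecording-class]
#' @param config see [fitFrame()]
#' @param verbose print per-frame diagnostics (default `FALSE`)
#' @return a [SplineTrack-class]
#' @export
fitRecording <- function(rec, config, verbose = FALSE) {
  t <- length(rec@imageFiles)
  mx <- matrix(NA_real_, t, 13L); my <- matrix(NA_real_, t, 13L)
  status <- character(t); thr <- numeric(t); att <- integer(t)
  len <- rep(NA_real_, t)
  prev <- NULL
  for (i in seq_len(t)) {
    img <- loadFrame(rec@imageFiles[i])
    res <- fitFrame(img, config, prev)
    status[i] <- if (res$ok) "ok" else "fail"
    thr[i] <- res$thresholdUsed; att[i] <- res$attempts
    if (res$ok) {
      mx[i, ] <- res$spline@markers[, 1]
      my[i, ] <- res$spline@markers[, 2]
      len[i] <- res$spline@lengthPx
      prev <- res
    }
    if (verbose)
      message(sprintf("frame %d: %s (threshold %g, attempts %d)",
                      i, status[i], thr[i], att[i]))
  }
  new("SplineTrack", frame = seq_len(t), status = status, threshold = thr,
      attempts = att, mx = mx, my = my, lengthPx = len)
}

#' Override marker positions for one frame
#'
#' Programmatic stand-in for interactive spline correction: replaces the 13
#' markers of frame `frame` and marks it fitted.
#'
#' @param track a [SplineTrack-class]
#' @param frame frame index
#' @param markers 13 x 2 matrix of (x, y) pixel positions
#' @return the modified [SplineTrack-class]
#' @export
setMarkers <- function(track, frame, markers) {
  stopifnot(is(track, "SplineTrack"), all(dim(markers) == c(13L, 2L)))
  track@mx[frame, ] <- markers[, 1]
  track@my[frame, ] <- markers[, 2]
  track@status[frame] <- "ok"
  track@lengthPx[frame] <- .arcLength(markers)
  validObject(track)
  track
}

`%||%` <- function(a, b) if (is.null(a)) b else a
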