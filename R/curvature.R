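# Inflection-bounded curvature segments and Kasa circle fitting.

#' Kasa least-squares circle fit
#'
#' Minimizes the algebraic residual sum((x^2 + y^2 - 2ax - 2by - c)^2) by
#' linear least squares; the center is (a, b) and the radius
#' sqrt(a^2 + b^2 + c). Exact on noiseless circles.
#'
#' @param points n x 2 matrix of (x, y) coordinates, n >= 3, not collinear
#' @return list with `center` (length-2) and `r`
#' @export
kasaFit <- function(points) {
  if (nrow(points) < 3L) stop("need at least 3 points")
  x <- points[, 1]; y <- points[, 2]
  X <- cbind(2 * x, 2 * y, 1)
  z <- x^2 + y^2
  qr_ <- qr(X)
  if (qr_$rank < 3L) stop("collinear points: circle radius infinite")
  beta <- qr.coef(qr_, z)
  r2 <- beta[1]^2 + beta[2]^2 + beta[3]
  if (!is.finite(r2) || r2 <= 0)
    stop("degenerate circle fit (nonpositive squared radius)")
  list(center = c(beta[1], beta[2]), r = sqrt(r2))
}

# Signed discrete curvature along a polyline: three-point finite-difference
# (cross product of successive chords over chord length product). Positive
# where the curve turns left in (x right, y down) coordinates.
.signedCurvature <- function(p) {
  n <- nrow(p)
  k <- rep(NA_real_, n)
  d1 <- p[2:(n - 1), ] - p[1:(n - 2), ]
  d2 <- p[3:n, ] - p[2:(n - 1), ]
  cr <- d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]
  len <- sqrt(rowSums(d1^2)) * sqrt(rowSums(d2^2))
  k[2:(n - 1)] <- cr / pmax(len, .Machine$double.eps)
  k[1] <- k[2]; k[n] <- k[n - 1]
  k
}

#' Segment the midline at inflection points
#'
#' Resamples the dense midline, smooths it, computes signed local
#' curvature by three-point finite differences, and cuts the midline at
#' sign changes (inflection points). Segments shorter than `minFrac` of
#' body length are merged into a neighboring segment of the same curvature
#' sign when one exists, otherwise dropped (one pass). A worm with no sign
#' change and near-zero curvature everywhere yields a single segment
#' flagged near-straight.
#'
#' @param spline a [Spline13-class]
#' @param nResample dense resampling count (default 100)
#' @param smoothWindow moving-average window on the resampled midline
#'   (default 7)
#' @param minFrac minimum segment length as a fraction of body length
#'   (default 0.03)
#' @param flatTol mean |curvature per step| below which the whole midline
#'   counts as straight (default 1e-3 radians/step)
#' @return data.frame with columns `start_frac`, `end_frac`, `mid_frac`,
#'   `sign` (+1 left-turning, -1 right-turning), `near_straight`, and a
#'   `points` attribute: list of the dense point matrices per segment
#' @export
detectInflections <- function(spline, nResample = 100, smoothWindow = 7,
                              minFrac = 0.03, flatTol = 1e-3) {
  p <- .resampleArc(spline@dense, nResample)
  p <- cbind(.movAvgOpen(p[, 1], smoothWindow), .movAvgOpen(p[, 2], smoothWindow))
  k <- .signedCurvature(p)
  n <- nrow(p)
  frac <- (seq_len(n) - 1) / (n - 1)
  if (mean(abs(k)) < flatTol) {
    seg <- data.frame(start_frac = 0, end_frac = 1, mid_frac = 0.5,
                      sign = sign(sum(k)), near_straight = TRUE)
    attr(seg, "points") <- list(p)
    return(seg)
  }
  s <- sign(k)
  s[s == 0] <- 1
  # smoothing is asymmetric at the curve ends and the three-point curvature
  # stencil reaches one point further: extend the first/last clean interior
  # signs outward over that boundary band
  pad <- (smoothWindow - 1L) %/% 2L + 2L
  if (n > 2L * pad) {
    s[1:pad] <- s[pad + 1L]
    s[(n - pad + 1L):n] <- s[n - pad]
  }
  cuts <- which(diff(s) != 0)  # boundary between i and i+1
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  segs <- data.frame(start = starts, end = ends,
                     sign = s[starts],
                     len = frac[ends] - frac[starts])
  # one merge pass: absorb sub-minFrac segments into a same-sign neighbor
  repeatDrop <- TRUE
  while (repeatDrop && nrow(segs) > 1L) {
    repeatDrop <- FALSE
    short <- which(segs$len < minFrac)
    if (!length(short)) break
    i <- short[1]
    nb <- c(if (i > 1 && segs$sign[i - 1] == segs$sign[i]) i - 1,
            if (i < nrow(segs) && segs$sign[i + 1] == segs$sign[i]) i + 1)
    if (length(nb)) {
      j <- nb[1]
      segs$start[j] <- min(segs$start[i], segs$start[j])
      segs$end[j] <- max(segs$end[i], segs$end[j])
      segs$len[j] <- frac[segs$end[j]] - frac[segs$start[j]]
    }
    segs <- segs[-i, , drop = FALSE]
    repeatDrop <- TRUE
  }
  segs <- segs[segs$len >= minFrac, , drop = FALSE]
  if (!nrow(segs)) stop("no segment of at least ", minFrac * 100,
                        "% body length")
  out <- data.frame(start_frac = frac[segs$start], end_frac = frac[segs$end],
                    mid_frac = (frac[segs$start] + frac[segs$end]) / 2,
                    sign = segs$sign, near_straight = FALSE)
  attr(out, "points") <- lapply(seq_len(nrow(segs)), function(i)
    p[segs$start[i]:segs$end[i], , drop = FALSE])
  out
}

#' Normalized body curvature per segment
#'
#' Fits a Kasa circle to each inflection-bounded midline segment and
#' reports the normalized curvature L/r (worm length over fitted radius).
#' The side of each segment (ventral/dorsal) follows its curvature sign
#' and the recording orientation; ranks are assigned head-to-tail within
#' each side (V1, V2, ..., D1, D2, ...). Collinear segments get curvature
#' 0. With unknown orientation the sides are reported as `U+`/`U-`
#' (undifferentiated).
#'
#' @param spline a [Spline13-class]
#' @param orientation `"ventral-right"`, `"ventral-left"` or `"unknown"`
#' @param ... passed to [detectInflections()]
#' @return data.frame with columns `start_frac`, `end_frac`, `mid_frac`,
#'   `side`, `rank` (e.g. `"V1"`), `r_px`, `curvature` (= L/r),
#'   `near_straight`
#' @export
curvatures <- function(spline, orientation = "unknown", ...) {
  segs <- detectInflections(spline, ...)
  pts <- attr(segs, "points")
  L <- spline@lengthPx
  r <- numeric(nrow(segs)); curv <- numeric(nrow(segs))
  for (i in seq_len(nrow(segs))) {
    fit <- tryCatch(kasaFit(pts[[i]]), error = function(e) NULL)
    if (is.null(fit)) { r[i] <- Inf; curv[i] <- 0 }
    else { r[i] <- fit$r; curv[i] <- L / fit$r }
  }
  sgn <- segs$sign
  if (orientation == "ventral-left") sgn <- -sgn
  side <- if (orientation == "unknown") ifelse(sgn > 0, "U+", "U-")
          else ifelse(sgn > 0, "V", "D")
  rank <- integer(nrow(segs))
  for (sd in unique(side)) rank[side == sd] <- seq_len(sum(side == sd))
  data.frame(start_frac = segs$start_frac, end_frac = segs$end_frac,
             mid_frac = segs$mid_frac, side = side,
             rank = paste0(side, rank), r_px = r, curvature = curv,
             near_straight = segs$near_straight)
}

#' Exclude weak primary curvatures and promote the next rank
#'
#' Within each side, while the first-ranked segment's curvature is below
#' `minValue` it is excluded and the subsequent ranks promoted (V2 becomes
#' V1, V3 becomes V2, ...). A side whose segments are all excluded is
#' reported missing (no rows for that side).
#'
#' @param segments data.frame from [curvatures()]
#' @param minValue primary-curvature cutoff (default 2.5)
#' @return the filtered, re-ranked data.frame
#' @export
filterPrimaryCurvatures <- function(segments, minValue = 2.5) {
  out <- NULL
  for (sd in unique(segments$side)) {
    rows <- segments[segments$side == sd, , drop = FALSE]
    rows <- rows[order(rows$mid_frac), , drop = FALSE]
    while (nrow(rows) && rows$curvature[1] < minValue)
      rows <- rows[-1, , drop = FALSE]
    if (nrow(rows)) {
      rows$rank <- paste0(sd, seq_len(nrow(rows)))
      out <- rbind(out, rows)
    }
  }
  if (is.null(out))
    out <- segments[0, , drop = FALSE]
  out
}
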