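# Internal geometry / numeric helpers shared across modules.

# Arc length of a polyline given as an n x 2 matrix.
.arcLength <- function(p) {
  d <- diff(p)
  sum(sqrt(rowSums(d^2)))
}

# Cumulative arc-length parameter (starts at 0).
.cumArc <- function(p) {
  d <- diff(p)
  c(0, cumsum(sqrt(rowSums(d^2))))
}

# Resample a polyline to n points equally spaced in arc length.
.resampleArc <- function(p, n) {
  s <- .cumArc(p)
  # drop duplicated parameter values (coincident vertices)
  keep <- c(TRUE, diff(s) > 0)
  s <- s[keep]; p <- p[keep, , drop = FALSE]
  if (nrow(p) < 2L) stop("polyline degenerate: fewer than 2 distinct points")
  si <- seq(0, s[length(s)], length.out = n)
  cbind(stats::approx(s, p[, 1], xout = si)$y,
        stats::approx(s, p[, 2], xout = si)$y)
}

# Circular (wrap-around) moving average, used for closed outlines.
.movAvgCircular <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  h <- (w - 1L) %/% 2L
  xx <- c(x[(n - h + 1L):n], x, x[1L:h])
  stats::filter(xx, rep(1 / w, w), sides = 2)[(h + 1L):(h + n)]
}

# Open-ended moving average; window shrinks symmetrically at the ends.
.movAvgOpen <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  h <- (w - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    mean(x[lo:hi])
  }, numeric(1))
}

# TRUE if the open polyline p (n x 2) intersects itself.
# Checks all non-adjacent segment pairs; O(n^2), fine for n <= ~200.
.selfIntersects <- function(p) {
  n <- nrow(p) - 1L
  if (n < 3L) return(FALSE)
  x1 <- p[1:n, 1]; y1 <- p[1:n, 2]
  x2 <- p[2:(n + 1L), 1]; y2 <- p[2:(n + 1L), 2]
  for (i in seq_len(n - 2L)) {
    j <- (i + 2L):n
    # orientation tests for segment i against all segments j
    d1 <- (x2[i] - x1[i]) * (y1[j] - y1[i]) - (y2[i] - y1[i]) * (x1[j] - x1[i])
    d2 <- (x2[i] - x1[i]) * (y2[j] - y1[i]) - (y2[i] - y1[i]) * (x2[j] - x1[i])
    d3 <- (x2[j] - x1[j]) * (y1[i] - y1[j]) - (y2[j] - y1[j]) * (x1[i] - x1[j])
    d4 <- (x2[j] - x1[j]) * (y2[i] - y1[j]) - (y2[j] - y1[j]) * (x2[i] - x1[j])
    hit <- (d1 * d2 < 0) & (d3 * d4 < 0)
    if (any(hit, na.rm = TRUE)) return(TRUE)
  }
  FALSE
}

# Arc-length position of the point on polyline p closest to q (projection
# onto the nearest segment for sub-vertex accuracy).
.arcPositionOf <- function(p, q) {
  d2 <- (p[, 1] - q[1])^2 + (p[, 2] - q[2])^2
  i <- which.min(d2)
  s <- .cumArc(p)
  best <- s[i]
  bestD <- d2[i]
  for (j in c(i - 1L, i)) {
    if (j < 1L || j >= nrow(p)) next
    a <- p[j, ]; b <- p[j + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- max(0, min(1, sum((q - a) * ab) / len2))
    proj <- a + t * ab
    dd <- sum((q - proj)^2)
    if (dd < bestD) { bestD <- dd; best <- s[j] + t * sqrt(len2) }
  }
  best
}

# Full-precision number formatting so text round-trips are bit-exact.
.fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

# Angle (degrees, in [0, 180]) between two 2-D vectors.
.vecAngleDeg <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-length vector in angle computation")
  cosang <- sum(a * b) / (na * nb)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}
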