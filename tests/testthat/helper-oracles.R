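# Shared helpers: independent brute-force oracles and small constructors.
# Oracles are deliberately written differently from the package internals.

# Spline13 from a dense polyline.
spline13From <- function(pts) {
  dense <- NemaTrack:::.resampleArc(pts, max(100L, nrow(pts)))
  new("Spline13", markers = NemaTrack:::.resampleArc(dense, 13L),
      dense = dense, lengthPx = NemaTrack:::.arcLength(dense))
}

# Brute-force 8-connected component labeling by queue flood fill.
floodLabel8 <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  cur <- 0L
  for (sx in seq_len(nx)) for (sy in seq_len(ny)) {
    if (mask[sx, sy] == 0L || lab[sx, sy] != 0L) next
    cur <- cur + 1L
    queue <- list(c(sx, sy)); lab[sx, sy] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dx in -1:1) for (dy in -1:1) {
        x <- p[1] + dx; y <- p[2] + dy
        if (x < 1 || x > nx || y < 1 || y > ny) next
        if (mask[x, y] == 1L && lab[x, y] == 0L) {
          lab[x, y] <- cur
          queue[[length(queue) + 1L]] <- c(x, y)
        }
      }
    }
  }
  lab
}

# Brute-force debris filter on top of floodLabel8.
debrisOracle <- function(mask, minArea) {
  lab <- floodLabel8(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (max(lab) > 0) {
    for (cc in seq_len(max(lab))) {
      px <- lab == cc
      if (sum(px) >= minArea) out[px] <- 1L
    }
  }
  out
}

# Direction oracle via angle comparison instead of the dot product.
directionOracle <- function(prev, cur, head) {
  v <- cur - prev; h <- head - cur
  if (all(v == 0)) return("stationary")
  dAng <- atan2(h[2], h[1]) - atan2(v[2], v[1])
  dAng <- atan2(sin(dAng), cos(dAng))  # wrap to (-pi, pi]
  if (abs(dAng) < pi / 2) "forward" else "backward"
}

# Sleep-bout oracle: per-frame walk, independent of the rle-based scanner.
boutOracle <- function(lab, k = 3, wakeK = 3) {
  n <- length(lab)
  bouts <- NULL
  i <- 1L
  isM <- function(j) !is.na(lab[j]) && lab[j] == "motionless"
  while (i + k - 1L <= n) {
    if (all(vapply(i:(i + k - 1L), isM, logical(1)))) {
      runA <- 0L; runM <- 0L; pos <- i; lastMEnd <- NA_integer_
      while (pos <= n) {
        if (is.na(lab[pos])) break
        if (lab[pos] == "active") {
          runA <- runA + 1L; runM <- 0L
          if (runA >= wakeK) break
        } else {
          runM <- runM + 1L; runA <- 0L
          if (runM >= k) lastMEnd <- pos
        }
        pos <- pos + 1L
      }
      bouts <- rbind(bouts, c(start = i, end = lastMEnd))
      i <- pos + 1L
    } else i <- i + 1L
  }
  bouts
}

# Kasa oracle: explicit normal equations.
kasaOracle <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  X <- cbind(2 * x, 2 * y, 1)
  z <- x^2 + y^2
  beta <- solve(t(X) %*% X, t(X) %*% z)
  list(center = c(beta[1], beta[2]),
       r = sqrt(beta[1]^2 + beta[2]^2 + beta[3]))
}

# Motion series straight from labels (10 s frames) for bout tests.
motionFromLabels <- function(lab, frameS = 10) {
  n <- length(lab)
  data.frame(time_s = seq_len(n) * frameS, duration_s = frameS,
             displacement_um = ifelse(is.na(lab), NA_real_,
                                      ifelse(lab == "active", 25, 1)),
             label = lab, stringsAsFactors = FALSE)
}

# BendTrace from an 11 x T angle matrix at sampling rate fs.
bendTraceFrom <- function(angles, fs) {
  new("BendTrace", angles = angles,
      time_s = (seq_len(ncol(angles)) - 1) / fs, fs = fs,
      orientation = "unknown")
}
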