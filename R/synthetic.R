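# Ground-truthed synthetic data: rendered worm frames, crawl recordings,
# sleep actograms and AP trains. Every generator is deterministic per seed
# and emits its ground truth alongside the data.

#' Construct a sinusoidal worm pose
#'
#' The midline is a sinusoid of amplitude `amp` and wavelength `lambda`
#' superimposed on a straight heading, resampled to equal arc length so
#' the true body length is exact. The half-width profile tapers at both
#' ends with the tail sharper than the head (as in the animal), so corner
#' detection has a real asymmetry to find.
#'
#' @param lengthPx worm body length along the midline (px, default 400 --
#'   a ~1 mm adult at 2.5 um/px)
#' @param amp sinusoid amplitude (px); keep `amp/lambda` under ~0.3 for a
#'   self-intersection-free body
#' @param lambda sinusoid wavelength (px)
#' @param phase phase offset (radians)
#' @param headingDeg heading of the body axis (degrees, 0 = +x)
#' @param position length-2 (x, y): image position of the head tip
#' @param centerAt optional length-2 (x, y); when given, the pose is
#'   translated so the midline bounding-box center lands there (overrides
#'   the translation implied by `position`)
#' @param widthPx maximum half-width of the body (px, default 13)
#' @param nDense dense midline sample count (default 400)
#' @return list of class `wormPose`: `dense` (n x 2 midline, head first),
#'   `halfWidth` (n), `lengthPx`, `markers13` (true markers),
#'   `bendAngles` (true signed bend angles at markers 1-11)
#' @export
wormPose <- function(lengthPx = 400, amp = 30, lambda = 300, phase = 0,
                     headingDeg = 0, position = c(120, 240), centerAt = NULL,
                     widthPx = 13, nDense = 400) {
  # build on a fine grid then arc-length-normalize to the requested length
  tt <- seq(0, 1, length.out = 4 * nDense)
  raw <- cbind(tt * lengthPx, amp * sin(2 * pi * tt * lengthPx / lambda + phase))
  raw <- .resampleArc(raw, 4 * nDense)
  s <- .cumArc(raw)
  raw <- raw * (lengthPx / s[length(s)])
  dense <- .resampleArc(raw, nDense)
  th <- headingDeg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  dense <- sweep(dense %*% t(R), 2, position, `+`)
  if (!is.null(centerAt)) {
    bbox <- (apply(dense, 2, max) + apply(dense, 2, min)) / 2
    dense <- sweep(dense, 2, centerAt - bbox, `+`)
  }
  if (.selfIntersects(dense)) stop("pose self-intersects; reduce amp/lambda")
  # half-width profile: beta-like taper, blunter head (exponent .30) than
  # tail (.80); normalized so the maximum equals widthPx
  sfrac <- seq(0, 1, length.out = nDense)
  prof <- sfrac^0.30 * (1 - sfrac)^0.80
  halfW <- widthPx * prof / max(prof)
  # conical caps: the half-width never exceeds the arc distance to the
  # nearer tip, so the painted body ends exactly at the midline endpoints
  # (the head cone is wider than the tail cone, preserving the asymmetry)
  halfW <- pmin(halfW, 0.95 * sfrac * lengthPx, 0.95 * (1 - sfrac) * lengthPx)
  mk <- .resampleArc(dense, 13L)
  bends <- vapply(1:11, function(i) bendAngle(mk, i, "unknown"), numeric(1))
  structure(list(dense = dense, halfWidth = halfW, lengthPx = lengthPx,
                 markers13 = mk, bendAngles = bends),
            class = "wormPose")
}

#' Render a worm pose into a grayscale frame
#'
#' Paints the body as the union of disks of radius `halfWidth(s)` along
#' the dense midline — a dark body (default intensity 40) on a bright
#' background (200) with optional Gaussian noise. Deterministic per seed.
#'
#' @param pose a `wormPose` from [wormPose()]
#' @param imgSize c(width, height) in pixels (default 640 x 480)
#' @param bodyIntensity,bgIntensity body and background gray levels
#'   (0-255)
#' @param noiseSd Gaussian noise standard deviation (intensity levels)
#' @param seed RNG seed for the noise (default 1)
#' @return list with `image` (0-255 matrix indexed `[x, y]`), `mask`
#'   (ground-truth 0/1 body mask), `truth` (the pose)
#' @export
renderWorm <- function(pose, imgSize = c(640, 480), bodyIntensity = 40,
                       bgIntensity = 200, noiseSd = 0, seed = 1) {
  nx <- imgSize[1]; ny <- imgSize[2]
  margin <- max(pose$halfWidth) + 1
  if (min(pose$dense[, 1]) < margin || max(pose$dense[, 1]) > nx - margin ||
      min(pose$dense[, 2]) < margin || max(pose$dense[, 2]) > ny - margin)
    stop("pose extends outside the canvas; recenter it or enlarge imgSize")
  # sample the midline finely enough that the union of disks is a tube
  n <- max(2L * nrow(pose$dense), ceiling(pose$lengthPx / 0.5))
  mid <- .resampleArc(pose$dense, n)
  hw <- stats::approx(seq(0, 1, length.out = length(pose$halfWidth)),
                      pose$halfWidth, xout = seq(0, 1, length.out = n))$y
  mask <- matrix(0L, nx, ny)
  for (i in seq_len(n)) {
    r <- hw[i]
    cx <- mid[i, 1]; cy <- mid[i, 2]
    if (r < 0.5) {  # sub-pixel taper: keep at least the center pixel
      xi <- round(cx); yi <- round(cy)
      if (xi >= 1 && xi <= nx && yi >= 1 && yi <= ny) mask[xi, yi] <- 1L
      next
    }
    x0 <- max(1L, floor(cx - r)); x1 <- min(nx, ceiling(cx + r))
    y0 <- max(1L, floor(cy - r)); y1 <- min(ny, ceiling(cy + r))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    d2 <- outer((xs - cx)^2, (ys - cy)^2, `+`)
    sub <- mask[xs, ys]
    sub[d2 <= r^2] <- 1L
    mask[xs, ys] <- sub
  }
  img <- matrix(bgIntensity, nx, ny)
  img[mask == 1L] <- bodyIntensity
  if (noiseSd > 0) {
    set.seed(seed)
    img <- img + matrix(stats::rnorm(nx * ny, 0, noiseSd), nx, ny)
    img <- pmin(pmax(img, 0), 255)
  }
  list(image = img, mask = mask, truth = pose)
}

#' Simulate a crawl recording with stage recentering
#'
#' The worm translates along its heading at constant speed while the
#' undulation phase advances at `undulationHz`; a simulated motorized
#' stage recenters the field of view at 1 s intervals so the worm stays
#' in frame. Emits a complete recording bundle (frame images, stage file,
#' time file) when `dir` is given and `render = TRUE`; always returns the
#' ground truth, including the true pixel-coordinate marker track and the
#' true world trajectory.
#'
#' @param durationS recording length (s, default 10)
#' @param fps frame rate (default 3; one of 1, 3, 5, 15)
#' @param speedUmS crawl speed (um/s, default 150 -- a typical wild-type
#'   crawl)
#' @param undulationHz undulation frequency (Hz, default 0.4)
#' @param ampPx,lambdaPx sinusoid amplitude and wavelength (px)
#' @param umPerPx calibration (default 2.5)
#' @param headingDeg crawl heading (degrees)
#' @param reversed `TRUE` simulates backward crawling (head opposed to the
#'   velocity)
#' @param stageRecenter recenter the stage every second (default `TRUE`)
#' @param render write frame images (slow); otherwise only logs + truth
#' @param dir recording folder to create (required when `render = TRUE`)
#' @param name recording name (default `"wt1"`); an `R_`/`L_` prefix is
#'   honored in the written folder name
#' @param noiseSd image noise passed to [renderWorm()]
#' @param seed RNG seed
#' @return list: `splineTrack` (true markers, pixel coords, as a
#'   [SplineTrack-class]), `rec` (a [WormRecording-class] when files were
#'   written, else `NULL`), `truth` (worldMarkers x/y, worldCentroid,
#'   lengthUm, bendAngles 11 x T, time_s, stage data.frame, speedUmS,
#'   undulationHz)
#' @export
simulateCrawl <- function(durationS = 10, fps = 3, speedUmS = 150,
                          undulationHz = 0.4, ampPx = 30, lambdaPx = 300,
                          umPerPx = 2.5, headingDeg = 0, reversed = FALSE,
                          stageRecenter = TRUE, render = FALSE, dir = NULL,
                          name = "wt1", noiseSd = 0, seed = 1) {
  nFrame <- round(durationS * fps)
  time_s <- (seq_len(nFrame) - 1) / fps
  # canvas sized so the worm stays in frame between 1 s recenterings:
  # half body + undulation amplitude + 1 s of travel + body width + slack
  halfExtent <- 200 + ampPx + (speedUmS / umPerPx) * 1.2 + 13 + 10
  side <- max(640, 2 * ceiling(halfExtent))
  imgSize <- c(side, max(480, side))
  center <- imgSize / 2
  th <- headingDeg * pi / 180
  u <- c(cos(th), sin(th))           # world heading (unit)
  speedPx <- speedUmS / umPerPx
  # head world position over time; body extends backward along -u
  startWorld <- c(0, 0)
  stageT <- numeric(0); stageX <- numeric(0); stageY <- numeric(0)
  mx <- matrix(NA_real_, nFrame, 13L); my <- matrix(NA_real_, nFrame, 13L)
  wx <- matrix(NA_real_, nFrame, 13L); wy <- matrix(NA_real_, nFrame, 13L)
  bends <- matrix(NA_real_, 11L, nFrame)
  lengthUm <- numeric(nFrame)
  stagePos <- c(0, 0)
  poses <- vector("list", nFrame)
  for (f in seq_len(nFrame)) {
    t <- time_s[f]
    # the head leads; the body trails 400 px behind it along -u. For a
    # reversal the body stays oriented the same way but progress reverses,
    # so the head vector opposes the velocity.
    progressPx <- speedPx * t * if (reversed) -1 else 1
    headWorldPx <- startWorld / umPerPx + u * progressPx
    # stage recenters at 1 s intervals (between image acquisitions)
    if (stageRecenter && (f == 1L || floor(t) > floor(time_s[f - 1]))) {
      midWorldUm <- (headWorldPx - u * 200) * umPerPx
      stagePos <- midWorldUm - center * umPerPx
      stageT <- c(stageT, t - 1e-3)  # move completes just before the frame
      stageX <- c(stageX, stagePos[1]); stageY <- c(stageY, stagePos[2])
    } else if (f == 1L) {
      stageT <- 0; stageX <- 0; stageY <- 0
    }
    phase <- 2 * pi * undulationHz * t
    headPix <- headWorldPx - stagePos / umPerPx
    pose <- wormPose(lengthPx = 400, amp = ampPx, lambda = lambdaPx,
                     phase = phase, headingDeg = headingDeg + 180,
                     position = headPix)
    poses[[f]] <- pose
    mk <- pose$markers13
    mx[f, ] <- mk[, 1]; my[f, ] <- mk[, 2]
    wx[f, ] <- mk[, 1] * umPerPx + stagePos[1]
    wy[f, ] <- mk[, 2] * umPerPx + stagePos[2]
    bends[, f] <- pose$bendAngles
    lengthUm[f] <- pose$lengthPx * umPerPx
  }
  splineTrack <- new("SplineTrack", frame = seq_len(nFrame),
                     status = rep("ok", nFrame),
                     threshold = rep(NA_real_, nFrame),
                     attempts = rep(1L, nFrame), mx = mx, my = my,
                     lengthPx = rep(400, nFrame))
  stage <- data.frame(time_s = stageT, x_um = stageX, y_um = stageY)
  truth <- list(worldX = wx, worldY = wy,
                worldCentroid = cbind(rowMeans(wx), rowMeans(wy)),
                lengthUm = lengthUm, bendAngles = bends, time_s = time_s,
                stage = stage, speedUmS = speedUmS,
                undulationHz = undulationHz, umPerPx = umPerPx, fps = fps,
                imgSize = imgSize)
  orientation <- if (startsWith(name, "R_")) "ventral-right"
                 else if (startsWith(name, "L_")) "ventral-left" else "unknown"
  rec <- new("WormRecording", name = sub("^[RL]_", "", name),
             imageFiles = character(0), stageLog = stage,
             frameTimes = data.frame(frame = seq_len(nFrame), time_s = time_s),
             moveTimes = stageT, orientation = orientation,
             umPerPx = umPerPx, fps = fps, splineFile = NA_character_,
             stageFree = FALSE)
  if (!is.null(dir)) {
    folder <- file.path(dir, name)
    dir.create(folder, recursive = TRUE, showWarnings = FALSE)
    if (render) {
      for (f in seq_len(nFrame)) {
        fr <- renderWorm(poses[[f]], imgSize = imgSize, noiseSd = noiseSd,
                         seed = seed + f)
        EBImage::writeImage(EBImage::Image(fr$image / 255),
                            file.path(folder, sprintf("img%05d.png", f)))
      }
    }
    base <- basename(folder)
    writeStageLog(stage, file.path(folder, paste0(base, ".txt")))
    writeTimeLog(data.frame(frame = seq_len(nFrame), time_s = time_s),
                 stageT, file.path(folder, paste0(base, "_times.txt")))
    if (render)
      rec <- resolveRecording(folder, umPerPx = umPerPx, fps = fps)
  }
  list(splineTrack = splineTrack, rec = rec, truth = truth)
}

#' Simulate a sleep actogram with planted bouts
#'
#' Centroid positions at one frame per `frameS` seconds: active epochs
#' take steps far above the 10 um motionless bound, quiescent (bout)
#' epochs far below it, with isolated single-frame active spikes planted
#' inside bouts at `spikeRate`. Step directions are uniform; the true
#' bout schedule is returned as ground truth.
#'
#' @param spanS recording span (s, default 7200)
#' @param frameS frame interval (s, default 10)
#' @param bouts list of c(start_s, end_s) planted quiescence intervals
#' @param activeStepUm mean active step (um, default 50)
#' @param quietSdUm quiescent step scale (um, default 1.5)
#' @param spikeRate probability of an active spike per in-bout frame
#'   (default 0)
#' @param seed RNG seed
#' @return list: `time_s`, `x_um`, `y_um`, `trueBouts` (2-column matrix),
#'   `spikes` (frame indices of planted spikes)
#' @export
simulateSleepTrace <- function(spanS = 7200, frameS = 10,
                               bouts = list(c(1800, 3600), c(5000, 6200)),
                               activeStepUm = 50, quietSdUm = 1.5,
                               spikeRate = 0, seed = 1) {
  set.seed(seed)
  time_s <- seq(0, spanS, by = frameS)
  n <- length(time_s)
  inBout <- rep(FALSE, n)
  for (b in bouts) inBout <- inBout | (time_s >= b[1] & time_s <= b[2])
  steps <- ifelse(inBout[-1], abs(stats::rnorm(n - 1, 0, quietSdUm)),
                  activeStepUm * (0.6 + stats::runif(n - 1, 0, 0.8)))
  spikes <- integer(0)
  if (spikeRate > 0) {
    # plant spikes well inside bouts so onset/offset detection is unaffected
    interior <- rep(FALSE, n)
    for (b in bouts)
      interior <- interior | (time_s >= b[1] + 3 * frameS &
                              time_s <= b[2] - 3 * frameS)
    cand <- which(interior[-1])
    cand <- cand[cand > 3 & cand < n - 3]
    pick <- cand[stats::runif(length(cand)) < spikeRate]
    # keep spikes isolated so they stay single-frame active events
    pick <- pick[c(TRUE, diff(pick) > 2)]
    steps[pick] <- activeStepUm
    spikes <- pick
  }
  dirA <- stats::runif(n - 1, 0, 2 * pi)
  x <- cumsum(c(0, steps * cos(dirA)))
  y <- cumsum(c(0, steps * sin(dirA)))
  list(time_s = time_s, x_um = x, y_um = y,
       trueBouts = do.call(rbind, bouts), spikes = spikes)
}

#' Simulate an AP train with closed-form ground truth
#'
#' Plants `n` identical AP templates on a flat baseline at 10 kHz.
#' The `"triangle"` template is piecewise linear — rise from `v0` to
#' `vPeak` over `riseMs`, fall back over `decayMs`, then an optional
#' linear dip to `ahpV` — so every metric has an exact closed form. The
#' `"smooth"` template has an exponential take-off `v0 + b(exp(t/tau)-1)`
#' whose dV/dt crosses a criterion c at the analytic voltage
#' `v0 + b(c tau/b - 1)`, followed by a half-cosine decay into a planted
#' AHP.
#'
#' @param n number of APs (default 7)
#' @param template `"triangle"` or `"smooth"`
#' @param intervalMs peak-to-peak interval (ms, default 100)
#' @param baseline baseline potential (mV); defaults to `v0`
#' @param v0 take-off potential (mV, default -40)
#' @param vPeak peak potential (mV, default 20)
#' @param riseMs,decayMs triangle rise/fall times (ms, defaults 5 and 10)
#' @param ahpV planted AHP minimum (mV, `NULL` for none)
#' @param tauMs smooth-template take-off time constant (ms, default 1.5)
#' @param noiseSd Gaussian noise (mV, default 0)
#' @param dt sampling interval (s, default 1e-4)
#' @param seed RNG seed
#' @return list: `trace` (a [VoltageTrace-class]), `truth` (data.frame of
#'   planted peak times/voltages and closed-form metrics)
#' @export
simulateAPTrain <- function(n = 7, template = c("triangle", "smooth"),
                            intervalMs = 100, baseline = NULL, v0 = -40,
                            vPeak = 20, riseMs = 5, decayMs = 10, ahpV = NULL,
                            tauMs = 1.5, noiseSd = 0, dt = 1e-4, seed = 1) {
  template <- match.arg(template)
  if (is.null(baseline)) baseline <- v0
  msN <- function(ms) round(ms / 1000 / dt)
  if (template == "triangle") {
    up <- seq(v0, vPeak, length.out = msN(riseMs) + 1L)
    down <- seq(vPeak, v0, length.out = msN(decayMs) + 1L)[-1]
    tpl <- c(up, down)
    if (!is.null(ahpV)) {
      dip <- c(seq(v0, ahpV, length.out = msN(3) + 1L)[-1],
               seq(ahpV, baseline, length.out = msN(5) + 1L)[-1])
      tpl <- c(tpl, dip)
    }
    peakOff <- msN(riseMs)          # samples from template start to peak
  } else {
    tau <- tauMs / 1000
    tUp <- seq(0, by = dt, length.out = 1 + ceiling(
      tau / dt * log((vPeak - v0) / (0.05 * (vPeak - v0)) + 1)))
    b <- 0.05 * (vPeak - v0)        # initial drive: dV/dt = b/tau at t=0
    upv <- v0 + b * (exp(tUp / tau) - 1)
    upv <- upv[upv <= vPeak]
    upv <- c(upv, vPeak)
    ahp <- if (is.null(ahpV)) baseline - 8 else ahpV
    nd <- msN(12)
    downv <- ahp + (vPeak - ahp) * (1 + cos(pi * seq_len(nd) / nd)) / 2
    rec <- seq(ahp, baseline, length.out = msN(8))[-1]
    tpl <- c(upv, downv, rec)
    peakOff <- length(upv) - 1L
  }
  gap <- msN(intervalMs)
  lead <- msN(30)
  total <- lead + n * gap + length(tpl) + msN(30)
  v <- rep(baseline, total)
  peakIdx <- integer(n)
  for (i in seq_len(n)) {
    s <- lead + (i - 1L) * gap
    v[s:(s + length(tpl) - 1L)] <- tpl
    peakIdx[i] <- s + peakOff
  }
  if (noiseSd > 0) {
    set.seed(seed)
    v <- v + stats::rnorm(total, 0, noiseSd)
  }
  trace <- new("VoltageTrace", v = v, dt = dt,
               meta = list(source = "simulateAPTrain", template = template))
  truth <- data.frame(
    peak_idx = peakIdx, peak_time_s = (peakIdx - 1L) * dt,
    peak_mV = vPeak, v0_mV = v0,
    amplitude_from_v0_mV = vPeak - v0,
    ahp_mV = if (is.null(ahpV)) NA_real_ else ahpV)
  if (template == "smooth") {
    tau <- tauMs / 1000
    b <- 0.05 * (vPeak - v0)
    # dV/dt = (b/tau) exp(t/tau) crosses criterion c (mV/ms) where
    # V = v0 + b (c*1000*tau/b - 1)
    truth$threshold_v_at_10mVms <- v0 + b * (10 * 1000 * tau / b - 1)
  }
  list(trace = trace, truth = truth)
}
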