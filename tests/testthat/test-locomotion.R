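test_that("stage compensation produces no spurious displacement", {
  # worm pixel position shifts +40 px in x while the stage moves -100 um:
  # at 2.5 um/px the world position is unchanged
  mx <- rbind(matrix(seq(100, 220, by = 10), 1), matrix(seq(140, 260, by = 10), 1))
  my <- matrix(200, 2, 13)
  tr <- new("SplineTrack", frame = 1:2, status = c("ok", "ok"),
            threshold = c(120, 120), attempts = c(1L, 1L), mx = mx, my = my,
            lengthPx = c(120, 120))
  rec <- new("WormRecording", name = "wt1", imageFiles = character(0),
             stageLog = data.frame(time_s = c(0, 0.2), x_um = c(0, -100),
                                   y_um = c(0, 0)),
             frameTimes = data.frame(frame = 1:2, time_s = c(0, 1 / 3)),
             moveTimes = 0.2, orientation = "unknown", umPerPx = 2.5,
             fps = 3, splineFile = NA_character_, stageFree = FALSE)
  w <- toWorld(tr, rec)
  expect_equal(centroids(w)[1, ], centroids(w)[2, ])
  # stage-free: world = pixel * umPerPx
  rec@stageFree <- TRUE
  w2 <- toWorld(tr, rec)
  expect_equal(w2@mx, mx * 2.5)
})

test_that("world centroid recovery on a simulated crawl is exact", {
  s <- simulateCrawl(durationS = 10, fps = 3, speedUmS = 150, seed = 4)
  w <- toWorld(s$splineTrack, s$rec)
  err <- sqrt(rowSums((centroids(w) - s$truth$worldCentroid)^2))
  expect_lt(max(err), 2.5)  # one pixel-equivalent
})

test_that("15 FPS tracks decimate to 3 FPS; 1/3/5 FPS pass through", {
  mkTrack <- function(n, fps) new("WorldTrack", time_s = (seq_len(n) - 1) / fps,
                                  mx = matrix(1, n, 13), my = matrix(1, n, 13),
                                  lengthUm = rep(1000, n), umPerPx = 2.5,
                                  fpsNominal = fps,
                                  fpsEffective = if (fps == 15) 3 else fps)
  t15 <- effectiveFrames(mkTrack(900, 15))
  expect_equal(nFrames(t15), 180L)
  expect_equal(t15@fpsEffective, 3)
  expect_equal(t15@time_s[1:3], c(0, 5, 10) / 15)  # frames 1, 6, 11
  t5 <- mkTrack(50, 5)
  expect_identical(effectiveFrames(t5), t5)
  bad <- mkTrack(10, 5); bad@fpsNominal <- 2
  expect_error(effectiveFrames(bad), "resample")
})

test_that("direction classification follows the head-vector projection", {
  expect_equal(classifyDirection(c(0, 0), c(10, 0), c(25, 5)), "forward")
  expect_equal(classifyDirection(c(0, 0), c(10, 0), c(-5, 0)), "backward")
  expect_equal(classifyDirection(c(0, 0), c(0, 0), c(5, 5)), "stationary")
  # zero projection is backward (the strict "otherwise")
  expect_equal(classifyDirection(c(0, 0), c(10, 0), c(10, 7)), "backward")
  set.seed(31)
  for (i in 1:200) {
    prev <- runif(2, -50, 50); cur <- runif(2, -50, 50); head <- runif(2, -50, 50)
    expect_equal(classifyDirection(prev, cur, head),
                 directionOracle(prev, cur, head),
                 label = paste("geometry", i))
  }
})

test_that("movement metrics recover simulated speed and direction", {
  s <- simulateCrawl(durationS = 10, fps = 3, speedUmS = 200, seed = 6)
  w <- toWorld(s$splineTrack, s$rec)
  mm <- movementMetrics(w)
  # truth: path speed of the true centroid over the same frames
  steps <- sqrt(rowSums(diff(s$truth$worldCentroid)^2))
  trueSpeed <- sum(steps) / (max(s$truth$time_s) - min(s$truth$time_s))
  expect_lt(abs(mm$avg_speed_um_s - trueSpeed) / trueSpeed, 0.01)
  expect_equal(mm$forward_time_fraction, 1)
  expect_lte(mm$net_distance_um, mm$total_distance_um)

  sr <- simulateCrawl(durationS = 10, fps = 3, speedUmS = 200, reversed = TRUE,
                      seed = 6)
  mr <- movementMetrics(toWorld(sr$splineTrack, sr$rec))
  expect_equal(mr$backward_time_fraction, 1)
  expect_equal(mr$forward_distance_um, 0)
})

test_that("a closed-loop path has near-zero net distance", {
  n <- 41
  th <- seq(0, 2 * pi, length.out = n)
  mx <- matrix(rep(500 + 300 * cos(th), 13), n, 13)
  my <- matrix(rep(500 + 300 * sin(th), 13), n, 13)
  # give the worm a head offset so direction labels are defined
  mx[, 1] <- mx[, 1] + 40
  w <- new("WorldTrack", time_s = seq(0, 40, length.out = n), mx = mx, my = my,
           lengthUm = rep(1000, n), umPerPx = 2.5, fpsNominal = 1,
           fpsEffective = 1)
  mm <- movementMetrics(w)
  expect_lt(mm$net_distance_um, 1e-6)
  expect_gt(mm$total_distance_um, 1000)
})

test_that("amplitude is the perpendicular extent in the velocity frame", {
  # straight worm aligned with velocity: A ~ 0
  mk <- cbind(seq(0, 1200, length.out = 13), rep(0, 13))
  a <- amplitudeAndLength(mk, c(1, 0), 1200)
  expect_equal(unname(a["A_um"]), 0)
  expect_equal(unname(a["A_over_L"]), 0)
  # sinusoid with markers on the extrema: A = 2a
  lam <- 400 / 1.5  # extrema fall on markers 4, 8, 12 (x = 100, 233.3, 366.7)
  x <- seq(0, 400, length.out = 13)
  y <- 50 * sin(2 * pi * x / lam - pi / 4)
  mkS <- cbind(x, y)
  aS <- amplitudeAndLength(mkS, c(1, 0), 420)
  expect_lt(abs(aS[["A_um"]] - 100) / 100, 0.03)
  # velocity rotated 90 degrees: A becomes the x-extent
  aR <- amplitudeAndLength(mkS, c(0, 1), 420)
  expect_lt(abs(aR[["A_um"]] - 400) / 400, 0.03)
  expect_error(amplitudeAndLength(mkS, c(0, 0), 420), "zero velocity")
})

test_that("travel path is consistent with movement metrics", {
  s <- simulateCrawl(durationS = 12, fps = 3, speedUmS = 150, seed = 8)
  w <- toWorld(s$splineTrack, s$rec)
  tp <- travelPath(w)
  mm <- movementMetrics(w)
  expect_equal(nrow(tp$path), nFrames(w))
  # single bin over the whole recording equals the average speed
  tp1 <- travelPath(w, binSeconds = 1000)
  expect_equal(tp1$speed$speed_um_s[1], mean(tp$speed$speed_um_s))
  # marker-1 path differs from the centroid path but nets out the same
  tpm <- travelPath(w, marker = 1L)
  netC <- sqrt(sum((tp$path[nrow(tp$path), 2:3] - tp$path[1, 2:3])^2))
  netM <- sqrt(sum((tpm$path[nrow(tpm$path), 2:3] - tpm$path[1, 2:3])^2))
  expect_gt(max(abs(tpm$path$y_um - tp$path$y_um)), 1)
  expect_lt(abs(netM - netC) / netC, 0.05)
})

test_that("calibration is the simple ratio with input validation", {
  expect_equal(calibrate(1000, 200), 5)
  expect_equal(calibrate(500, 500), 1)
  expect_error(calibrate(1000, 0), "positive")
  expect_error(calibrate(-5, 10), "positive")
})
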