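test_that("binarize flags degenerate masks and matches the renderer mask", {
  uni <- matrix(100, 50, 50)
  m <- binarize(uni, 150, "worm-dark")     # all foreground
  expect_false(attr(m, "usable"))
  m2 <- binarize(uni, 30, "worm-dark")     # empty foreground
  expect_false(attr(m2, "usable"))

  p <- wormPose(phase = 0.5, centerAt = c(320, 240))
  r <- renderWorm(p, bodyIntensity = 40, bgIntensity = 200, noiseSd = 0)
  m3 <- binarize(r$image, 120, "worm-dark")
  expect_true(attr(m3, "usable"))
  agree <- mean(m3 == r$mask)
  expect_gte(agree, 0.99)
  # worm-bright polarity is the complement
  m4 <- binarize(255 - r$image, 135, "worm-bright")
  expect_identical(unclass(m4)[, ], unclass(m3)[, ])
})

test_that("debris filter removes components below the area cutoff", {
  # components of 2999 and 3001 pixels around the boundary
  mask <- matrix(0L, 200, 100)
  mask[1:100, 1:30] <- 1L          # 3000 px block
  mask[100, 30] <- 0L              # -> 2999
  mask[101:200, 50:79] <- 1L       # 3000 px block
  mask[101, 80] <- 1L              # -> 3001 (8-connected extra pixel)
  out <- removeDebris(mask, 3000)
  expect_equal(sum(out[1:100, 1:30]), 0)
  expect_equal(sum(out[101:200, 50:80]), 3001)
})

test_that("debris filter equals the brute-force component-area oracle", {
  set.seed(11)
  for (i in 1:200) {
    mask <- matrix(0L, 40, 40)
    nblob <- sample(1:4, 1)
    for (b in seq_len(nblob)) {
      cx <- sample(5:35, 1); cy <- sample(5:35, 1); r <- sample(2:6, 1)
      for (x in max(1, cx - r):min(40, cx + r))
        for (y in max(1, cy - r):min(40, cy + r))
          if ((x - cx)^2 + (y - cy)^2 <= r^2) mask[x, y] <- 1L
    }
    minArea <- sample(c(10, 40, 80), 1)
    got <- removeDebris(mask, minArea)
    expect_identical(unclass(got)[, ], debrisOracle(mask, minArea),
                     label = paste("random mask", i))
  }
})

test_that("outline of a disk has the analytic perimeter", {
  mask <- matrix(0L, 140, 140)
  for (x in 1:140) for (y in 1:140)
    if ((x - 70)^2 + (y - 70)^2 <= 50^2) mask[x, y] <- 1L
  o <- extractOutline(mask)
  expect_lt(abs(o$perimeter - 2 * pi * 50) / (2 * pi * 50), 0.03)
  expect_gte(nrow(o$xy), 40L)
})

test_that("outline encloses the rendered body", {
  p <- wormPose(phase = 1.2, centerAt = c(320, 240))
  r <- renderWorm(p, noiseSd = 0)
  mask <- removeDebris(binarize(r$image, 120))
  o <- extractOutline(mask)
  # polygon area (shoelace) should be close to the mask area
  xy <- o$xy
  area <- abs(sum(xy[, 1] * c(xy[-1, 2], xy[1, 2]) -
                  c(xy[-1, 1], xy[1, 1]) * xy[, 2])) / 2
  expect_gte(area / sum(r$mask), 0.95)
})

test_that("head and tail are found by corner sharpness", {
  set.seed(5)
  for (i in 1:10) {
    p <- wormPose(amp = runif(1, 10, 40), lambda = runif(1, 260, 400),
                  phase = runif(1, 0, 2 * pi), headingDeg = runif(1, 0, 360),
                  centerAt = c(320, 240))
    r <- renderWorm(p, noiseSd = 5, seed = i)
    mask <- removeDebris(binarize(r$image, 120))
    o <- extractOutline(mask)
    ht <- detectHeadTail(o)  # unseeded: sharpness ranking alone
    L <- p$lengthPx
    # tail within 5% of body length of the true tail tip
    expect_lt(sqrt(sum((ht$tail - p$markers13[13, ])^2)), 0.05 * L)
    expect_lt(sqrt(sum((ht$head - p$markers13[1, ])^2)), 0.05 * L)
    expect_false(ht$confirmed)
    # with a previous head position the assignment is confirmed
    ht2 <- detectHeadTail(o, prevHead = p$markers13[1, ] + c(3, -2))
    expect_true(ht2$confirmed)
    expect_lt(sqrt(sum((ht2$head - p$markers13[1, ])^2)), 0.05 * L)
  }
})

test_that("a symmetric silhouette raises an ambiguity error", {
  mask <- matrix(0L, 300, 200)
  for (x in 1:300) for (y in 1:200)
    if (((x - 150) / 120)^2 + ((y - 100) / 30)^2 <= 1) mask[x, y] <- 1L
  o <- extractOutline(mask)
  expect_error(detectHeadTail(o), "ambiguity")
})

test_that("midline recovery is accurate on rendered poses", {
  set.seed(21)
  for (i in 1:10) {
    p <- wormPose(amp = runif(1, 10, 45), lambda = runif(1, 250, 400),
                  phase = runif(1, 0, 2 * pi), headingDeg = runif(1, 0, 360),
                  centerAt = c(320, 240))
    r <- renderWorm(p, noiseSd = 5, seed = i)
    res <- fitFrame(r$image, list(threshold = 120,
                                  headSeed = p$markers13[1, ]))
    expect_true(res$ok)
    sp <- res$spline
    expect_equal(nrow(markers(sp)), 13L)
    err <- sqrt(rowSums((markers(sp) - p$markers13)^2))
    expect_lt(max(err), 5)
    expect_lt(abs(sp@lengthPx - p$lengthPx) / p$lengthPx, 0.03)
  }
})

test_that("straight worms give collinear markers and accurate length", {
  p <- wormPose(amp = 0, centerAt = c(320, 240))
  r <- renderWorm(p, noiseSd = 0)
  res <- fitFrame(r$image, list(threshold = 120, headSeed = p$markers13[1, ]))
  expect_true(res$ok)
  mk <- markers(res$spline)
  expect_lt(abs(res$spline@lengthPx - 400) / 400, 0.02)
  # markers collinear within ~1 px of the best-fit line
  fit <- stats::lm(mk[, 2] ~ mk[, 1])
  expect_lt(max(abs(stats::resid(fit))), 1)
})

test_that("omega postures signal fit failure", {
  th <- seq(0, 1.4 * 2 * pi, length.out = 400)
  dense <- cbind(320 + 70 * cos(th), 240 + 70 * sin(th))
  sfrac <- seq(0, 1, length.out = 400)
  prof <- sfrac^0.3 * (1 - sfrac)^0.8
  pose <- structure(list(dense = dense, halfWidth = 13 * prof / max(prof),
                         lengthPx = NemaTrack:::.arcLength(dense),
                         markers13 = NemaTrack:::.resampleArc(dense, 13)),
                    class = "wormPose")
  r <- renderWorm(pose)
  res <- fitFrame(r$image, list(threshold = 120, headSeed = dense[1, ]))
  expect_false(res$ok)
  expect_match(res$error, "omega")
})

test_that("threshold retry explores both directions and caps at 10 retries", {
  p <- wormPose(phase = 0.4, centerAt = c(320, 240))
  r <- renderWorm(p, bodyIntensity = 40, bgIntensity = 200, noiseSd = 0)
  # initial threshold below the body intensity: the alternating schedule
  # (+step, -step, +2 step, ...) reaches the working level at attempt 2
  res <- fitFrame(r$image, list(threshold = 40, step = 5))
  expect_true(res$ok)
  expect_equal(res$attempts, 2L)
  # a level two steps up costs two more attempts (the -step probe between)
  res4 <- fitFrame(r$image, list(threshold = 35, step = 5))
  expect_true(res4$ok)
  expect_equal(res4$attempts, 4L)
  # pure noise frame: all 11 thresholds tried, then failure
  set.seed(9)
  noise <- matrix(runif(200 * 200, 0, 255), 200, 200)
  res2 <- fitFrame(noise, list(threshold = 128, step = 5))
  expect_false(res2$ok)
  expect_equal(res2$attempts, 11L)
})

test_that("head identity never flips across a rendered crawl", {
  d <- withr::local_tempdir()
  s <- simulateCrawl(durationS = 4, fps = 15, speedUmS = 100,
                     undulationHz = 0.5, render = TRUE, dir = d,
                     name = "wt1", noiseSd = 5, seed = 3)
  rec <- resolveRecording(file.path(d, "wt1"), umPerPx = 2.5)
  seed1 <- c(s$splineTrack@mx[1, 1], s$splineTrack@my[1, 1])
  tr <- fitRecording(rec, list(threshold = 120, headSeed = seed1))
  expect_true(all(fitStatus(tr) == "ok"))
  for (f in seq_len(nFrames(tr))) {
    est1 <- c(tr@mx[f, 1], tr@my[f, 1])
    trueHead <- c(s$splineTrack@mx[f, 1], s$splineTrack@my[f, 1])
    trueTail <- c(s$splineTrack@mx[f, 13], s$splineTrack@my[f, 13])
    expect_lt(sum((est1 - trueHead)^2), sum((est1 - trueTail)^2))
  }
})

test_that("marker override replaces a frame and revalidates", {
  s <- simulateCrawl(durationS = 2, fps = 3)
  tr <- s$splineTrack
  mk <- cbind(seq(10, 130, by = 10), rep(50, 13))
  tr2 <- setMarkers(tr, 2L, mk)
  expect_equal(tr2@mx[2, ], mk[, 1])
  expect_equal(fitStatus(tr2)[2], "ok")
})
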