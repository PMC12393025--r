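test_that("CSV traces load with a uniform timebase", {
  d <- withr::local_tempdir()
  f <- file.path(d, "trace.csv")
  n <- 50000
  write.csv(data.frame(time_s = (seq_len(n) - 1) * 1e-4,
                       voltage_mV = rep(-60, n)), f, row.names = FALSE)
  tr <- readVoltageTrace(f)
  expect_s4_class(tr, "VoltageTrace")
  expect_equal(tr@dt, 1e-4)
  expect_equal(length(tr@v), n)
  # jittered timestamps are rejected
  set.seed(3)
  f2 <- file.path(d, "jitter.csv")
  write.csv(data.frame(time_s = cumsum(runif(100, 0.5e-4, 1.5e-4)),
                       voltage_mV = rep(-60, 100)), f2, row.names = FALSE)
  expect_error(readVoltageTrace(f2), "nonuniform")
  expect_error(readVoltageTrace(file.path(d, "x.abf")), "ABF")
})

test_that("AP detection finds planted peaks and honors the refractory gap", {
  s <- simulateAPTrain(n = 7, template = "triangle", intervalMs = 100,
                       noiseSd = 0.5, seed = 5)
  pk <- detectAPs(s$trace)
  expect_equal(length(pk), 7L)
  expect_lte(max(abs(pk - s$truth$peak_idx)), 1)
  # flat trace: nothing
  flat <- new("VoltageTrace", v = rep(-60, 5000), dt = 1e-4, meta = list())
  expect_length(detectAPs(flat), 0L)
  # two peaks 2 ms apart with a 5 ms refractory gap: one survives
  v <- rep(-60, 3000)
  v[1000:1010] <- seq(-60, 20, length.out = 11)
  v[1010:1020] <- seq(20, -60, length.out = 11)
  v[1030:1040] <- seq(-60, 15, length.out = 11)
  v[1040:1050] <- seq(15, -60, length.out = 11)
  two <- new("VoltageTrace", v = v, dt = 1e-4, meta = list())
  expect_length(detectAPs(two, refractoryMs = 5), 1L)
  expect_length(detectAPs(two, refractoryMs = 1), 2L)
})

test_that("fixed-lead threshold reads the voltage at the lead point", {
  s <- simulateAPTrain(n = 3, template = "triangle")
  pk <- detectAPs(s$trace)
  # linear rise -40 -> +20 over 5 ms: at 2 ms before the peak, V = -4
  th <- thresholdFixedLead(s$trace, pk[1], leadMs = 2)
  expect_equal(th$v_mV, -4)
  expect_equal(pk[1] - th$idx, 20L)  # 2 ms at 10 kHz
  # the same lead applies to every AP of the train
  thAll <- vapply(pk, function(p)
    thresholdFixedLead(s$trace, p, leadMs = 2)$v_mV, numeric(1))
  expect_lt(max(abs(thAll - thAll[1])), 0.5)
  expect_warning(thresholdFixedLead(s$trace, pk[1], leadMs = 0), "degenerates")
  expect_error(thresholdFixedLead(s$trace, 5, leadMs = 50), "before the start")
  expect_error(thresholdFixedLead(s$trace, pk[1]), "required")
})

test_that("inflection threshold finds the dV/dt crossing", {
  s <- simulateAPTrain(n = 5, template = "smooth", intervalMs = 120)
  pk <- detectAPs(s$trace)
  for (p in pk) {
    th <- thresholdInflection(s$trace, p, dvdtCriterion = 10)
    expect_lt(abs(th$v_mV - s$truth$threshold_v_at_10mVms[1]), 2)
  }
  # ramp-only depolarization below the criterion: no-inflection signal
  ramp <- new("VoltageTrace",
              v = c(rep(-60, 500), seq(-60, -20, by = 5e-4), rep(-20, 200)),
              dt = 1e-4, meta = list())  # 5 mV/ms max
  peakIdx <- which.max(ramp@v)
  expect_null(thresholdInflection(ramp, peakIdx, dvdtCriterion = 10))
  # threshold voltage rises monotonically with the criterion
  th10 <- thresholdInflection(s$trace, pk[1], dvdtCriterion = 10)
  th20 <- thresholdInflection(s$trace, pk[1], dvdtCriterion = 20)
  expect_gte(th20$v_mV, th10$v_mV)
})

test_that("RMP modes follow their window definitions", {
  # constant -60 before the reference: both modes give -60
  flat <- new("VoltageTrace", v = rep(-60, 5000), dt = 1e-4, meta = list())
  expect_equal(restingPotential(flat, 3000, "fixed-lead"), -60)
  expect_equal(restingPotential(flat, 3000, "inflection"), -60)
  # linear ramp of slope s mV/ms ending at ref: mean = V(ref) - s * 10 ms
  dt <- 1e-4
  slope <- 0.8  # mV/ms
  v <- -70 + slope * (seq_len(5000) * dt * 1000)
  tr <- new("VoltageTrace", v = v, dt = dt, meta = list())
  ref <- 4000
  got <- restingPotential(tr, ref, "fixed-lead", windowMs = 20)
  # window holds the 200 samples before ref; its mean sits 10.05 ms back
  exp_ <- mean(v[(ref - 200):(ref - 1)])
  expect_equal(got, exp_)
  expect_lt(abs(got - (v[ref] - slope * 10)), slope * 0.2)
  # V-shaped dip inside the window: inflection mode finds it
  v2 <- rep(-60, 5000)
  v2[3800:3830] <- -60 - 10 * (1 - abs(seq(-1, 1, length.out = 31)))
  tr2 <- new("VoltageTrace", v = v2, dt = dt, meta = list())
  rf <- restingPotential(tr2, 3900, "fixed-lead")
  ri <- restingPotential(tr2, 3900, "inflection")
  expect_lt(ri, rf)
  # brute force over all 3 ms sub-windows of the 20 ms window
  seg <- v2[(3900 - 200):(3900 - 1)]
  sub <- vapply(seq_len(200 - 30 + 1), function(i) mean(seg[i:(i + 29)]),
                numeric(1))
  expect_equal(ri, min(sub))
  expect_error(restingPotential(tr2, 100, "fixed-lead"), "manually")
})

test_that("AP metrics match the piecewise-linear closed form", {
  s <- simulateAPTrain(n = 3, template = "triangle", intervalMs = 100,
                       ahpV = -68)
  pk <- detectAPs(s$trace)
  th <- thresholdFixedLead(s$trace, pk[1], leadMs = 2)
  m <- apMetrics(s$trace, pk[1], th, rmp = -40, nextLimitIdx = pk[2])
  expect_equal(m$amplitude_mV, 24)
  expect_equal(m$apd50_ms, 3)
  expect_equal(m$rise_time_ms, 2)
  expect_equal(m$decay_time_ms, 4)
  expect_equal(m$ahp_mV, -68, tolerance = 0.5 / 68)
  # plateau that never recrosses threshold: decay and AHP unavailable
  v <- c(rep(-40, 500), seq(-40, 20, length.out = 51), rep(10, 2000))
  plat <- new("VoltageTrace", v = v, dt = 1e-4, meta = list())
  pkP <- which.max(v)
  thP <- thresholdFixedLead(plat, pkP, leadMs = 2)
  mP <- apMetrics(plat, pkP, thP, rmp = -40)
  expect_true(is.na(mP$decay_time_ms))
  expect_true(is.na(mP$ahp_mV))
})

test_that("phase plot slopes match analytic derivatives", {
  s <- simulateAPTrain(n = 1, template = "triangle")
  pk <- detectAPs(s$trace)
  pp <- phasePlot(s$trace, pk[1] - 60, pk[1] + 120)
  expect_equal(pp$max_slope_mV_ms, 12)  # 60 mV / 5 ms
  expect_equal(pp$min_slope_mV_ms, -6)  # -60 mV / 10 ms
  # sinusoid: max slope = 2 pi f A
  dt <- 1e-4; f <- 20; A <- 30
  tt <- seq(0, 0.5, by = dt)
  sine <- new("VoltageTrace", v = A * sin(2 * pi * f * tt), dt = dt,
              meta = list())
  ppS <- phasePlot(sine)
  expect_lt(abs(ppS$max_slope_mV_ms - 2 * pi * f * A / 1000) /
            (2 * pi * f * A / 1000), 0.02)
  # slope extremum sits between threshold and peak on smooth APs
  s2 <- simulateAPTrain(n = 3, template = "smooth")
  pk2 <- detectAPs(s2$trace)
  for (p in pk2) {
    th <- thresholdInflection(s2$trace, p)
    pp2 <- phasePlot(s2$trace, th$idx, p)
    vAtMax <- pp2$curve$v_mV[which.max(pp2$curve$dvdt_mV_ms)]
    expect_gte(vAtMax, th$v_mV)
    expect_lte(vAtMax, s2$trace@v[p])
  }
})

test_that("averaged AP reproduces the template and obeys the noise law", {
  s <- simulateAPTrain(n = 7, template = "triangle")
  pk <- detectAPs(s$trace)
  av <- averageAP(s$trace, pk, 10, 30)
  expect_equal(av$n, 7L)
  one <- averageAP(s$trace, pk[1], 10, 30)
  expect_lt(max(abs(av$v_mV - one$v_mV)), 1e-9)
  # noisy templates: pointwise error shrinks as 3 sigma / sqrt(n)
  sN <- simulateAPTrain(n = 50, template = "triangle", intervalMs = 60,
                        noiseSd = 2, seed = 11)
  # align on the planted peaks: detection jitter on a noisy sharp peak is a
  # property of the detector, not of the averaging law under test
  avN <- averageAP(sN$trace, sN$truth$peak_idx, 5, 20)
  resid <- abs(avN$v_mV - one$v_mV[51:301])
  # pointwise 3 sigma / sqrt(n) law: nearly all points inside, none far out
  expect_gte(mean(resid < 3 * 2 / sqrt(avN$n)), 0.98)
  expect_lt(max(resid), 5 * 2 / sqrt(avN$n))
  expect_error(averageAP(s$trace, integer(0)), "no peaks")
})

test_that("voltage offsets shift potentials but not durations", {
  s <- simulateAPTrain(n = 3, template = "triangle", ahpV = -68)
  pk <- detectAPs(s$trace)
  sh <- new("VoltageTrace", v = s$trace@v + 7.5, dt = s$trace@dt, meta = list())
  th1 <- thresholdFixedLead(s$trace, pk[1], 2)
  th2 <- thresholdFixedLead(sh, pk[1], 2)
  m1 <- apMetrics(s$trace, pk[1], th1, rmp = -40, nextLimitIdx = pk[2])
  m2 <- apMetrics(sh, pk[1], th2, rmp = -32.5, nextLimitIdx = pk[2])
  expect_equal(m2$threshold_mV, m1$threshold_mV + 7.5)
  expect_equal(m2$ahp_mV, m1$ahp_mV + 7.5)
  expect_equal(m2$amplitude_mV, m1$amplitude_mV)
  expect_equal(m2$apd50_ms, m1$apd50_ms)
  expect_equal(m2$decay_time_ms, m1$decay_time_ms)
})

test_that("whole-trace AP tables are produced per sweep", {
  s <- simulateAPTrain(n = 5, template = "triangle", ahpV = -68, noiseSd = 0)
  tab <- analyzeAPs(s$trace, "fixed-lead", leadMs = 2)
  expect_equal(nrow(tab), 5L)
  expect_true(all(tab$amplitude_mV == 24))
  s2 <- simulateAPTrain(n = 4, template = "smooth")
  tab2 <- analyzeAPs(s2$trace, "inflection")
  expect_equal(nrow(tab2), 4L)
  expect_true(all(tab2$method == "inflection"))
})
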