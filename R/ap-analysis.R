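# Action-potential detection and feature extraction from current-clamp
# voltage traces (nominal 10 kHz sampling).

#' Load a current-clamp voltage trace
#'
#' Reads a two-column CSV (`time_s`, `voltage_mV`, one header line) into a
#' [VoltageTrace-class]. The timebase must be uniform (relative jitter
#' above 1e-4 of the sampling interval is an error). pClamp ABF files are
#' a binary acquisition format outside this package's scope: export the
#' sweep as text/CSV first.
#'
#' @param path CSV file path
#' @return a [VoltageTrace-class]
#' @export
readVoltageTrace <- function(path) {
  if (grepl("\\.abf$", path, ignore.case = TRUE))
    stop("ABF is a binary acquisition format not read by this package; ",
         "export the sweep to CSV (time_s, voltage_mV) first")
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("expected two columns: time_s, voltage_mV")
  tt <- df[[1]]; v <- df[[2]]
  if (length(tt) < 2L) stop("trace needs at least 2 samples")
  dts <- diff(tt)
  dt <- stats::median(dts)
  if (dt <= 0 || any(abs(dts - dt) > 1e-4 * dt))
    stop("nonuniform timebase in ", path,
         "; resample to a constant interval first")
  new("VoltageTrace", v = as.numeric(v), dt = dt,
      meta = list(source = path, sweep = 1L, channel = names(df)[2]))
}

#' Detect action-potential peaks
#'
#' Local maxima above `minPeakV` with topographic prominence of at least
#' `minProminence`, separated by at least the refractory gap (closer peaks
#' keep the larger one).
#'
#' @param trace a [VoltageTrace-class]
#' @param minProminence minimum peak prominence (mV, default 20)
#' @param minPeakV minimum absolute peak voltage (mV, default -20)
#' @param refractoryMs minimum separation between reported peaks (ms,
#'   default 5)
#' @return integer vector of peak sample indices (possibly empty)
#' @export
detectAPs <- function(trace, minProminence = 20, minPeakV = -20,
                      refractoryMs = 5) {
  v <- trace@v
  n <- length(v)
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  cand <- cand[v[cand] >= minPeakV]
  if (!length(cand)) return(integer(0))
  # topographic prominence: lowest point to the nearest higher ground
  prom <- vapply(cand, function(i) {
    left <- which(v[1:i] > v[i])
    lmin <- if (length(left)) min(v[max(left):i]) else min(v[1:i])
    right <- which(v[i:n] > v[i])
    rmin <- if (length(right)) min(v[i:(i + min(right) - 1L)]) else min(v[i:n])
    v[i] - max(lmin, rmin)
  }, numeric(1))
  cand <- cand[prom >= minProminence]
  if (length(cand) < 2L) return(cand)
  gap <- round(refractoryMs / 1000 / trace@dt)
  keep <- order(v[cand], decreasing = TRUE)
  chosen <- integer(0)
  for (i in keep)
    if (!length(chosen) || all(abs(cand[i] - chosen) >= gap))
      chosen <- c(chosen, cand[i])
  sort(chosen)
}

#' AP threshold at a fixed user-defined lead before the peak
#'
#' For APs without a preupstroke inflection point, the threshold is the
#' membrane potential a fixed, user-defined time before the AP peak; the
#' same lead is applied to every AP of an analysis so parameters are
#' standardized across recordings. `leadMs` has no default on purpose.
#'
#' @param trace a [VoltageTrace-class]
#' @param peakIdx peak sample index
#' @param leadMs lead time before the peak (ms); required
#' @return list with `idx`, `time_s`, `v_mV`, `method = "fixed-lead"`
#' @export
thresholdFixedLead <- function(trace, peakIdx, leadMs) {
  if (missing(leadMs)) stop("leadMs is required (user-defined lead)")
  if (leadMs == 0) warning("leadMs = 0: threshold degenerates to the peak")
  idx <- peakIdx - round(leadMs / 1000 / trace@dt)
  if (idx < 1L) stop("lead time extends before the start of the trace")
  list(idx = idx, time_s = (idx - 1L) * trace@dt, v_mV = trace@v[idx],
       method = "fixed-lead")
}

# Smoothed derivative in mV/ms: central differences + 3-sample moving mean.
.dvdt <- function(v, dt) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt * 1000)
  d[1] <- d[2]; d[n] <- d[n - 1]
  stats::filter(d, rep(1 / 3, 3), sides = 2) -> sm
  sm[1] <- d[1]; sm[n] <- d[n]
  as.numeric(sm)
}

#' Automatic AP threshold at the preupstroke inflection
#'
#' For APs with a clear preupstroke inflection, the threshold is the last
#' sample before the peak at which the smoothed dV/dt rises through
#' `dvdtCriterion` and stays above it until the peak. When the criterion is
#' never reached in the search window the AP is flagged non-inflected
#' (return value `NULL`) and the fixed-lead method should be used instead.
#'
#' @param trace a [VoltageTrace-class]
#' @param peakIdx peak sample index
#' @param dvdtCriterion threshold on dV/dt (mV/ms, default 10)
#' @param searchMs pre-peak search window (ms, default 20)
#' @return list with `idx`, `time_s`, `v_mV`, `method = "inflection"`, or
#'   `NULL` when no inflection qualifies
#' @export
thresholdInflection <- function(trace, peakIdx, dvdtCriterion = 10,
                                searchMs = 20) {
  w <- round(searchMs / 1000 / trace@dt)
  lo <- max(1L, peakIdx - w)
  if (peakIdx - w < 1L)
    warning("search window truncated by the start of the trace")
  d <- .dvdt(trace@v, trace@dt)
  pre <- lo:(peakIdx - 1L)
  if (!length(pre) || max(d[pre]) < dvdtCriterion) return(NULL)
  # walk back from the peak through the final suprathreshold stretch
  i <- peakIdx - 1L
  while (i > lo && d[i] >= dvdtCriterion) i <- i - 1L
  idx <- if (d[i] >= dvdtCriterion) i else i + 1L
  list(idx = idx, time_s = (idx - 1L) * trace@dt, v_mV = trace@v[idx],
       method = "inflection")
}

#' Resting membrane potential before a reference point
#'
#' Fixed-lead mode: the mean of the `windowMs` (default 20 ms) of trace
#' preceding the reference point. Inflection mode: the lowest mean over
#' all `subMs` (default 3 ms) sliding sub-windows within that same window
#' — robust to the pre-AP depolarizing ramp of inflected APs.
#'
#' @param trace a [VoltageTrace-class]
#' @param refIdx reference sample index (the user-selected point, or the
#'   detected threshold)
#' @param mode `"fixed-lead"` or `"inflection"`
#' @param windowMs RMP window (ms, default 20)
#' @param subMs sliding sub-window (ms, default 3)
#' @return RMP in mV
#' @export
restingPotential <- function(trace, refIdx, mode = c("fixed-lead", "inflection"),
                             windowMs = 20, subMs = 3) {
  mode <- match.arg(mode)
  w <- round(windowMs / 1000 / trace@dt)
  lo <- refIdx - w
  if (lo < 1L)
    stop("RMP window extends before the trace; measure RMP manually from ",
         "a quiescent segment of the recording")
  seg <- trace@v[lo:(refIdx - 1L)]
  if (mode == "fixed-lead") return(mean(seg))
  m <- round(subMs / 1000 / trace@dt)
  m <- max(1L, min(m, length(seg)))
  means <- as.numeric(stats::filter(seg, rep(1 / m, m), sides = 1))
  min(means[m:length(seg)])
}

# Linear-interpolated crossing time (in samples, 1-based fractional) of
# level `lev` between samples i and i+1.
.crossAt <- function(v, i, lev) {
  i + (lev - v[i]) / (v[i + 1L] - v[i])
}

#' Quantify one action potential
#'
#' Given a peak, its threshold point and the RMP, measures amplitude
#' (peak minus threshold voltage), APD50 (width at half amplitude, with
#' sub-sample linear interpolation), rise time (threshold to peak), decay
#' time (peak back to the threshold voltage), and the afterhyperpolarization
#' as the actual membrane-voltage minimum between repolarization and the
#' next AP's threshold (capped at `ahpCapMs`). When the voltage never
#' returns to the threshold level before the next AP, decay time and AHP
#' are flagged unavailable (`NA`).
#'
#' @param trace a [VoltageTrace-class]
#' @param peakIdx peak sample index
#' @param threshold list from [thresholdFixedLead()] or
#'   [thresholdInflection()]
#' @param rmp resting membrane potential (mV)
#' @param nextLimitIdx sample index bounding the AHP search (the next AP's
#'   threshold), or `NULL` for trace end
#' @param ahpCapMs cap on the AHP search window (ms, default 200)
#' @return one-row data.frame (an AP event record)
#' @export
apMetrics <- function(trace, peakIdx, threshold, rmp, nextLimitIdx = NULL,
                      ahpCapMs = 200) {
  v <- trace@v; dt <- trace@dt
  thrIdx <- threshold$idx; thrV <- threshold$v_mV
  if (thrIdx >= peakIdx) stop("threshold must precede the peak")
  peakV <- v[peakIdx]
  amp <- peakV - thrV
  if (amp <= 0) stop("nonpositive amplitude: threshold above peak")
  half <- thrV + amp / 2
  # upstroke crossing of the half level (last crossing before the peak)
  upSeg <- thrIdx:(peakIdx - 1L)
  upI <- upSeg[v[upSeg] <= half & v[upSeg + 1L] > half]
  upX <- if (length(upI)) .crossAt(v, upI[length(upI)], half) else NA_real_
  # downstroke crossings after the peak
  lim <- length(v) - 1L
  i <- peakIdx
  downHalf <- NA_real_; downThr <- NA_real_
  while (i <= lim) {
    if (is.na(downHalf) && v[i] > half && v[i + 1L] <= half)
      downHalf <- .crossAt(v, i, half)
    if (v[i] > thrV && v[i + 1L] <= thrV) { downThr <- .crossAt(v, i, thrV); break }
    i <- i + 1L
  }
  apd50 <- if (!is.na(upX) && !is.na(downHalf)) (downHalf - upX) * dt * 1000
           else NA_real_
  rise <- (peakIdx - thrIdx) * dt * 1000
  decay <- if (!is.na(downThr)) (downThr - peakIdx) * dt * 1000 else NA_real_
  ahp <- NA_real_
  if (!is.na(downThr)) {
    from <- ceiling(downThr)
    to <- min(length(v),
              if (is.null(nextLimitIdx)) length(v) else nextLimitIdx,
              from + round(ahpCapMs / 1000 / dt))
    if (from <= to) ahp <- min(v[from:to])
  }
  data.frame(peak_time_s = (peakIdx - 1L) * dt, peak_mV = peakV,
             threshold_time_s = threshold$time_s, threshold_mV = thrV,
             method = threshold$method, rmp_mV = rmp,
             amplitude_mV = amp, apd50_ms = apd50, ahp_mV = ahp,
             rise_time_ms = rise, decay_time_ms = decay)
}

#' Phase plot and extreme slopes of an AP
#'
#' Computes dV/dt (central differences, mV/ms) over a window around the
#' peak and returns the (V, dV/dt) phase curve together with the maximum
#' and minimum slopes — the points where the membrane potential rises and
#' falls most rapidly.
#'
#' @param trace a [VoltageTrace-class]
#' @param from,to sample index range (defaults: whole trace)
#' @return list with `curve` (data.frame `v_mV`, `dvdt_mV_ms`),
#'   `max_slope_mV_ms`, `min_slope_mV_ms`
#' @export
phasePlot <- function(trace, from = 1L, to = length(trace@v)) {
  v <- trace@v
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * trace@dt * 1000)
  d[1] <- d[2]; d[n] <- d[n - 1]
  w <- from:to
  list(curve = data.frame(v_mV = v[w], dvdt_mV_ms = d[w]),
       max_slope_mV_ms = max(d[w]), min_slope_mV_ms = min(d[w]))
}

#' Peak-aligned average AP trace
#'
#' Aligns a window around each detected peak and averages sample-wise.
#' APs whose window would extend beyond the trace are dropped and counted.
#'
#' @param trace a [VoltageTrace-class]
#' @param peaks integer vector of peak indices
#' @param preMs,postMs window before/after the peak (ms)
#' @return list with `time_ms` (relative to the peak), `v_mV` (the mean
#'   trace), `n` (APs averaged), `dropped`
#' @export
averageAP <- function(trace, peaks, preMs = 10, postMs = 30) {
  if (!length(peaks)) stop("no peaks to average")
  pre <- round(preMs / 1000 / trace@dt)
  post <- round(postMs / 1000 / trace@dt)
  ok <- peaks - pre >= 1L & peaks + post <= length(trace@v)
  if (!any(ok)) stop("no AP window fits inside the trace")
  win <- vapply(peaks[ok], function(p) trace@v[(p - pre):(p + post)],
                numeric(pre + post + 1L))
  list(time_ms = ((-pre):post) * trace@dt * 1000,
       v_mV = rowMeans(win), n = sum(ok), dropped = sum(!ok))
}

#' Analyze every AP in a trace
#'
#' Convenience wrapper: detects peaks, applies the chosen threshold
#' method per AP (inflection mode falls back to fixed-lead when no
#' inflection qualifies and `leadMs` is given), measures the RMP before
#' each AP's reference point, and tabulates [apMetrics()] for all APs.
#'
#' @param trace a [VoltageTrace-class]
#' @param method `"fixed-lead"` or `"inflection"`
#' @param leadMs fixed lead (ms); required for `"fixed-lead"`
#' @param dvdtCriterion dV/dt criterion for `"inflection"` (mV/ms)
#' @param ... passed to [detectAPs()]
#' @return data.frame with one row per AP
#' @export
analyzeAPs <- function(trace, method = c("fixed-lead", "inflection"),
                       leadMs = NULL, dvdtCriterion = 10, ...) {
  method <- match.arg(method)
  if (method == "fixed-lead" && is.null(leadMs))
    stop("leadMs is required for the fixed-lead method")
  peaks <- detectAPs(trace, ...)
  if (!length(peaks)) return(data.frame())
  thr <- vector("list", length(peaks))
  for (i in seq_along(peaks)) {
    thr[[i]] <- if (method == "inflection") {
      th <- thresholdInflection(trace, peaks[i], dvdtCriterion)
      if (is.null(th)) {
        if (is.null(leadMs)) stop("AP ", i, " has no preupstroke inflection; ",
                                  "supply leadMs for the fixed-lead fallback")
        thresholdFixedLead(trace, peaks[i], leadMs)
      } else th
    } else thresholdFixedLead(trace, peaks[i], leadMs)
  }
  out <- NULL
  for (i in seq_along(peaks)) {
    rmp <- tryCatch(
      restingPotential(trace, thr[[i]]$idx,
                       if (thr[[i]]$method == "inflection") "inflection"
                       else "fixed-lead"),
      error = function(e) NA_real_)
    nxt <- if (i < length(peaks)) thr[[i + 1L]]$idx else NULL
    out <- rbind(out, apMetrics(trace, peaks[i], thr[[i]], rmp, nxt))
  }
  out
}
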