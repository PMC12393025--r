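# Sleep-like quiescence: motion classification and bout detection.

#' Classify per-frame motion from centroid displacements
#'
#' The displacement between consecutive centroids classifies each
#' transition: motionless when strictly below `threshold` micrometers,
#' active at or above it (the exactly-at-threshold case is assigned
#' active, keeping "motionless" a strict inequality). Missing centroids
#' (failed segmentation) yield `NA` labels that break runs downstream.
#'
#' @param time_s frame timestamps (s); sleep recordings are nominally one
#'   frame per 10 s
#' @param x_um,y_um centroid coordinates (um); `NA` for lost frames
#' @param threshold motionless displacement bound (um, default 10)
#' @return data.frame with one row per transition: `time_s` (timestamp of
#'   the later frame), `duration_s`, `displacement_um`, `label`
#'   (`"motionless"`/`"active"`/`NA`)
#' @export
classifyMotion <- function(time_s, x_um, y_um, threshold = 10) {
  n <- length(time_s)
  if (n < 2L) stop("need at least 2 frames")
  d <- sqrt(diff(x_um)^2 + diff(y_um)^2)
  label <- ifelse(is.na(d), NA_character_,
                  ifelse(d < threshold, "motionless", "active"))
  data.frame(time_s = time_s[-1], duration_s = diff(time_s),
             displacement_um = d, label = label,
             stringsAsFactors = FALSE)
}

#' Detect sleep bouts from a motion-label series
#'
#' A bout opens at the first frame of a run of at least `k` consecutive
#' motionless frames and closes at an awakening — a run of at least
#' `wakeK` consecutive active frames — or at the end of the series; the
#' bout's end is then trimmed back to the end of the last run of at least
#' `k` motionless frames before the awakening. Active runs shorter than
#' `wakeK` inside a bout are recorded as active events. `NA` labels
#' (lost frames) conservatively break runs without counting as activity.
#'
#' @param motion data.frame from [classifyMotion()]
#' @param k motionless frames required for onset and offset (default 3)
#' @param wakeK consecutive active frames that end a bout (default 3);
#'   chosen by symmetry with the onset rule
#' @param invalid_s optional 2-column matrix of (start, end) times; bouts
#'   overlapping any such range are flagged `invalid`
#' @return data.frame with one row per bout: `start_time_s`, `end_time_s`,
#'   `total_duration_s`, `n_active_events`, `active_duration_s`,
#'   `motionless_duration_s`, `invalid`; attribute `events` holds a
#'   per-event table
#' @export
detectSleepBouts <- function(motion, k = 3, wakeK = 3, invalid_s = NULL) {
  lab <- motion$label
  dur <- motion$duration_s
  tEnd <- motion$time_s
  tStart <- motion$time_s - motion$duration_s
  n <- length(lab)
  emptyRes <- data.frame(start_time_s = numeric(), end_time_s = numeric(),
                         total_duration_s = numeric(),
                         n_active_events = integer(),
                         active_duration_s = numeric(),
                         motionless_duration_s = numeric(),
                         invalid = logical())
  # run-length encode, treating NA as its own run type
  key <- ifelse(is.na(lab), "gap", lab)
  r <- rle(key)
  rEnd <- cumsum(r$lengths)
  rStart <- rEnd - r$lengths + 1L
  isM <- r$values == "motionless" & r$lengths >= k
  isWake <- r$values == "active" & r$lengths >= wakeK
  isGap <- r$values == "gap"
  bouts <- emptyRes
  events <- data.frame(bout = integer(), start_time_s = numeric(),
                       duration_s = numeric())
  i <- 1L
  boutNo <- 0L
  while (i <= length(r$lengths)) {
    if (!isM[i]) { i <- i + 1L; next }
    # find the closing run: awakening, gap, or end of series
    j <- i
    while (j + 1L <= length(r$lengths) && !isWake[j + 1L] && !isGap[j + 1L])
      j <- j + 1L
    # trim back to the last >= k motionless run in i..j
    lastM <- max(which(isM[i:j])) + i - 1L
    startIdx <- rStart[i]
    endIdx <- rEnd[lastM]
    boutNo <- boutNo + 1L
    inBout <- startIdx:endIdx
    total <- sum(dur[inBout])
    activeRuns <- which(r$values == "active" &
                        rStart >= startIdx & rEnd <= endIdx)
    adur <- 0
    for (a in activeRuns) {
      adur <- adur + sum(dur[rStart[a]:rEnd[a]])
      events <- rbind(events, data.frame(
        bout = boutNo, start_time_s = tStart[rStart[a]],
        duration_s = sum(dur[rStart[a]:rEnd[a]])))
    }
    inval <- FALSE
    if (!is.null(invalid_s) && nrow(invalid_s))
      inval <- any(invalid_s[, 1] < tEnd[endIdx] &
                   invalid_s[, 2] > tStart[startIdx])
    bouts <- rbind(bouts, data.frame(
      start_time_s = tStart[startIdx], end_time_s = tEnd[endIdx],
      total_duration_s = total, n_active_events = length(activeRuns),
      active_duration_s = adur,
      motionless_duration_s = total - adur, invalid = inval))
    # resume scanning after the closing run (skip past awakening/gap)
    i <- j + 1L
  }
  attr(bouts, "events") <- events
  bouts
}

#' Summarize sleep over a recording
#'
#' Totals over all detected bouts: sleep duration, bout count, mean and
#' longest bout length, active-event count and duration, and motionless
#' sleep duration (total sleep minus active periods). Both the sum over
#' bouts and the single longest bout are reported.
#'
#' @param bouts data.frame from [detectSleepBouts()]
#' @param recordingSpan_s total recorded span (s), for the sleep fraction
#' @return one-row data.frame
#' @export
sleepSummary <- function(bouts, recordingSpan_s = NA_real_) {
  if (!nrow(bouts)) {
    return(data.frame(total_sleep_s = 0, n_bouts = 0L, mean_bout_s = 0,
                      longest_bout_s = 0, n_active_events = 0L,
                      active_duration_s = 0, motionless_sleep_s = 0,
                      sleep_fraction = if (is.na(recordingSpan_s)) NA_real_ else 0))
  }
  total <- sum(bouts$total_duration_s)
  data.frame(total_sleep_s = total,
             n_bouts = nrow(bouts),
             mean_bout_s = mean(bouts$total_duration_s),
             longest_bout_s = max(bouts$total_duration_s),
             n_active_events = sum(bouts$n_active_events),
             active_duration_s = sum(bouts$active_duration_s),
             motionless_sleep_s = sum(bouts$motionless_duration_s),
             sleep_fraction = total / recordingSpan_s)
}
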