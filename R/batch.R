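# End-to-end analysis of one recording and batch processing of a parent
# folder, mirroring the analyze / batch-analyze workflow.

#' Analyze one recording end to end
#'
#' Loads (or fits) the midline track, merges it with the stage log into
#' world coordinates, reduces to the effective frame rate, and computes
#' the movement, bending and curvature summaries.
#'
#' @param rec a [WormRecording-class] from [resolveRecording()]
#' @param config fitting/analysis parameters (see [fitFrame()]); extra
#'   keys: `marker` (movement marker, default `"centroid"`),
#'   `bendMarker` (summary bend marker, default 6 -- mid-body),
#'   `minBendAngle` (maximum-bend gate, default 20)
#' @param track optional pre-fitted [SplineTrack-class]; defaults to the
#'   recording's spline file when present, else the frames are fitted
#' @return list of data.frames: `movement`, `bending`, `curvature`
#' @export
analyzeRecording <- function(rec, config = list(), track = NULL) {
  if (is.null(track)) {
    track <- if (!is.na(rec@splineFile)) readSplineFile(rec@splineFile)
             else fitRecording(rec, config)
  }
  world <- effectiveFrames(toWorld(track, rec))
  mv <- movementMetrics(world, config$marker %||% "centroid")
  mv <- cbind(data.frame(recording = rec@name), mv)
  bt <- bendTrace(world, rec@orientation)
  bm <- config$bendMarker %||% 6L
  dom <- tryCatch(dominantFrequency(bt, bm)$frequency_hz,
                  error = function(e) NA_real_)
  mb <- maximumBend(bt, bm, config$minBendAngle %||% 20)
  bend <- data.frame(recording = rec@name, marker = bm,
                     rms_bend_deg = rmsBend(bt, bm),
                     sum_of_all_bends_deg = sumOfAllBends(bt),
                     dominant_frequency_hz = dom,
                     maximum_bend_deg = as.numeric(mb))
  # per-frame curvature segments in world scale
  curv <- NULL
  okf <- which(fitStatus(track) == "ok")
  for (f in okf) {
    mk <- cbind(track@mx[f, ], track@my[f, ])
    dense <- .resampleArc(mk, 100L)
    sp <- new("Spline13", markers = .resampleArc(dense, 13L), dense = dense,
              lengthPx = .arcLength(dense))
    cs <- tryCatch(curvatures(sp, rec@orientation), error = function(e) NULL)
    if (!is.null(cs) && nrow(cs))
      curv <- rbind(curv, cbind(data.frame(recording = rec@name, frame = f),
                                cs))
  }
  if (is.null(curv))
    curv <- data.frame(recording = character(), frame = integer())
  list(movement = mv, bending = bend, curvature = curv)
}

#' Batch-analyze every recording under a parent folder
#'
#' Processes each resolvable recording subfolder independently — a failure
#' in one recording is logged and does not stop the rest — and writes a
#' combined results workbook into the parent folder.
#'
#' @param parent parent folder holding per-worm recording subfolders
#' @param config see [analyzeRecording()]; `umPerPx` and `fps` are read
#'   from it (defaults 2.5 and `NULL`)
#' @param workbook name of the combined workbook directory (default
#'   `"results"`)
#' @return list with `movement`, `bending`, `curvature` (combined tables),
#'   `failures` (named character vector of error messages), invisibly
#' @export
runBatch <- function(parent, config = list(), workbook = "results") {
  subs <- list.dirs(parent, recursive = FALSE)
  subs <- subs[vapply(subs, function(d)
    length(list.files(d, pattern = "^img[0-9]+\\.(jpeg|jpg|png)$")) > 0,
    logical(1))]
  if (!length(subs)) stop("no resolvable recording subfolder in ", parent)
  mv <- NULL; bend <- NULL; curv <- NULL
  failures <- character(0)
  for (d in subs) {
    res <- tryCatch({
      rec <- resolveRecording(d, umPerPx = config$umPerPx %||% 2.5,
                              fps = config$fps)
      analyzeRecording(rec, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[basename(d)] <- conditionMessage(res)
      next
    }
    mv <- rbind(mv, res$movement)
    bend <- rbind(bend, res$bending)
    if (nrow(res$curvature)) curv <- rbind(curv, res$curvature)
  }
  tables <- list()
  if (!is.null(mv)) tables$movement <- mv
  if (!is.null(bend)) tables$bending <- bend
  if (!is.null(curv)) tables$curvature <- curv
  if (length(tables))
    exportResults(tables, file.path(parent, workbook))
  invisible(list(movement = mv, bending = bend, curvature = curv,
                 failures = failures))
}
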