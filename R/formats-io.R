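#' Read and write the recording-bundle text dialects
#'
#' A recording lives in one folder per worm: frame images `img00001.jpeg`
#' (`.jpg`/`.png` accepted), a stage file `<name>.txt`, a time file
#' `<name>_times.txt`, and — after midline fitting — a spline file
#' `<name>_spline.txt` saved in the parent folder. Folder names may carry an
#' `R_` or `L_` prefix encoding the worm's ventral side (ventral-right /
#' ventral-left as seen in the image).
#'
#' All three companion files are tab-separated with a one-line header, so
#' they diff cleanly and survive write-then-read bit-exactly:
#' \describe{
#'   \item{stage file}{columns `time_s`, `x_um`, `y_um`: absolute stage
#'     positions, strictly increasing timestamps.}
#'   \item{time file}{columns `record` (`frame` or `move`), `frame`
#'     (index, empty for moves), `time_s`.}
#'   \item{spline file}{columns `frame`, `status` (`ok`/`fail`),
#'     `threshold`, `attempts`, `length_px`, then `x1..x13`, `y1..y13`
#'     marker pixel coordinates (NA on failed frames).}
#' }
#'
#' @param path file path
#' @param stage data.frame with columns `time_s`, `x_um`, `y_um`
#' @param frameTimes data.frame with columns `frame`, `time_s`
#' @param moveTimes numeric vector of stage-movement timestamps
#' @param track a [SplineTrack-class]
#' @return readers return the corresponding object; writers return `path`
#'   invisibly
#' @name bundle-io
NULL

#' @rdname bundle-io
#' @export
writeStageLog <- function(stage, path) {
  stopifnot(all(c("time_s", "x_um", "y_um") %in% names(stage)))
  lines <- c("time_s\tx_um\ty_um",
             paste(.fmtNum(stage$time_s), .fmtNum(stage$x_um),
                   .fmtNum(stage$y_um), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname bundle-io
#' @export
readStageLog <- function(path) {
  df <- utils::read.delim(path, colClasses = "numeric")
  if (!identical(names(df), c("time_s", "x_um", "y_um")))
    stop("malformed stage file: ", path)
  df
}

#' @rdname bundle-io
#' @export
writeTimeLog <- function(frameTimes, moveTimes, path) {
  stopifnot(all(c("frame", "time_s") %in% names(frameTimes)))
  lines <- c("record\tframe\ttime_s",
             paste("frame", frameTimes$frame, .fmtNum(frameTimes$time_s),
                   sep = "\t"))
  if (length(moveTimes))
    lines <- c(lines, paste("move", "", .fmtNum(moveTimes), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname bundle-io
#' @export
readTimeLog <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", "integer",
                                               "numeric"))
  if (!identical(names(df), c("record", "frame", "time_s")))
    stop("malformed time file: ", path)
  list(frameTimes = df[df$record == "frame", c("frame", "time_s")],
       moveTimes = df$time_s[df$record == "move"])
}

#' @rdname bundle-io
#' @export
writeSplineFile <- function(track, path) {
  stopifnot(is(track, "SplineTrack"))
  validObject(track)
  hdr <- paste(c("frame", "status", "threshold", "attempts", "length_px",
                 paste0("x", 1:13), paste0("y", 1:13)), collapse = "\t")
  rows <- vapply(seq_along(track@frame), function(i) {
    paste(c(track@frame[i], track@status[i], .fmtNum(track@threshold[i]),
            track@attempts[i], .fmtNum(track@lengthPx[i]),
            .fmtNum(track@mx[i, ]), .fmtNum(track@my[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname bundle-io
#' @export
readSplineFile <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(hdr) != 31L || hdr[1] != "frame")
    stop("malformed spline file header: ", path)
  body <- lines[-1]
  t <- length(body)
  mk <- function() matrix(NA_real_, t, 13L)
  out <- list(frame = integer(t), status = character(t), threshold = numeric(t),
              attempts = integer(t), lengthPx = numeric(t), mx = mk(), my = mk())
  num <- function(x) { x[x == "NA"] <- NA_character_; as.numeric(x) }
  for (i in seq_len(t)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 31L)
      stop("malformed spline row for frame index ", i, " in ", path,
           " (expected 31 fields, got ", length(f), ")")
    out$frame[i] <- as.integer(f[1]); out$status[i] <- f[2]
    out$threshold[i] <- num(f[3]); out$attempts[i] <- as.integer(f[4])
    out$lengthPx[i] <- num(f[5])
    out$mx[i, ] <- num(f[6:18]); out$my[i, ] <- num(f[19:31])
  }
  new("SplineTrack", frame = out$frame, status = out$status,
      threshold = out$threshold, attempts = out$attempts,
      mx = out$mx, my = out$my, lengthPx = out$lengthPx)
}

#' Locate a recording bundle by its folder conventions
#'
#' Finds the frame images (`img%05d.jpeg/.jpg/.png`, sorted by index),
#' the stage file `<folder>.txt` and time file `<folder>_times.txt` inside
#' the folder, and a spline file `<folder>_spline.txt` in the parent folder.
#' An `R_`/`L_` folder-name prefix sets the orientation (ventral-right /
#' ventral-left); without it the orientation is `"unknown"`. When the stage
#' or time file is missing, the bundle is marked stage-free (all stage
#' offsets zero) and a warning is raised; frame times then fall back to the
#' nominal frame rate.
#'
#' @param folder path to the per-worm recording folder
#' @param umPerPx micrometers per pixel from calibration (default 2.5)
#' @param fps nominal frame rate; `NULL` (default) infers it from the time
#'   log (rounded median frame interval), falling back to 3
#' @return a [WormRecording-class]
#' @export
resolveRecording <- function(folder, umPerPx = 2.5, fps = NULL) {
  if (!dir.exists(folder)) stop("missing image folder: ", folder)
  base <- basename(normalizePath(folder, mustWork = TRUE))
  orientation <- if (startsWith(base, "R_")) "ventral-right"
                 else if (startsWith(base, "L_")) "ventral-left"
                 else "unknown"
  name <- sub("^[RL]_", "", base)

  imgs <- list.files(folder, pattern = "^img[0-9]+\\.(jpeg|jpg|png)$",
                     full.names = TRUE)
  if (!length(imgs)) stop("no frame images (img%05d.*) in ", folder)
  idx <- as.integer(sub("^img0*([0-9]+)\\..*$", "\\1", basename(imgs)))
  imgs <- imgs[order(idx)]; idx <- sort(idx)
  if (idx[1] != 1L || any(diff(idx) != 1L))
    stop("frame indices not contiguous from 1 in ", folder)

  stagePath <- file.path(folder, paste0(base, ".txt"))
  timePath <- file.path(folder, paste0(base, "_times.txt"))
  stageFree <- !(file.exists(stagePath) && file.exists(timePath))
  if (stageFree) {
    warning("stage/time file missing for ", base,
            "; treating recording as stage-free (zero offsets)")
    stage <- data.frame(time_s = numeric(), x_um = numeric(), y_um = numeric())
    frameTimes <- data.frame(frame = seq_along(imgs), time_s = NA_real_)
    moves <- numeric()
  } else {
    stage <- readStageLog(stagePath)
    tl <- readTimeLog(timePath)
    frameTimes <- tl$frameTimes
    moves <- tl$moveTimes
  }

  if (is.null(fps)) {
    dtf <- diff(frameTimes$time_s)
    fps <- if (length(dtf) && all(is.finite(dtf)) && median(dtf) > 0)
      round(1 / stats::median(dtf)) else 3
    if (!fps %in% c(1, 3, 5, 15)) fps <- 3
  }
  if (all(is.na(frameTimes$time_s)))
    frameTimes$time_s <- (seq_along(imgs) - 1L) / fps

  splinePath <- file.path(dirname(normalizePath(folder)),
                          paste0(base, "_spline.txt"))
  if (!file.exists(splinePath)) splinePath <- NA_character_

  new("WormRecording", name = name, imageFiles = imgs, stageLog = stage,
      frameTimes = frameTimes, moveTimes = moves, orientation = orientation,
      umPerPx = umPerPx, fps = fps, splineFile = splinePath,
      stageFree = stageFree)
}

#' Load one grayscale frame as a 0-255 intensity matrix
#'
#' @param path image file path (JPEG or PNG)
#' @return numeric matrix indexed `[x, y]` (x rightward, y downward),
#'   intensities on the 0-255 scale
#' @export
loadFrame <- function(path) {
  img <- EBImage::readImage(path)
  if (length(dim(img)) > 2L) img <- EBImage::channel(img, "gray")
  m <- EBImage::imageData(img) * 255
  dim(m) <- dim(m)[1:2]
  m
}

#' Export result tables as a results workbook
#'
#' Writes one CSV sheet per named table into a workbook directory, plus a
#' `manifest.tsv` listing the sheets. Numeric columns are expected to carry
#' their units in the header (e.g. `avg_speed_um_s`). Values round-trip
#' exactly through [readResults()].
#'
#' @param tables named list of nonempty data.frames, one per metric family
#'   (e.g. movement, bending, curvature, sleep, ap)
#' @param path workbook directory to create (overwritten if present)
#' @return `path` invisibly
#' @export
exportResults <- function(tables, path) {
  if (!length(tables) || is.null(names(tables)) || any(names(tables) == ""))
    stop("tables must be a nonempty named list")
  for (nm in names(tables))
    if (!is.data.frame(tables[[nm]]) || nrow(tables[[nm]]) == 0L)
      stop("empty table: ", nm)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) {
    df <- tables[[nm]]
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], .fmtNum)
    utils::write.csv(df, file.path(path, paste0(nm, ".csv")),
                     row.names = FALSE, quote = TRUE)
  }
  writeLines(c("sheet", names(tables)), file.path(path, "manifest.tsv"))
  invisible(path)
}

#' @rdname exportResults
#' @export
readResults <- function(path) {
  sheets <- readLines(file.path(path, "manifest.tsv"))[-1]
  out <- lapply(sheets, function(nm)
    utils::read.csv(file.path(path, paste0(nm, ".csv")), check.names = FALSE))
  names(out) <- sheets
  out
}

#' Reduce or restore the frame rate of a recording folder
#'
#' `reduceFramerate()` keeps every `keepEvery`-th frame (starting at frame
#' 1), moves the others into a `Removed/` subfolder, and rewrites the time
#' file (the original is kept as `<name>_times_before_RF.txt`).
#' `restoreFramerate()` reverts the operation. Pure file bookkeeping; frame
#' files are renumbered contiguously after reduction.
#'
#' @param folder recording folder
#' @param keepEvery keep one frame out of this many (e.g. 5 turns 15 FPS
#'   into 3 FPS)
#' @return invisibly, the number of frames moved (or restored)
#' @export
reduceFramerate <- function(folder, keepEvery) {
  stopifnot(keepEvery >= 2L)
  base <- basename(normalizePath(folder, mustWork = TRUE))
  imgs <- list.files(folder, pattern = "^img[0-9]+\\.(jpeg|jpg|png)$")
  idx <- as.integer(sub("^img0*([0-9]+)\\..*$", "\\1", imgs))
  imgs <- imgs[order(idx)]
  keep <- seq(1L, length(imgs), by = keepEvery)
  drop <- setdiff(seq_along(imgs), keep)
  rmdir <- file.path(folder, "Removed")
  dir.create(rmdir, showWarnings = FALSE)
  file.rename(file.path(folder, imgs[drop]), file.path(rmdir, imgs[drop]))
  # renumber the kept frames contiguously
  ext <- sub("^.*\\.", "", imgs[keep])
  tmp <- file.path(folder, paste0("tmp_", seq_along(keep), ".", ext))
  file.rename(file.path(folder, imgs[keep]), tmp)
  file.rename(tmp, file.path(folder, sprintf("img%05d.%s", seq_along(keep), ext)))
  timePath <- file.path(folder, paste0(base, "_times.txt"))
  if (file.exists(timePath)) {
    file.copy(timePath, file.path(folder, paste0(base, "_times_before_RF.txt")),
              overwrite = TRUE)
    tl <- readTimeLog(timePath)
    ft <- tl$frameTimes[keep, , drop = FALSE]
    ft$frame <- seq_along(keep)
    writeTimeLog(ft, tl$moveTimes, timePath)
  }
  invisible(length(drop))
}

#' @rdname reduceFramerate
#' @export
restoreFramerate <- function(folder) {
  base <- basename(normalizePath(folder, mustWork = TRUE))
  rmdir <- file.path(folder, "Removed")
  if (!dir.exists(rmdir)) stop("nothing to restore: no Removed/ in ", folder)
  removed <- list.files(rmdir)
  kept <- list.files(folder, pattern = "^img[0-9]+\\.(jpeg|jpg|png)$")
  # removed files retain their original names; renumber kept frames back
  origIdx <- sort(setdiff(
    seq_len(length(removed) + length(kept)),
    as.integer(sub("^img0*([0-9]+)\\..*$", "\\1", removed))))
  ext <- sub("^.*\\.", "", kept)
  tmp <- file.path(folder, paste0("tmp_", seq_along(kept), ".", ext))
  file.rename(file.path(folder, sort(kept)), tmp)
  file.rename(tmp, file.path(folder, sprintf("img%05d.%s", origIdx, ext)))
  file.rename(file.path(rmdir, removed), file.path(folder, removed))
  unlink(rmdir, recursive = TRUE)
  before <- file.path(folder, paste0(base, "_times_before_RF.txt"))
  if (file.exists(before))
    file.rename(before, file.path(folder, paste0(base, "_times.txt")))
  invisible(length(removed))
}
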