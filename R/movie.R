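#' Two-channel time-lapse movie
#'
#' Container for a pair of co-registered intensity stacks: a vascular channel
#' (intravascular dye, used for motion correction and lumen segmentation) and
#' an activity channel (Ca2+ indicator). Arrays are `H x W x T`. The global
#' coordinate convention is 0-based `(row, col)` with the origin at the centre
#' of the top-left pixel; frame indices are 0-based and time in seconds is
#' `frame * frame_interval`.
#'
#' @param vascular,activity numeric `H x W x T` arrays of identical shape.
#' @param pixel_size physical pixel size, micrometres per pixel.
#' @param frame_interval time between frames, seconds.
#' @param channel_names length-2 character vector of channel labels.
#' @return an object of class `two_channel_movie`.
#' @export
two_channel_movie <- function(vascular, activity, pixel_size = 1,
                              frame_interval = 1,
                              channel_names = c("vascular", "activity")) {
  if (length(dim(vascular)) == 2) dim(vascular) <- c(dim(vascular), 1L)
  if (length(dim(activity)) == 2) dim(activity) <- c(dim(activity), 1L)
  if (length(dim(vascular)) != 3 || length(dim(activity)) != 3)
    stop("channels must be H x W x T arrays", call. = FALSE)
  if (!identical(dim(vascular), dim(activity)))
    stop(sprintf(
      "channel shapes differ: vascular %s vs activity %s",
      paste(dim(vascular), collapse = "x"),
      paste(dim(activity), collapse = "x")), call. = FALSE)
  stopifnot_finite(vascular, "vascular")
  stopifnot_finite(activity, "activity")
  if (dim(vascular)[3] < 1) stop("movie needs at least one frame", call. = FALSE)
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be positive", call. = FALSE)
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be positive", call. = FALSE)
  structure(list(vascular = vascular, activity = activity,
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 channel_names = channel_names),
            class = "two_channel_movie")
}

#' @export
print.two_channel_movie <- function(x, ...) {
  d <- dim(x$vascular)
  cat(sprintf("<two_channel_movie> %d x %d px, %d frames\n", d[1], d[2], d[3]))
  cat(sprintf("  pixel size %.3g um/px, frame interval %.3g s\n",
              x$pixel_size, x$frame_interval))
  cat(sprintf("  channels: %s\n", paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' @export
dim.two_channel_movie <- function(x) dim(x$vascular)

#' Number of frames in a movie
#' @param movie a [two_channel_movie()].
#' @return integer frame count.
#' @export
n_frames <- function(movie) dim(movie$vascular)[3]

#' Write a two-channel movie to multi-page TIFF files
#'
#' One TIFF per channel plus a JSON sidecar holding the calibration. Integer
#' data in `[0, 65535]` are stored as 16-bit and round-trip exactly;
#' non-integer data are stored as 32-bit float, rescaled into `[0, 1]` with the
#' scale factor recorded in the sidecar.
#'
#' @param movie a [two_channel_movie()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, named character vector of the three paths written.
#' @export
write_movie <- function(movie, dir, prefix = "movie") {
  stopifnot(inherits(movie, "two_channel_movie"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vascular = file.path(dir, paste0(prefix, "_vascular.tif")),
    activity = file.path(dir, paste0(prefix, "_activity.tif")),
    sidecar  = file.path(dir, paste0(prefix, "_sidecar.json"))
  )
  scales <- numeric(2)
  chans <- list(movie$vascular, movie$activity)
  for (i in 1:2) {
    x <- chans[[i]]
    is_int <- all(x == round(x)) && min(x) >= 0 && max(x) <= 65535
    pages <- lapply(seq_len(dim(x)[3]), function(t) x[, , t])
    if (is_int) {
      scales[i] <- NA_real_  # 16-bit integer storage
      tiff::writeTIFF(lapply(pages, function(p) p / 65535),
                      paths[i], bits.per.sample = 16L)
    } else {
      lo <- min(x); hi <- max(x)
      sc <- if (hi > lo) hi - lo else 1
      scales[i] <- sc
      attr(scales, "offsets") <- c(attr(scales, "offsets"), lo)
      tiff::writeTIFF(lapply(pages, function(p) (p - lo) / sc),
                      paths[i], bits.per.sample = 32L)
    }
  }
  offs <- attr(scales, "offsets")
  sidecar <- list(
    pixel_size_um = movie$pixel_size,
    frame_interval_s = movie$frame_interval,
    channel_names = as.list(movie$channel_names),
    n_frames = n_frames(movie),
    float_scale = as.list(ifelse(is.na(scales), NA, scales)),
    float_offset = as.list(if (is.null(offs)) c(NA, NA) else {
      o <- rep(NA_real_, 2); o[which(!is.na(scales))] <- offs; o
    })
  )
  jsonlite::write_json(sidecar, paths["sidecar"], auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(paths)
}

#' Read a two-channel movie from multi-page TIFF files
#'
#' @param vascular_path,activity_path paths to the per-channel TIFF stacks.
#' @param sidecar_path optional path to the JSON sidecar written by
#'   [write_movie()]; if missing, calibration defaults (1 um/px, 1 s/frame)
#'   are used with a warning.
#' @return a [two_channel_movie()].
#' @export
read_movie <- function(vascular_path, activity_path, sidecar_path = NULL) {
  side <- NULL
  if (!is.null(sidecar_path) && file.exists(sidecar_path)) {
    side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  } else {
    warning("no sidecar found; using default calibration (1 um/px, 1 s/frame)",
            call. = FALSE)
  }
  read_chan <- function(path, k) {
    if (!file.exists(path)) stop("cannot read TIFF: ", path, call. = FALSE)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
    for (t in seq_along(pages)) arr[, , t] <- pages[[t]]
    sc <- if (!is.null(side)) unlist(side$float_scale)[k] else NA
    if (!is.null(sc) && !is.na(sc)) {
      # 32-bit float storage: readTIFF(as.is) rescales; reread natively
      pages <- tiff::readTIFF(path, all = TRUE)
      off <- unlist(side$float_offset)[k]
      for (t in seq_along(pages)) arr[, , t] <- pages[[t]] * sc + off
    }
    arr
  }
  vas <- read_chan(vascular_path, 1)
  act <- read_chan(activity_path, 2)
  if (!identical(dim(vas), dim(act)))
    stop(sprintf("channel frame counts/shapes differ: vascular %s vs activity %s",
                 paste(dim(vas), collapse = "x"),
                 paste(dim(act), collapse = "x")), call. = FALSE)
  two_channel_movie(
    vas, act,
    pixel_size = if (!is.null(side)) side$pixel_size_um else 1,
    frame_interval = if (!is.null(side)) side$frame_interval_s else 1,
    channel_names = if (!is.null(side)) unlist(side$channel_names)
                    else c("vascular", "activity"))
}

#' Write tidy result tables and a manifest
#'
#' Writes one CSV per result family (diameter trace, soma events, endfoot
#' events, per-ROI summaries, ...) with one row per (unit, frame) or
#' (unit, event), plus `manifest.json` listing every file with its row count.
#' Empty data frames yield header-only CSVs.
#'
#' @param results named list of data frames.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest as a data frame (`file`, `rows`).
#' @export
write_tables <- function(results, out_dir) {
  stopifnot(is.list(results), length(names(results)) == length(results))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(file = character(), rows = integer())
  for (nm in names(results)) {
    df <- results[[nm]]
    if (!is.data.frame(df)) next
    fn <- paste0(nm, ".csv")
    write.csv(df, file.path(out_dir, fn), row.names = FALSE)
    manifest <- rbind(manifest, data.frame(file = fn, rows = nrow(df)))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
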