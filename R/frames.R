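#' Construct a single time-stamped frame
#'
#' A frame couples an 8-bit intensity grid with its acquisition time.
#' Daytime frames are RGB (`rows x cols x 3`), nighttime IR frames are
#' single-channel (`rows x cols`). Intensities are stored on the 0-255
#' scale as numerics.
#'
#' @param pixels Numeric matrix (night) or `rows x cols x 3` array (day),
#'   values in `[0, 255]`.
#' @param timestamp Minutes since the start of the experiment.
#' @param clock_time Clock time in hours of day, in `[0, 24)`. Derived from
#'   `start_clock + timestamp` when omitted.
#' @param condition `"day"` or `"night"`. Derived from `schedule` when
#'   omitted.
#' @param start_clock Clock time (hours) of the first experiment minute,
#'   used to derive `clock_time`.
#' @param schedule A [photoperiod()] used to derive `condition`.
#' @return An object of class `taa_frame`.
#' @export
taa_frame <- function(pixels, timestamp, clock_time = NULL, condition = NULL,
                      start_clock = 8, schedule = photoperiod()) {
  pixels <- as.array(pixels)
  if (!(length(dim(pixels)) %in% c(2L, 3L)))
    stop("`pixels` must be a matrix or a rows x cols x channels array")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must lie in [0, 255]")
  if (is.null(clock_time)) clock_time <- (start_clock + timestamp / 60) %% 24
  if (is.null(condition)) condition <- clock_condition(clock_time, schedule)
  condition <- match.arg(condition, c("day", "night"))
  structure(list(pixels = pixels, timestamp = as.numeric(timestamp),
                 clock_time = as.numeric(clock_time) %% 24,
                 condition = condition),
            class = "taa_frame")
}

#' @export
print.taa_frame <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<taa_frame> %d x %d, %s, t = %.0f min (clock %05.2f h), %s\n",
              d[1], d[2], if (is_rgb(x$pixels)) "RGB" else "1-channel",
              x$timestamp, x$clock_time, x$condition))
  invisible(x)
}

#' Photoperiod schedule
#'
#' Lights-on / lights-off clock times in hours; defaults to the 12 h : 12 h
#' cycle with dawn at 8:00 and dusk at 20:00. The boundary instant belongs
#' to the period it starts: a frame taken exactly at lights-off is a night
#' frame, one exactly at lights-on a day frame.
#'
#' @param lights_on,lights_off Clock hours in `[0, 24)`.
#' @return An object of class `taa_photoperiod`.
#' @export
photoperiod <- function(lights_on = 8, lights_off = 20) {
  stopifnot(lights_on >= 0, lights_on < 24, lights_off >= 0, lights_off < 24,
            lights_on != lights_off)
  structure(list(lights_on = lights_on, lights_off = lights_off),
            class = "taa_photoperiod")
}

clock_condition <- function(clock_time, schedule) {
  on <- schedule$lights_on; off <- schedule$lights_off
  in_day <- if (on < off) clock_time >= on & clock_time < off
            else clock_time >= on | clock_time < off
  ifelse(in_day, "day", "night")
}

#' Construct an ordered image series
#'
#' @param frames List of [taa_frame()] objects with strictly increasing
#'   timestamps and identical pixel dimensions.
#' @param nominal_interval Nominal frame spacing in minutes (default 1).
#' @return An object of class `taa_series` (a list of frames with
#'   attributes).
#' @export
taa_series <- function(frames, nominal_interval = 1) {
  stopifnot(is.list(frames))
  if (length(frames)) {
    ts <- vapply(frames, function(f) f$timestamp, numeric(1))
    if (any(diff(ts) <= 0)) stop("frame timestamps must be strictly increasing")
    dims <- vapply(frames, function(f) paste(dim(f$pixels)[1:2], collapse = "x"),
                   character(1))
    if (length(unique(dims)) > 1L)
      stop("all frames in a series must share pixel dimensions")
  }
  structure(frames, nominal_interval = nominal_interval, class = "taa_series")
}

#' @export
print.taa_series <- function(x, ...) {
  cat(sprintf("<taa_series> %d frames", length(x)))
  if (length(x))
    cat(sprintf(", t = [%.0f, %.0f] min, %d day / %d night",
                x[[1]]$timestamp, x[[length(x)]]$timestamp,
                sum(series_conditions(x) == "day"),
                sum(series_conditions(x) == "night")))
  cat("\n")
  invisible(x)
}

series_timestamps <- function(series)
  vapply(unclass(series), function(f) f$timestamp, numeric(1))

series_conditions <- function(series)
  vapply(unclass(series), function(f) f$condition, character(1))

#' Split an image series into day and night partitions
#'
#' Every frame is assigned to exactly one partition by its clock time
#' against the photoperiod schedule; frames exactly at lights-off go to the
#' night partition and frames exactly at lights-on to the day partition.
#' The night partition carries the preceding day's final frame as its
#' reference frame (attribute `reference_frame`), mirroring the practice of
#' combining the night stack with the last image taken in the light.
#'
#' @param series A [taa_series()].
#' @param schedule A [photoperiod()].
#' @return A list with elements `day` and `night`, both `taa_series`.
#' @export
split_day_night <- function(series, schedule = photoperiod()) {
  conds <- if (length(series)) clock_condition(
    vapply(unclass(series), function(f) f$clock_time, numeric(1)), schedule)
    else character(0)
  frames <- unclass(series)
  day <- taa_series(frames[conds == "day"],
                    nominal_interval = attr(series, "nominal_interval"))
  night <- taa_series(frames[conds == "night"],
                      nominal_interval = attr(series, "nominal_interval"))
  if (length(night) && length(day)) {
    first_night_t <- night[[1]]$timestamp
    before <- Filter(function(f) f$timestamp < first_night_t, unclass(day))
    if (length(before))
      attr(night, "reference_frame") <- before[[length(before)]]
  }
  list(day = day, night = night)
}

#' Read an image frame from disk
#'
#' Supports PNG, TIFF and JPEG frame files. Single-channel files become
#' matrices, RGB(A) files `rows x cols x 3` arrays (alpha dropped);
#' intensities are rescaled to the 0-255 range.
#'
#' @param path Path to the image file.
#' @inheritParams taa_frame
#' @return A [taa_frame()].
#' @export
read_frame <- function(path, timestamp = NA_real_, clock_time = NULL,
                       condition = NULL, start_clock = 8,
                       schedule = photoperiod()) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG frames requires the 'jpeg' package")
      jpeg::readJPEG(path)
    },
    stop("unsupported frame format: .", ext, " (PNG/TIFF/JPEG frame files only)"))
  px <- raw * 255
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] >= 3L) px <- px[, , 1:3, drop = FALSE]
    else px <- px[, , 1]
  }
  if (is.na(timestamp)) {
    ti <- parse_frame_timestamp(path)
    timestamp <- ti$minutes
    if (is.null(clock_time)) clock_time <- ti$clock
  }
  taa_frame(px, timestamp, clock_time, condition, start_clock, schedule)
}

#' Write a frame to disk as PNG or TIFF
#'
#' @param frame A [taa_frame()] or a bare pixel array on the 0-255 scale.
#' @param path Output path; format chosen by extension.
#' @export
write_frame <- function(frame, path) {
  px <- if (inherits(frame, "taa_frame")) frame$pixels else frame
  img <- clamp(px / 255, 0, 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = , tiff = tiff::writeTIFF(img, path),
    stop("unsupported output format: .", ext))
  invisible(path)
}

# Parse `<prefix>_YYYYMMDD-HHMMSS.<ext>` filenames into absolute minutes
# (since 2000-01-01, only differences matter) and clock hours.
parse_frame_timestamp <- function(path) {
  m <- regmatches(basename(path),
                  regexpr("[0-9]{8}-[0-9]{6}", basename(path)))
  if (!length(m))
    stop("cannot parse timestamp from filename '", basename(path),
         "'; expected <prefix>_YYYYMMDD-HHMMSS.<ext>")
  t <- as.POSIXct(m, format = "%Y%m%d-%H%M%S", tz = "UTC")
  origin <- as.POSIXct("2000-01-01", tz = "UTC")
  lt <- as.POSIXlt(t)
  list(minutes = as.numeric(difftime(t, origin, units = "mins")),
       clock = lt$hour + lt$min / 60 + lt$sec / 3600)
}

#' Read an image series from a directory or manifest
#'
#' Frames are discovered either from `<prefix>_YYYYMMDD-HHMMSS.<ext>` file
#' names under `path`, or from a CSV manifest with columns `path` and
#' `timestamp_iso`. Timestamps are re-based to minutes since the first
#' frame; clock times come from the stamps themselves.
#'
#' @param path Directory of frame files, or a manifest CSV path.
#' @param schedule A [photoperiod()] used to flag day/night.
#' @param pattern Filename regexp used when `path` is a directory.
#' @param rebase Rebase timestamps to minutes since the first frame of
#'   this series (default). With `FALSE`, timestamps stay on the stamps'
#'   absolute minute scale so several series can share one time base.
#' @return A [taa_series()].
#' @export
read_series <- function(path, schedule = photoperiod(),
                        pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                        rebase = TRUE) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = pattern, full.names = TRUE)
    if (!length(files)) stop("no frame files found under ", path,
                             " (expected <prefix>_YYYYMMDD-HHMMSS.<ext>)")
    info <- lapply(files, parse_frame_timestamp)
    mins <- vapply(info, `[[`, numeric(1), "minutes")
    ord <- order(mins)
    files <- files[ord]; info <- info[ord]; mins <- mins[ord]
  } else if (file.exists(path)) {
    man <- read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("path", "timestamp_iso") %in% names(man)))
      stop("manifest must have columns 'path' and 'timestamp_iso'")
    t <- as.POSIXct(man$timestamp_iso, tz = "UTC")
    ord <- order(t)
    files <- man$path[ord]
    lt <- as.POSIXlt(t[ord])
    mins <- as.numeric(difftime(t[ord], min(t), units = "mins"))
    info <- Map(function(m, h) list(minutes = m, clock = h),
                mins, lt$hour + lt$min / 60 + lt$sec / 3600)
  } else stop("no such file or directory: ", path)
  if (rebase) mins <- mins - mins[1]
  frames <- Map(function(f, i, m) read_frame(f, timestamp = m,
                                             clock_time = i$clock,
                                             schedule = schedule),
                files, info, mins)
  taa_series(unname(frames))
}
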