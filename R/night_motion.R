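#' Per-spikelet nighttime crop stack
#'
#' @param spikelet_id Identifier (string or integer).
#' @param frames A `rows x cols x n` array of single-channel crops on the
#'   0-255 scale, ordered in time.
#' @param timestamps Minutes, strictly increasing, one per frame.
#' @param bbox Optional originating bounding box (0-based half-open, in
#'   full-frame coordinates).
#' @return An object of class `taa_track`.
#' @export
spikelet_track <- function(spikelet_id, frames, timestamps, bbox = NULL) {
  frames <- as.array(frames)
  if (length(dim(frames)) != 3L)
    stop("`frames` must be a rows x cols x n_frames array")
  if (dim(frames)[3] != length(timestamps))
    stop("one timestamp per frame required")
  if (any(diff(timestamps) <= 0))
    stop("track timestamps must be strictly increasing")
  structure(list(spikelet_id = spikelet_id, frames = frames,
                 timestamps = as.numeric(timestamps), bbox = bbox),
            class = "taa_track")
}

#' @export
print.taa_track <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<taa_track> '%s': %d x %d crop, %d frames, t = [%.0f, %.0f] min%s\n",
              x$spikelet_id, d[1], d[2], d[3], x$timestamps[1],
              x$timestamps[d[3]],
              if (isTRUE(attr(x, "stabilized"))) " (stabilized)" else ""))
  invisible(x)
}

#' Intensity-weighted centroid of a crop
#'
#' Coordinates are 0-based, so a single bright pixel at array position
#' `(4, 6)` has centroid `(3, 5)` and a uniform 10x10 crop `(4.5, 4.5)`.
#'
#' @param crop A single-channel matrix of non-negative intensities with
#'   nonzero total.
#' @return `c(row, col)`, real-valued.
#' @export
intensity_centroid <- function(crop) {
  tot <- sum(crop)
  if (tot <= 0) stop("all-zero crop: intensity centroid undefined")
  rows <- seq_len(nrow(crop)) - 1
  cols <- seq_len(ncol(crop)) - 1
  c(row = sum(rowSums(crop) * rows) / tot,
    col = sum(colSums(crop) * cols) / tot)
}

# Translate a matrix by integer (drow, dcol), zero-filling exposed
# borders: out[i + drow, j + dcol] = in[i, j].
shift_matrix <- function(m, drow, dcol, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m)); src_c <- seq_len(ncol(m))
  dst_r <- src_r + drow; dst_c <- src_c + dcol
  keep_r <- dst_r >= 1 & dst_r <= nrow(m)
  keep_c <- dst_c >= 1 & dst_c <= ncol(m)
  out[dst_r[keep_r], dst_c[keep_c]] <- m[src_r[keep_r], src_c[keep_c]]
  out
}

#' Stabilise a spikelet track against panicle drift
#'
#' Each frame is translated by the integer-rounded shift that aligns its
#' intensity centroid with the first frame's centroid, compensating slow
#' drift from panicle growth or vibration. Exposed borders are
#' zero-filled; the attribute `valid_mask` marks pixels observed in every
#' shifted frame, and downstream change fractions are computed over that
#' mask only. A frame whose required shift exceeds half the crop size is
#' left unshifted with a warning (pathological drift).
#'
#' @param track A [spikelet_track()] whose frames all have nonzero
#'   intensity.
#' @return The stabilised `taa_track`, with attributes `valid_mask` and
#'   `stabilized = TRUE`. Applying the operation again is a no-op.
#' @export
stabilize <- function(track) {
  stopifnot(inherits(track, "taa_track"))
  fr <- track$frames
  n <- dim(fr)[3]
  ref <- intensity_centroid(fr[, , 1])
  valid <- matrix(TRUE, dim(fr)[1], dim(fr)[2])
  for (k in seq_len(n)) {
    ck <- intensity_centroid(fr[, , k])
    s <- round(ref - ck)
    if (any(abs(s) > dim(fr)[1:2] / 2)) {
      warning(sprintf("track '%s' frame %d: drift (%g, %g) exceeds half the crop; not shifted",
                      track$spikelet_id, k, s[1], s[2]))
      next
    }
    if (any(s != 0)) {
      fr[, , k] <- shift_matrix(fr[, , k], s[1], s[2])
      valid <- valid & shift_matrix(matrix(TRUE, nrow(valid), ncol(valid)),
                                    s[1], s[2], fill = FALSE)
    }
  }
  track$frames <- fr
  attr(track, "valid_mask") <- valid
  attr(track, "stabilized") <- TRUE
  track
}

#' Motion-detector configuration
#'
#' Defaults implement the canonical rule: within 30-minute windows, a
#' frame signals opening when at least 5% of its pixels change intensity
#' (relative to the window's first frame) by strictly more than 50% of the
#' bit-depth maximum (255 for 8-bit).
#'
#' @param window_minutes Window length in minutes.
#' @param pixel_fraction_threshold Minimum changed-pixel fraction
#'   (inclusive).
#' @param intensity_fraction_threshold Intensity-change criterion as a
#'   fraction of `bit_depth_max` (exclusive).
#' @param bit_depth_max Maximum representable intensity.
#' @return A `taa_motion_config` list.
#' @export
motion_config <- function(window_minutes = 30, pixel_fraction_threshold = 0.05,
                          intensity_fraction_threshold = 0.5,
                          bit_depth_max = 255) {
  stopifnot(window_minutes > 0,
            pixel_fraction_threshold > 0, pixel_fraction_threshold <= 1,
            intensity_fraction_threshold > 0, intensity_fraction_threshold <= 1)
  structure(list(window_minutes = window_minutes,
                 pixel_fraction_threshold = pixel_fraction_threshold,
                 intensity_fraction_threshold = intensity_fraction_threshold,
                 bit_depth_max = bit_depth_max),
            class = "taa_motion_config")
}

#' Segment a track into consecutive time windows
#'
#' Windows are consecutive, non-overlapping spans of `window_minutes`
#' starting at the first timestamp; the last window may be shorter.
#'
#' @param track A [spikelet_track()] (or a numeric timestamp vector).
#' @param window_minutes Window length in minutes.
#' @return A list of integer frame-index vectors, one per window.
#' @export
segment_windows <- function(track, window_minutes = 30) {
  ts <- if (inherits(track, "taa_track")) track$timestamps else track
  stopifnot(window_minutes > 0, length(ts) >= 1)
  bin <- floor((ts - ts[1]) / window_minutes)
  unname(split(seq_along(ts), bin))
}

#' Detect a flower-opening event in one spikelet track
#'
#' Within every window, each frame is differenced against the window's
#' first frame. A pixel counts as changed when its absolute intensity
#' difference exceeds `intensity_fraction_threshold * bit_depth_max`; a
#' frame triggers when the changed fraction (over the stabilisation
#' validity mask) reaches `pixel_fraction_threshold`. The earliest
#' triggering frame across all windows defines the time of anther
#' appearance (TAA); movement often spans several minutes, so later
#' triggering windows are ignored.
#'
#' Each window's reference is additionally differenced against the first
#' frame of the following window: a window's first frame is its own
#' reference, so without the one-frame overlap an event landing exactly
#' on a window boundary would be invisible to both adjacent windows.
#'
#' @param track A [spikelet_track()]; stabilised automatically (see
#'   [stabilize()]) unless already done.
#' @param config A [motion_config()].
#' @return A `taa_opening_call`: list with `spikelet_id`, `opened`,
#'   `taa_timestamp` (`NA` when not opened), `window_index` and
#'   `fraction_changed`.
#' @export
detect_opening <- function(track, config = motion_config()) {
  stopifnot(inherits(track, "taa_track"))
  if (!isTRUE(attr(track, "stabilized"))) track <- stabilize(track)
  mask <- attr(track, "valid_mask") %||%
    matrix(TRUE, dim(track$frames)[1], dim(track$frames)[2])
  n_valid <- sum(mask)
  cut <- config$intensity_fraction_threshold * config$bit_depth_max
  windows <- segment_windows(track, config$window_minutes)
  for (w in seq_along(windows)) {
    idx <- windows[[w]]
    # overlap: also test the next window's first frame against this
    # reference, so boundary-frame events are not invisible
    if (w < length(windows)) idx <- c(idx, windows[[w + 1]][1])
    ref <- track$frames[, , idx[1]][mask]
    for (j in idx[-1]) {
      frac <- sum(abs(track$frames[, , j][mask] - ref) > cut) / n_valid
      if (frac >= config$pixel_fraction_threshold) {
        return(structure(list(spikelet_id = track$spikelet_id, opened = TRUE,
                              taa_timestamp = track$timestamps[j],
                              window_index = w, fraction_changed = frac),
                         class = "taa_opening_call"))
      }
    }
  }
  structure(list(spikelet_id = track$spikelet_id, opened = FALSE,
                 taa_timestamp = NA_real_, window_index = NA_integer_,
                 fraction_changed = NA_real_),
            class = "taa_opening_call")
}

#' @export
print.taa_opening_call <- function(x, ...) {
  if (x$opened)
    cat(sprintf("<taa_opening_call> '%s': opened at %.0f min (window %d, %.1f%% pixels changed)\n",
                x$spikelet_id, x$taa_timestamp, x$window_index,
                100 * x$fraction_changed))
  else cat(sprintf("<taa_opening_call> '%s': no opening detected\n",
                   x$spikelet_id))
  invisible(x)
}

#' Call nighttime opening events for all closed spikelets
#'
#' The last daytime frame locates every spikelet (either from its
#' classifier tile calls or from an annotation data frame); spikelets
#' closed at lights-off are tracked through the night by cropping their
#' (padded) bounding box out of every night frame, stabilising, and
#' running [detect_opening()]. Spikelets already open at dusk are
#' excluded — a flower cannot open both at night and in the day.
#'
#' @param last_day_calls A `taa_tile_calls` from [classify_image()] on the
#'   last light frame, or an annotation data frame with labels.
#' @param night A [taa_series()] of single-channel night frames.
#' @param config A [motion_config()].
#' @param pad Pixels of padding added around each bounding box before
#'   cropping (default 4), giving drift headroom.
#' @return A list of `taa_opening_call`s, one per closed spikelet; see
#'   [opening_calls_df()] for a tabular view.
#' @export
call_night_openings <- function(last_day_calls, night,
                                config = motion_config(), pad = 4) {
  if (!length(night)) stop("empty night series: nothing to analyse")
  boxes <- if (inherits(last_day_calls, "taa_tile_calls"))
    tile_bboxes(last_day_calls, "closed")
  else {
    validate_annotations(last_day_calls)
    last_day_calls[last_day_calls$label == "closed", , drop = FALSE]
  }
  if (!nrow(boxes)) return(list())
  d <- dim(night[[1]]$pixels)[1:2]
  ts <- series_timestamps(night)
  lapply(seq_len(nrow(boxes)), function(i) {
    b <- boxes[i, ]
    r <- c(max(0, b$row_min - pad), min(d[1], b$row_max + pad))
    cc <- c(max(0, b$col_min - pad), min(d[2], b$col_max + pad))
    stack <- vapply(unclass(night),
                    function(f) f$pixels[(r[1] + 1):r[2], (cc[1] + 1):cc[2]],
                    matrix(0, r[2] - r[1], cc[2] - cc[1]))
    tr <- spikelet_track(as.character(i), stack, ts,
                         bbox = c(b$row_min, b$col_min, b$row_max, b$col_max))
    cl <- detect_opening(tr, config)
    cl$bbox <- tr$bbox
    cl
  })
}

#' Tabulate opening calls
#'
#' @param calls List of `taa_opening_call`s.
#' @param start_clock Clock time (hours) at experiment minute 0, used to
#'   derive `taa_clock`.
#' @return Data frame with one row per call (`spikelet_id`, `opened`,
#'   `taa_minutes`, `taa_clock`, `window_index`, `fraction_changed`).
#' @export
opening_calls_df <- function(calls, start_clock = 8) {
  if (!length(calls))
    return(data.frame(spikelet_id = character(0), opened = logical(0),
                      taa_minutes = numeric(0), taa_clock = numeric(0),
                      window_index = integer(0), fraction_changed = numeric(0)))
  data.frame(
    spikelet_id = vapply(calls, function(x) as.character(x$spikelet_id), ""),
    opened = vapply(calls, `[[`, logical(1), "opened"),
    taa_minutes = vapply(calls, `[[`, numeric(1), "taa_timestamp"),
    taa_clock = (start_clock + vapply(calls, `[[`, numeric(1),
                                      "taa_timestamp") / 60) %% 24,
    window_index = vapply(calls, function(x) as.integer(x$window_index),
                          integer(1)),
    fraction_changed = vapply(calls, `[[`, numeric(1), "fraction_changed"))
}
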