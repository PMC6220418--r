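## Seeded generators for every input the pipeline consumes, with ground
## truth carried alongside. Rendering is deliberately simple (ellipses,
## discs, strips): the pipeline's operators are under test, not
## photorealism. Every generator is a pure function of its spec — the seed
## is part of the spec and global RNG state is left untouched.

#' Day-scene specification
#'
#' @param seed RNG seed (part of the scene identity).
#' @param dim `c(rows, cols)`, each >= 34.
#' @param n_closed,n_open Spikelet counts.
#' @param n_background Number of background boxes annotated (texture
#'   samples for classifier training).
#' @param n_bristles Thin pale strokes added to the background texture.
#' @param noise_sd Gaussian pixel noise (0-255 scale).
#' @return A `taa_day_scene_spec` list.
#' @export
day_scene_spec <- function(seed = 1, dim = c(340, 340), n_closed = 6,
                           n_open = 4, n_background = 20, n_bristles = 0,
                           noise_sd = 8) {
  stopifnot(all(dim >= 34), n_closed >= 0, n_open >= 0, n_background >= 0,
            noise_sd >= 0)
  structure(list(seed = seed, dim = dim, n_closed = n_closed, n_open = n_open,
                 n_background = n_background, n_bristles = n_bristles,
                 noise_sd = noise_sd),
            class = "taa_day_scene_spec")
}

# Paint a filled ellipse onto an RGB array (in place semantics via return).
paint_ellipse <- function(px, center, radii, color, angle = 0) {
  d <- dim(px)
  rr <- max(1, floor(center[1] - max(radii))):min(d[1], ceiling(center[1] + max(radii)))
  cc <- max(1, floor(center[2] - max(radii))):min(d[2], ceiling(center[2] + max(radii)))
  dr <- outer(rr - center[1], rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - center[2])
  u <- dr * cos(angle) + dc * sin(angle)
  v <- -dr * sin(angle) + dc * cos(angle)
  inside <- (u / radii[1])^2 + (v / radii[2])^2 <= 1
  for (ch in 1:3) {
    sl <- px[rr, cc, ch]
    sl[inside] <- color[ch]
    px[rr, cc, ch] <- sl
  }
  px
}

# Sample `n` points with pairwise separation >= min_sep inside margins.
sample_centers <- function(n, dim, margin, min_sep, max_tries = 2000) {
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(pts) < n) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("could not place ", n, " objects without overlap; ",
           "use a larger scene or fewer objects")
    p <- c(runif(1, margin, dim[1] - margin), runif(1, margin, dim[2] - margin))
    if (!nrow(pts) || min(sqrt(rowSums(sweep(pts, 2, p)^2))) >= min_sep)
      pts <- rbind(pts, p)
  }
  pts
}

#' Generate a synthetic daytime panicle scene with annotations
#'
#' Renders a textured background with closed spikelets (compact green
#' ellipses), open spikelets (the same ellipses with protruding bright
#' anther dots) and optional bristle strokes, and emits one 34x34
#' annotation box per spikelet plus background boxes sampled away from
#' any spikelet. Regeneration from the same spec is bit-identical.
#'
#' @param spec A [day_scene_spec()].
#' @return List with `frame` (a day [taa_frame()]), `annotations` (data
#'   frame, see [parse_annotations()]) and `truth` (spikelet centers and
#'   labels).
#' @export
make_day_scene <- function(spec = day_scene_spec()) {
  stopifnot(inherits(spec, "taa_day_scene_spec"))
  with_seed(spec$seed, {
    d <- spec$dim
    base <- c(125, 105, 75)                       # brownish canopy litter
    px <- array(0, c(d, 3))
    for (ch in 1:3)
      px[, , ch] <- base[ch] + matrix(rnorm(prod(d), 0, spec$noise_sd), d[1], d[2])
    if (spec$n_bristles > 0) {
      for (i in seq_len(spec$n_bristles)) {
        r0 <- runif(1, 5, d[1] - 5); c0 <- runif(1, 5, d[2] - 5)
        ang <- runif(1, 0, pi); len <- runif(1, 15, 40)
        t <- seq(0, len, by = 0.5)
        rr <- clamp(round(r0 + t * cos(ang)), 1, d[1])
        cc <- clamp(round(c0 + t * sin(ang)), 1, d[2])
        for (ch in 1:3) px[cbind(rr, cc, ch)] <- c(170, 160, 120)[ch]
      }
    }
    n_spike <- spec$n_closed + spec$n_open
    ann <- empty_annotations()
    truth <- data.frame(row = numeric(0), col = numeric(0),
                        label = character(0))
    if (n_spike > 0) {
      centers <- sample_centers(n_spike, d, margin = 20, min_sep = 36)
      labels <- sample(c(rep("closed", spec$n_closed),
                         rep("open", spec$n_open)))
      for (i in seq_len(n_spike)) {
        ctr <- centers[i, ]
        col_jit <- c(70, 150, 70) + rnorm(3, 0, 6)
        px <- paint_ellipse(px, ctr, radii = c(9, 6) + runif(2, -1, 1),
                            color = col_jit, angle = runif(1, 0, pi))
        if (labels[i] == "open") {
          n_dots <- sample(3:5, 1)
          th <- runif(n_dots, 0, 2 * pi)
          for (k in seq_len(n_dots))
            px <- paint_ellipse(px, ctr + 9 * c(cos(th[k]), sin(th[k])),
                                radii = c(2.2, 2.2),
                                color = c(245, 240, 190))
        }
      }
      half <- 17
      bc <- function(x, lim) clamp(round(x), half, lim - half)
      ann <- data.frame(label = labels,
                        row_min = bc(centers[, 1], d[1]) - half,
                        col_min = bc(centers[, 2], d[2]) - half,
                        row_max = bc(centers[, 1], d[1]) + half,
                        col_max = bc(centers[, 2], d[2]) + half)
      truth <- data.frame(row = centers[, 1], col = centers[, 2],
                          label = labels)
    }
    if (spec$n_background > 0) {
      half <- 17
      bg <- matrix(numeric(0), 0, 2)
      while (nrow(bg) < spec$n_background) {
        p <- c(runif(1, half, spec$dim[1] - half),
               runif(1, half, spec$dim[2] - half))
        if (!n_spike ||
            min(sqrt(rowSums(sweep(as.matrix(truth[, c("row", "col")]),
                                   2, p)^2))) >= 30)
          bg <- rbind(bg, p)
      }
      ann <- rbind(ann,
                   data.frame(label = "background",
                              row_min = round(bg[, 1]) - half,
                              col_min = round(bg[, 2]) - half,
                              row_max = round(bg[, 1]) + half,
                              col_max = round(bg[, 2]) + half))
    }
    px <- clamp(px, 0, 255)
    list(frame = taa_frame(px, timestamp = 240, clock_time = 12,
                           condition = "day"),
         annotations = ann, truth = truth)
  })
}

#' Night-series specification
#'
#' Defaults emulate one 12 h night imaged once per minute: 720
#' single-channel 34x34 crops per spikelet starting at dusk (experiment
#' minute 720, clock 20:00), with a dim spikelet blob on a dark
#' background, optional scripted opening events, a shared integer drift
#' trajectory and Gaussian noise. An opening adds a bright anther patch
#' covering at least `affected_fraction` of the crop at
#' `amplitude * 255` above the underlying scene from its opening frame
#' onward.
#'
#' @param seed RNG seed.
#' @param n_spikelets Number of spikelet stacks.
#' @param crop_dim `c(rows, cols)` per crop.
#' @param n_frames Frames per stack.
#' @param interval Minutes between frames.
#' @param t_start Experiment minute of the first frame (720 = dusk under
#'   the default 8:00 start).
#' @param opening_times Minutes-from-series-start of each spikelet's
#'   scripted opening (`NA` = never opens); recycled to `n_spikelets`.
#' @param amplitude Opening signal as a fraction of the bit depth.
#' @param affected_fraction Minimum fraction of crop pixels the anther
#'   patch covers.
#' @param drift_max Drift trajectory bound in pixels (integer random
#'   walk, shared by all spikelets).
#' @param noise_sd Gaussian noise sd (0-255 scale).
#' @param bg_level,blob_level Background and spikelet-blob intensities;
#'   their contrast is kept below the 50% intensity criterion, as in IR
#'   imagery where only the emerging anthers are bright.
#' @return A `taa_night_series_spec` list.
#' @export
night_series_spec <- function(seed = 1, n_spikelets = 1, crop_dim = c(34, 34),
                              n_frames = 720, interval = 1, t_start = 720,
                              opening_times = NA, amplitude = 0.8,
                              affected_fraction = 0.1, drift_max = 3,
                              noise_sd = 8, bg_level = 15, blob_level = 110) {
  opening_times <- rep_len(opening_times, n_spikelets)
  span <- n_frames * interval
  if (any(!is.na(opening_times) &
          (opening_times < interval | opening_times >= span)))
    stop("scripted opening times must lie within the series span")
  stopifnot(affected_fraction > 0, affected_fraction <= 1,
            amplitude >= 0, amplitude <= 1)
  structure(list(seed = seed, n_spikelets = n_spikelets, crop_dim = crop_dim,
                 n_frames = n_frames, interval = interval, t_start = t_start,
                 opening_times = opening_times, amplitude = amplitude,
                 affected_fraction = affected_fraction, drift_max = drift_max,
                 noise_sd = noise_sd, bg_level = bg_level,
                 blob_level = blob_level),
            class = "taa_night_series_spec")
}

# Integer drift random walk clamped to [-drift_max, drift_max], n x 2.
drift_trajectory <- function(n, drift_max) {
  if (drift_max == 0) return(matrix(0L, n, 2))
  steps <- matrix(sample(c(-1L, 0L, 1L), 2 * n, replace = TRUE), n, 2)
  steps[1, ] <- 0L
  traj <- apply(steps, 2, cumsum)
  clamp(traj, -drift_max, drift_max)
}

#' Generate synthetic nighttime spikelet stacks with ground truth
#'
#' @param spec A [night_series_spec()].
#' @return List with `tracks` (list of [spikelet_track()]s), `truth`
#'   (data frame `spikelet_id`, `opens`, `open_minute` — minutes from
#'   series start) and the `spec`.
#' @export
make_night_series <- function(spec = night_series_spec()) {
  stopifnot(inherits(spec, "taa_night_series_spec"))
  with_seed(spec$seed, {
    d <- spec$crop_dim
    ts <- spec$t_start + (seq_len(spec$n_frames) - 1) * spec$interval
    center <- (d + 1) / 2
    blob_r <- min(d) / 4
    patch_r <- ceiling(sqrt(spec$affected_fraction * prod(d) / pi))
    rows <- matrix(seq_len(d[1]), d[1], d[2])
    cols <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
    tracks <- vector("list", spec$n_spikelets)
    for (s in seq_len(spec$n_spikelets)) {
      blob <- ((rows - center[1]) / blob_r)^2 +
              ((cols - center[2]) / (blob_r * 0.75))^2 <= 1
      scene <- matrix(spec$bg_level, d[1], d[2])
      scene[blob] <- spec$blob_level
      # anther patch straddles the blob edge (half on, half off)
      pang <- runif(1, 0, 2 * pi)
      pc <- center + blob_r * c(cos(pang), 0.75 * sin(pang))
      patch <- (rows - pc[1])^2 + (cols - pc[2])^2 <= patch_r^2
      open_t <- spec$opening_times[s]
      open_frame <- if (is.na(open_t)) Inf else
        which(ts - spec$t_start >= open_t)[1]
      traj <- drift_trajectory(spec$n_frames, spec$drift_max)
      stack <- array(0, c(d, spec$n_frames))
      for (k in seq_len(spec$n_frames)) {
        fr <- scene
        if (k >= open_frame)
          fr[patch] <- fr[patch] + spec$amplitude * 255
        fr <- shift_matrix(fr, traj[k, 1], traj[k, 2], fill = spec$bg_level)
        if (spec$noise_sd > 0)
          fr <- fr + matrix(rnorm(prod(d), 0, spec$noise_sd), d[1], d[2])
        stack[, , k] <- clamp(fr, 0, 255)
      }
      tracks[[s]] <- spikelet_track(as.character(s), stack, ts)
    }
    truth <- data.frame(spikelet_id = as.character(seq_len(spec$n_spikelets)),
                        opens = !is.na(spec$opening_times),
                        open_minute = spec$opening_times)
    list(tracks = tracks, truth = truth, spec = spec)
  })
}

#' Generate a synthetic binary panicle mask with known bristles
#'
#' A triangular panicle body with its apex at `apex_row` widening towards
#' the image bottom, plus `n_bristles` one-pixel-wide strokes leaving the
#' flanks, with their base and tip pixels recorded.
#'
#' @param n_bristles Number of bristles (placed alternately on the two
#'   flanks, spaced apart so no two touch).
#' @param apex_row 0-based apex row.
#' @param dims `c(rows, cols)`.
#' @param seed RNG seed.
#' @param bristle_length Stroke length in pixels.
#' @return List with `mask` (logical) and `truth` (`n_bristles`,
#'   `apex_row`, `bases`, `tips`).
#' @export
make_panicle_mask <- function(n_bristles = 5, apex_row = 20,
                              dims = c(200, 160), seed = 1,
                              bristle_length = 18) {
  stopifnot(n_bristles >= 0, apex_row >= 0, apex_row < dims[1] - 10)
  with_seed(seed, {
    nr <- dims[1]; nc <- dims[2]
    midc <- (nc + 1) / 2
    # leave room for bristles but keep the flanks gentle so pixel
    # rounding of the bases maps to small apex error
    bottom_halfw <- max(nc / 4, nc / 2 - bristle_length - 8)
    mask <- matrix(FALSE, nr, nc)
    halfw <- function(r)                      # 1-based row -> half width
      pmax(1, bottom_halfw * (r - (apex_row + 1)) / (nr - (apex_row + 1)))
    for (r in (apex_row + 1):nr) {
      w <- halfw(r)
      mask[r, max(1, round(midc - w)):min(nc, round(midc + w))] <- TRUE
    }
    bases <- tips <- list()
    if (n_bristles > 0) {
      # keep clear of the apex so no bristle touches the narrow tip
      lo <- apex_row + 1 + 25; hi <- nr - 8
      if (hi - lo < 6 * n_bristles)
        stop("panicle too short to place ", n_bristles,
             " separated bristles; enlarge `dims`")
      rows_at <- round(seq(lo, hi, length.out = n_bristles))
      for (i in seq_len(n_bristles)) {
        side <- if (i %% 2 == 1) 1 else -1    # alternate right/left flank
        r0 <- rows_at[i]
        c0 <- round(midc + side * halfw(r0))
        ang <- side * runif(1, -0.25, 0.25)   # mostly horizontal, jittered
        dirc <- side * cos(ang); dirr <- sin(ang)
        t <- seq(1, bristle_length, by = 0.5)
        rr <- clamp(round(r0 + t * dirr), 1, nr)
        cc <- clamp(round(c0 + t * dirc), 1, nc)
        mask[cbind(rr, cc)] <- TRUE
        bases[[i]] <- c(row = r0 - 1, col = c0 - 1)
        tips[[i]] <- c(row = rr[length(rr)] - 1, col = cc[length(cc)] - 1)
      }
    }
    list(mask = mask,
         truth = list(n_bristles = n_bristles, apex_row = apex_row,
                      bases = as.data.frame(do.call(rbind, bases) %||%
                                              cbind(row = numeric(0),
                                                    col = numeric(0))),
                      tips = as.data.frame(do.call(rbind, tips) %||%
                                             cbind(row = numeric(0),
                                                   col = numeric(0)))))
  })
}

#' Generate a synthetic leaf mask with known midline length
#'
#' Builds a constant-width strip around a midline interpolated through
#' the control points (rows strictly increasing); the true length is the
#' arc length of the per-row interpolated midline polyline.
#'
#' @param control_points Data frame with columns `row` and `col`
#'   (0-based), rows strictly increasing.
#' @param width Strip width in pixels.
#' @param dims `c(rows, cols)`.
#' @return List with `mask` and `true_length`.
#' @export
make_leaf_mask <- function(control_points, width = 9, dims = c(120, 60)) {
  stopifnot(is.data.frame(control_points), nrow(control_points) >= 2,
            all(diff(control_points$row) > 0))
  rows <- control_points$row[1]:control_points$row[nrow(control_points)]
  cols <- stats::approx(control_points$row, control_points$col,
                        xout = rows)$y
  mask <- matrix(FALSE, dims[1], dims[2])
  half <- (width - 1) / 2
  for (i in seq_along(rows)) {
    r <- rows[i] + 1
    if (r < 1 || r > dims[1]) next
    c1 <- clamp(round(cols[i] - half), 0, dims[2] - 1) + 1
    c2 <- clamp(round(cols[i] + half), 0, dims[2] - 1) + 1
    mask[r, c1:c2] <- TRUE
  }
  true_length <- sum(sqrt(diff(rows)^2 + diff(cols)^2))
  list(mask = mask, true_length = true_length)
}

#' Draw leaf emergence hours from a wrapped unimodal distribution
#'
#' Hours are drawn as `(peak_hour + N(0, 1/sqrt(concentration))) mod 24`:
#' a wrapped normal centred on `peak_hour` whose spread shrinks with
#' `concentration` (infinite concentration collapses every event onto the
#' peak).
#'
#' @param peak_hour Modal hour of day in `[0, 24)`.
#' @param concentration Inverse variance in hours^-2, > 0 (may be `Inf`).
#' @param n Number of events, >= 1.
#' @param seed RNG seed.
#' @return Numeric vector of `n` hours in `[0, 24)`.
#' @export
make_emergence_schedule <- function(peak_hour, concentration, n, seed = 1) {
  stopifnot(n >= 1, concentration > 0, peak_hour >= 0, peak_hour < 24)
  with_seed(seed, {
    sd <- if (is.infinite(concentration)) 0 else 1 / sqrt(concentration)
    (peak_hour + rnorm(n, 0, sd)) %% 24
  })
}
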