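#' Experiment-simulation specification
#'
#' Conditions for a full simulated imaging run: one panicle scene imaged
#' through a dusk frame, a 12 h night at one frame per minute, and a dawn
#' frame. Spikelets are laid out on the 34-pixel tile lattice; a subset is
#' already open at dusk, and a scripted subset of the closed ones opens
#' during the night.
#'
#' @param seed RNG seed.
#' @param dim Scene `c(rows, cols)`; multiples of 34 keep tiles aligned.
#' @param n_spikelets Total spikelets in the scene.
#' @param n_open_at_dusk Spikelets already open in the last light image.
#' @param n_night_open Closed spikelets that open during the night.
#' @param night_minutes Night length (default 720 = 12 h).
#' @param interval Minutes between night frames.
#' @param amplitude,drift_max,noise_sd As in [night_series_spec()].
#' @param n_train_scenes,train_counts,validation_counts Training corpus
#'   for the day classifier: scenes via [make_day_scene()] and per-class
#'   crop counts in the canonical 10:2:1 proportion.
#' @return A `taa_experiment_spec` list.
#' @export
experiment_spec <- function(seed = 1, dim = c(204, 204), n_spikelets = 8,
                            n_open_at_dusk = 2, n_night_open = 4,
                            night_minutes = 720, interval = 1,
                            amplitude = 0.8, drift_max = 3, noise_sd = 8,
                            n_train_scenes = 4,
                            train_counts = c(background = 400, closed = 80,
                                             open = 40),
                            validation_counts = NULL) {
  stopifnot(n_open_at_dusk + n_night_open <= n_spikelets,
            all(dim %% 34 == 0), night_minutes >= 60)
  structure(list(seed = seed, dim = dim, n_spikelets = n_spikelets,
                 n_open_at_dusk = n_open_at_dusk, n_night_open = n_night_open,
                 night_minutes = night_minutes, interval = interval,
                 amplitude = amplitude, drift_max = drift_max,
                 noise_sd = noise_sd, n_train_scenes = n_train_scenes,
                 train_counts = train_counts,
                 validation_counts = validation_counts),
            class = "taa_experiment_spec")
}

# Render one full-scene day frame given spikelet centers and open flags.
render_day_frame <- function(dim, centers, open_flags, noise_sd) {
  base <- c(125, 105, 75)
  px <- array(0, c(dim, 3))
  for (ch in 1:3)
    px[, , ch] <- base[ch] + matrix(rnorm(prod(dim), 0, noise_sd),
                                    dim[1], dim[2])
  for (i in seq_len(nrow(centers))) {
    ctr <- centers[i, ]
    px <- paint_ellipse(px, ctr, radii = c(9, 6), color = c(70, 150, 70))
    if (open_flags[i]) {
      th <- seq(0, 2 * pi, length.out = 6)[1:5]
      for (k in seq_along(th))
        px <- paint_ellipse(px, ctr + 9 * c(cos(th[k]), sin(th[k])),
                            radii = c(2.2, 2.2), color = c(245, 240, 190))
    }
  }
  clamp(px, 0, 255)
}

# Render one full-scene night (IR) frame.
render_night_frame <- function(dim, centers, patch_centers, patch_on,
                               shift, noise_sd, patch_r,
                               bg_level = 15, blob_level = 110,
                               amplitude = 0.8) {
  rows <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cols <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  fr <- matrix(bg_level, dim[1], dim[2])
  for (i in seq_len(nrow(centers))) {
    blob <- ((rows - centers[i, 1]) / 8)^2 + ((cols - centers[i, 2]) / 6)^2 <= 1
    fr[blob] <- blob_level
  }
  for (i in which(patch_on)) {
    patch <- (rows - patch_centers[i, 1])^2 +
             (cols - patch_centers[i, 2])^2 <= patch_r^2
    fr[patch] <- fr[patch] + amplitude * 255
  }
  fr <- shift_matrix(fr, shift[1], shift[2], fill = bg_level)
  clamp(fr + matrix(rnorm(prod(dim), 0, noise_sd), dim[1], dim[2]), 0, 255)
}

#' Simulate a complete imaging experiment on disk
#'
#' Writes a directory layout mirroring a real run — `day/` and `night/`
#' frame PNGs named `<prefix>_YYYYMMDD-HHMMSS.png`, training scenes with
#' VOC XML under `train/`, a ground-truth CSV and a run config — ready
#' for [run_pipeline()]. The experiment clock starts at 8:00 (dawn) on
#' day one; the dusk frame is taken at 20:00, night frames through the
#' 12 h dark period, and the dawn frame at 8:00 the next day.
#'
#' @param dir Output directory (created).
#' @param spec An [experiment_spec()].
#' @return The ground-truth data frame, invisibly (also written to
#'   `truth.csv`).
#' @export
simulate_experiment <- function(dir, spec = experiment_spec()) {
  stopifnot(inherits(spec, "taa_experiment_spec"))
  seeds <- child_seeds(spec$seed, 6 + spec$n_train_scenes)
  for (sub in c("day", "night", "train", "out"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  d <- spec$dim
  with_seed(seeds[1], {
    # spikelet centers on distinct 34-px tile centers (interior tiles)
    n_tr <- d[1] %/% 34; n_tc <- d[2] %/% 34
    cells <- expand.grid(tr = 2:(n_tr - 1), tc = 2:(n_tc - 1))
    if (nrow(cells) < spec$n_spikelets)
      stop("scene too small for ", spec$n_spikelets, " spikelets")
    cells <- cells[sample(nrow(cells), spec$n_spikelets), ]
    centers <- cbind((cells$tr - 1) * 34 + 17.5, (cells$tc - 1) * 34 + 17.5)
    status <- sample(c(rep("open_at_dusk", spec$n_open_at_dusk),
                       rep("night_open", spec$n_night_open),
                       rep("closed", spec$n_spikelets - spec$n_open_at_dusk -
                             spec$n_night_open)))
    night_span <- spec$night_minutes
    open_minute <- rep(NA_real_, spec$n_spikelets)
    open_minute[status == "night_open"] <-
      sort(round(runif(spec$n_night_open, 5, night_span - 35)))
    pang <- runif(spec$n_spikelets, 0, 2 * pi)
    patch_centers <- centers + 8 * cbind(cos(pang), sin(pang))
    patch_r <- ceiling(sqrt(0.1 * 34 * 34 / pi))
    truth <- data.frame(spikelet_id = seq_len(spec$n_spikelets),
                        row = centers[, 1] - 1, col = centers[, 2] - 1,
                        status = status, open_minute = open_minute,
                        open_clock = (20 + open_minute / 60) %% 24)
    # --- day frames: dawn-ish, midday, dusk (last light), next dawn ---
    t0 <- as.POSIXct("2026-01-01 08:00:00", tz = "UTC")
    stamp <- function(min) format(t0 + min * 60, "%Y%m%d-%H%M%S")
    day_opens <- status == "open_at_dusk"
    for (m in c(0, 360, 719)) {
      fr <- render_day_frame(d, centers, day_opens, spec$noise_sd)
      write_frame(fr, file.path(dir, "day", sprintf("day_%s.png", stamp(m))))
    }
    dawn_opens <- day_opens | status == "night_open"
    fr <- render_day_frame(d, centers, dawn_opens, spec$noise_sd)
    write_frame(fr, file.path(dir, "day",
                              sprintf("day_%s.png", stamp(720 + night_span))))
    # --- night frames ---
    n_frames <- night_span %/% spec$interval
    traj <- drift_trajectory(n_frames, spec$drift_max)
    for (k in seq_len(n_frames)) {
      m <- (k - 1) * spec$interval
      on <- !is.na(open_minute) & m >= open_minute
      fr <- render_night_frame(d, centers, patch_centers, on, traj[k, ],
                               spec$noise_sd, patch_r,
                               amplitude = spec$amplitude)
      write_frame(fr, file.path(dir, "night",
                                sprintf("night_%s.png", stamp(720 + m))))
    }
    write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  })
  # --- training scenes (independent seeds) ---
  for (i in seq_len(spec$n_train_scenes)) {
    sc <- make_day_scene(day_scene_spec(seed = seeds[6 + i],
                                        dim = c(408, 408),
                                        n_closed = 25, n_open = 15,
                                        n_background = 130,
                                        noise_sd = spec$noise_sd))
    write_frame(sc$frame, file.path(dir, "train", sprintf("scene_%02d.png", i)))
    write_annotations(sc$annotations,
                      file.path(dir, "train", sprintf("scene_%02d.xml", i)),
                      image_dim = dim(sc$frame$pixels)[1:2],
                      filename = sprintf("scene_%02d.png", i))
  }
  cfg <- c("[paths]",
           paste0("day_dir = ", file.path(dir, "day")),
           paste0("night_dir = ", file.path(dir, "night")),
           paste0("train_dir = ", file.path(dir, "train")),
           paste0("out_dir = ", file.path(dir, "out")),
           "[schedule]", "lights_on = 8", "lights_off = 20", "start_clock = 8",
           "[tiling]", "tile_size = 34",
           "[thresholds]", "window_minutes = 30",
           "pixel_fraction_threshold = 0.05",
           "intensity_fraction_threshold = 0.5",
           "[classifier]", "backend = multinom",
           paste0("seed = ", spec$seed),
           paste0("train_background = ", spec$train_counts["background"]),
           paste0("train_closed = ", spec$train_counts["closed"]),
           paste0("train_open = ", spec$train_counts["open"]))
  writeLines(cfg, file.path(dir, "config.ini"))
  invisible(utils::read.csv(file.path(dir, "truth.csv")))
}

#' Read a run configuration file
#'
#' Minimal INI dialect: `[section]` headers and `key = value` lines;
#' blank lines and `#` comments ignored. Numeric-looking values are
#' converted. Returns a nested named list.
#'
#' @param path Config file path.
#' @return Named list of sections.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- list(); section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      cfg[[section]] <- cfg[[section]] %||% list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      num <- suppressWarnings(as.numeric(val))
      cfg[[section]][[key]] <- if (!is.na(num)) num else val
    } else stop("cannot parse config line: '", ln, "'")
  }
  cfg
}

#' Run the full TAA pipeline on an experiment directory
#'
#' Stages, in order: train (or load) the day classifier; classify the
#' last light frame before the night and the first light frame after it
#' to anchor the open ratios; track every closed-tile spikelet through
#' the night and call opening events; fit the anchored cumulative curve
#' and its smoothing-spline rate. Writes `calls.csv`, `ratios.csv`,
#' `rates.csv` and a machine-readable `manifest.json` (config hash, seed,
#' output checksums) into the output directory.
#'
#' @param config Path to a config file (see [read_run_config()]) or an
#'   equivalent nested list.
#' @return A `taa_run_report` list with `calls` (data frame), `calls_raw`
#'   (the `taa_opening_call` objects with bounding boxes), `ratios`,
#'   `rate` (a `taa_rate_curve`), `model` and `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  need <- function(sec, key, default = NULL) {
    v <- cfg[[sec]][[key]] %||% default
    if (is.null(v)) stop("config error: missing [", sec, "] ", key)
    v
  }
  for (p in c("day_dir", "night_dir")) {
    if (!dir.exists(need("paths", p)))
      stop("data error: [paths] ", p, " does not exist: ", need("paths", p))
  }
  out_dir <- need("paths", "out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  schedule <- photoperiod(need("schedule", "lights_on", 8),
                          need("schedule", "lights_off", 20))
  start_clock <- need("schedule", "start_clock", 8)
  tile_size <- need("tiling", "tile_size", 34)
  mc <- motion_config(
    window_minutes = need("thresholds", "window_minutes", 30),
    pixel_fraction_threshold = need("thresholds", "pixel_fraction_threshold",
                                    0.05),
    intensity_fraction_threshold =
      need("thresholds", "intensity_fraction_threshold", 0.5))
  seed <- need("classifier", "seed", 1)

  # -- stage: classifier ------------------------------------------------
  model <- if (!is.null(cfg$classifier$model_path)) {
    load_classifier(cfg$classifier$model_path)
  } else {
    train_dir <- need("paths", "train_dir")
    xmls <- list.files(train_dir, pattern = "\\.xml$", full.names = TRUE)
    if (!length(xmls)) stop("data error: no training annotations (*.xml) in ",
                            train_dir)
    scenes <- lapply(xmls, function(x) {
      img <- sub("\\.xml$", ".png", x)
      if (!file.exists(img)) stop("data error: no image for annotation ", x)
      frame <- read_frame(img, timestamp = 0, clock_time = 12)
      list(frame = frame, annotations = parse_annotations(x,
                                                          dim(frame$pixels)[1:2]))
    })
    counts <- c(background = need("classifier", "train_background", 400),
                closed = need("classifier", "train_closed", 80),
                open = need("classifier", "train_open", 40))
    ts <- build_training_set(scenes, counts, seed = seed)
    train_classifier(ts, backend = need("classifier", "backend", "multinom"),
                     seed = seed)
  }

  # -- stage: day anchors ----------------------------------------------
  # shared absolute time base across the two directories, rebased to the
  # earliest frame of the whole run
  day <- read_series(need("paths", "day_dir"), schedule, rebase = FALSE)
  night <- read_series(need("paths", "night_dir"), schedule, rebase = FALSE)
  if (!length(night)) stop("data error: no night frames found")
  t0 <- min(series_timestamps(day)[1], series_timestamps(night)[1])
  rebase_series <- function(s) {
    frames <- lapply(unclass(s), function(f) { f$timestamp <- f$timestamp - t0; f })
    taa_series(frames, attr(s, "nominal_interval"))
  }
  day <- rebase_series(day); night <- rebase_series(night)
  night_t <- range(series_timestamps(night))
  day_t <- series_timestamps(day)
  pre <- which(day_t < night_t[1])
  post <- which(day_t > night_t[2])
  if (!length(pre) || !length(post))
    stop("data error: need light frames both before and after the night")
  dusk_frame <- day[[max(pre)]]
  dawn_frame <- day[[min(post)]]
  dusk_calls <- classify_image(model, dusk_frame, tile_size)
  dawn_calls <- classify_image(model, dawn_frame, tile_size)
  ratios <- data.frame(anchor = c("dusk", "dawn"),
                       timestamp = c(dusk_frame$timestamp,
                                     dawn_frame$timestamp),
                       open_ratio = c(open_ratio(dusk_calls),
                                      open_ratio(dawn_calls)))

  # -- stage: night motion ---------------------------------------------
  calls <- call_night_openings(dusk_calls, night, mc)
  calls_df <- opening_calls_df(calls, start_clock)

  # -- stage: rates ------------------------------------------------------
  grid <- series_timestamps(night)
  curve <- anchor_scale(cumulative_curve(calls_df, grid),
                        ratios$open_ratio[1], max(ratios$open_ratio),
                        start_clock = start_clock)
  rate <- fit_rate(curve)

  # -- outputs -----------------------------------------------------------
  write.csv(calls_df, file.path(out_dir, "calls.csv"), row.names = FALSE)
  write.csv(ratios, file.path(out_dir, "ratios.csv"), row.names = FALSE)
  rates_df <- data.frame(time = rate$times, clock = rate$clock,
                         fraction = rate$smoothed_fraction, rate = rate$rate,
                         normalized_rate = rate$normalized_rate)
  write.csv(rates_df, file.path(out_dir, "rates.csv"), row.names = FALSE)
  files <- file.path(out_dir, c("calls.csv", "ratios.csv", "rates.csv"))
  manifest <- list(package_version = as.character(utils::packageVersion("taatrack")),
                   seed = seed,
                   config = cfg,
                   output_md5 = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(list(calls = calls_df, calls_raw = calls, ratios = ratios,
                 rate = rate, model = model, manifest = manifest),
            class = "taa_run_report")
}

#' @export
print.taa_run_report <- function(x, ...) {
  cat(sprintf("<taa_run_report> %d spikelets tracked, %d opened; dusk ratio %.3f -> dawn ratio %.3f\n",
              nrow(x$calls), sum(x$calls$opened), x$ratios$open_ratio[1],
              x$ratios$open_ratio[2]))
  invisible(x)
}

#' Match pipeline opening calls against simulated ground truth
#'
#' A true night-opening event is recovered when some opened call's
#' (padded) bounding box contains the spikelet center and the called TAA
#' lies within `tol_minutes` of the scripted opening minute.
#'
#' @param calls List of `taa_opening_call`s (with bboxes) from
#'   [call_night_openings()], or the `calls` element of a run report
#'   cannot be used (bboxes required) — pass the call list.
#' @param truth Ground-truth data frame from [simulate_experiment()].
#' @param night_t0 Experiment minute of the first night frame (720 by
#'   default), used to place `truth$open_minute` on the experiment clock.
#' @param tol_minutes Temporal matching tolerance.
#' @param pad Spatial padding around call bboxes, matching the tracking
#'   padding.
#' @return Logical vector over the true events: recovered or not.
#' @export
match_calls_to_truth <- function(calls, truth, night_t0 = 720,
                                 tol_minutes = 2, pad = 4) {
  events <- truth[truth$status == "night_open", , drop = FALSE]
  vapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    any(vapply(calls, function(cl) {
      if (!cl$opened || is.null(cl$bbox)) return(FALSE)
      inside <- ev$row >= cl$bbox[1] - pad && ev$row < cl$bbox[3] + pad &&
                ev$col >= cl$bbox[2] - pad && ev$col < cl$bbox[4] + pad
      inside && abs(cl$taa_timestamp - (night_t0 + ev$open_minute)) <= tol_minutes
    }, logical(1)))
  }, logical(1))
}

#' Compare accessions' flowering rates within a clock window
#'
#' Summarises each replicate panicle by its [window_mean_rate()] in the
#' window, then runs [one_way_anova()] across accessions and
#' [pairwise_holm()] pairwise tests.
#'
#' @param rates_by_accession Named list (one entry per accession) of
#'   lists of `taa_rate_curve`s (one per replicate panicle).
#' @param window `c(clock_start, clock_end)` hours, e.g. `c(20, 21.5)`
#'   for the 1.5 h after dusk.
#' @return List with `window`, per-accession `means`, `anova` and
#'   `pairwise` (Holm-adjusted p matrix).
#' @export
compare_accessions <- function(rates_by_accession, window = c(20, 21.5)) {
  groups <- lapply(rates_by_accession, function(reps)
    vapply(reps, window_mean_rate, numeric(1), window = window))
  list(window = window,
       means = vapply(groups, mean, numeric(1)),
       anova = one_way_anova(groups),
       pairwise = pairwise_holm(groups))
}
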