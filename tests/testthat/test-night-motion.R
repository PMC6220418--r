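test_that("intensity centroid is the weighted mean in 0-based coordinates", {
  m <- matrix(0, 10, 10); m[4, 6] <- 200
  expect_equal(intensity_centroid(m), c(row = 3, col = 5))
  expect_equal(intensity_centroid(matrix(7, 10, 10)),
               c(row = 4.5, col = 4.5))
  m2 <- matrix(0, 1, 9); m2[1, 1] <- 10; m2[1, 9] <- 10
  expect_equal(intensity_centroid(m2), c(row = 0, col = 4))
  expect_error(intensity_centroid(matrix(0, 3, 3)), "all-zero")
})

test_that("stabilisation undoes an injected translation and is idempotent", {
  base <- matrix(0, 20, 20)
  base[8:12, 8:12] <- 150                     # compact blob away from borders
  shifted <- taatrack:::shift_matrix(base, 2, 3)
  tr <- spikelet_track("s", array(c(base, shifted), c(20, 20, 2)), c(0, 1))
  st <- stabilize(tr)
  mask <- attr(st, "valid_mask")
  expect_equal(st$frames[, , 2][mask], st$frames[, , 1][mask])
  # already aligned: untouched, and re-stabilising changes nothing
  st2 <- stabilize(st)
  expect_equal(st2$frames, st$frames)
  aligned <- spikelet_track("a", array(rep(base, 3), c(20, 20, 3)), 0:2)
  expect_equal(stabilize(aligned)$frames, aligned$frames)
})

test_that("pathological drift leaves the frame unshifted with a warning", {
  # centroid jumps across the whole crop: required shift > half the crop
  base <- matrix(0, 10, 10); base[2, 2] <- 100
  f2 <- matrix(0, 10, 10); f2[10, 10] <- 100
  tr <- spikelet_track("p", array(c(base, f2), c(10, 10, 2)), c(0, 1))
  expect_warning(st <- stabilize(tr), "drift")
  expect_equal(st$frames[, , 2], f2)           # left unshifted
})

test_that("windows are consecutive, non-overlapping, last may be short", {
  expect_length(segment_windows(0:719, 30), 24)
  expect_true(all(lengths(segment_windows(0:719, 30)) == 30))
  w31 <- segment_windows(0:30, 30)
  expect_equal(lengths(w31), c(30, 1))
  expect_equal(segment_windows(5, 30), list(1L))
  expect_equal(unlist(segment_windows(0:100, 30)), 1:101)
})

test_that("the 5% pixel / 50% intensity rule triggers exactly at threshold", {
  # 10% of pixels jump 0 -> 255 at frame 25
  tr <- as_stabilized(spikelet_track("a", jump_stack(frac = 0.10, at = 25),
                                     0:59))
  call <- detect_opening(tr)
  expect_true(call$opened)
  expect_equal(call$taa_timestamp, 24)         # timestamps are 0-based minutes
  expect_equal(call$window_index, 1L)
  expect_gte(call$fraction_changed, 0.05)

  # exactly 5% triggers ("at least"), 4% does not
  expect_true(detect_opening(as_stabilized(
    spikelet_track("b", jump_stack(frac = 0.05, at = 25), 0:59)))$opened)
  expect_false(detect_opening(as_stabilized(
    spikelet_track("c", jump_stack(frac = 0.04, at = 25), 0:59)))$opened)

  # intensity change must be strictly greater than 50% of bit depth
  expect_false(detect_opening(as_stabilized(
    spikelet_track("d", jump_stack(frac = 0.10, at = 25, amp = 127.5),
                   0:59)))$opened)
  expect_true(detect_opening(as_stabilized(
    spikelet_track("e", jump_stack(frac = 0.10, at = 25, amp = 128),
                   0:59)))$opened)

  # identical frames: nothing to call
  expect_false(detect_opening(as_stabilized(
    spikelet_track("f", jump_stack(frac = 0, at = Inf), 0:59)))$opened)
})

test_that("detector matches the brute-force per-pixel oracle on random stacks", {
  set.seed(1234)
  for (i in 1:25) {
    stack <- array(sample(0:255, 16 * 16 * 60, replace = TRUE) *
                     (runif(16 * 16 * 60) < 0.3), c(16, 16, 60))
    tr <- as_stabilized(spikelet_track(paste0("r", i), stack, 0:59))
    got <- detect_opening(tr)
    want <- oracle_detect(tr$frames, tr$timestamps)
    expect_identical(got$opened, want$opened)
    expect_identical(got$taa_timestamp, want$taa)
  }
})

test_that("raising either threshold never creates additional opened calls", {
  set.seed(99)
  stacks <- lapply(1:12, function(i) {
    sp <- night_series_spec(seed = 300 + i, n_frames = 120,
                            opening_times = if (i %% 2) 45 else NA,
                            amplitude = runif(1, 0.3, 1),
                            noise_sd = 5, drift_max = 2)
    make_night_series(sp)$tracks[[1]]
  })
  n_open <- function(pf, ifr) sum(vapply(stacks, function(tr)
    detect_opening(tr, motion_config(pixel_fraction_threshold = pf,
                                     intensity_fraction_threshold = ifr))$opened,
    logical(1)))
  base <- n_open(0.05, 0.5)
  expect_lte(n_open(0.10, 0.5), base)
  expect_lte(n_open(0.05, 0.7), base)
  expect_lte(n_open(0.20, 0.9), n_open(0.10, 0.7))
})

test_that("detection is invariant to a global integer translation of the stack", {
  ns <- make_night_series(night_series_spec(seed = 77, n_frames = 120,
                                            opening_times = 61, drift_max = 0))
  tr <- ns$tracks[[1]]
  moved <- tr
  for (k in seq_len(dim(tr$frames)[3]))
    moved$frames[, , k] <- taatrack:::shift_matrix(tr$frames[, , k], 2, -3,
                                                   fill = 15)
  a <- detect_opening(tr); b <- detect_opening(moved)
  expect_equal(b$opened, a$opened)
  expect_equal(b$taa_timestamp, a$taa_timestamp)
})

test_that("night openings are called only for spikelets closed at dusk", {
  # all spikelets open at dusk -> nothing to track
  ann_open <- data.frame(label = "open", row_min = 0, col_min = 0,
                         row_max = 20, col_max = 20)
  night <- taa_series(lapply(0:5, function(m)
    taa_frame(matrix(10, 40, 40), 720 + m, start_clock = 8)))
  expect_length(call_night_openings(ann_open, night), 0)

  ann_closed <- data.frame(label = "closed", row_min = 5, col_min = 5,
                           row_max = 30, col_max = 30)
  expect_error(call_night_openings(ann_closed, taa_series(list())), "empty")
})

test_that("scripted synthetic openings are recovered at their scripted times", {
  times <- c(100, NA, 37, 415, NA)
  ns <- make_night_series(night_series_spec(seed = 21, n_spikelets = 5,
                                            n_frames = 480,
                                            opening_times = times))
  calls <- lapply(ns$tracks, detect_opening)
  opened <- vapply(calls, `[[`, logical(1), "opened")
  expect_equal(opened, !is.na(times))
  got <- vapply(calls[opened], `[[`, numeric(1), "taa_timestamp") - 720
  expect_true(all(abs(got - times[!is.na(times)]) <= 1))
})
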