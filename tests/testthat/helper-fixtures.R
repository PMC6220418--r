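# Small programmatic fixtures shared across test files.

# A tiny set of day scenes with enough annotated objects for desk-scale
# classifier corpora; memoised so several test files can share it.
tiny_scene_pool <- local({
  pool <- NULL
  function() {
    if (is.null(pool))
      pool <<- lapply(1:6, function(i) {
        s <- make_day_scene(day_scene_spec(seed = 100 + i, n_closed = 10,
                                           n_open = 8, n_background = 40))
        list(frame = s$frame, annotations = s$annotations)
      })
    pool
  }
})

# Single-channel stack with a scripted pixel jump: `frac` of pixels go
# 0 -> `amp` at frame `at`.
jump_stack <- function(dims = c(10, 10), n = 60, at = 25, frac = 0.10,
                       amp = 255, base = 0) {
  stack <- array(base, c(dims, n))
  npx <- round(frac * prod(dims))
  if (npx > 0 && is.finite(at)) {
    idx <- arrayInd(seq_len(npx), dims)
    for (k in at:n) for (i in seq_len(npx))
      stack[idx[i, 1], idx[i, 2], k] <- base + amp
  }
  stack
}

# Mark a track as already stabilised with a full validity mask (for
# detector tests that construct their own pixel geometry).
as_stabilized <- function(track) {
  attr(track, "stabilized") <- TRUE
  attr(track, "valid_mask") <- matrix(TRUE, dim(track$frames)[1],
                                      dim(track$frames)[2])
  track
}
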