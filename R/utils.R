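#' @keywords internal
"_PACKAGE"

#' @import stats
#' @importFrom utils head tail read.csv write.csv
#' @importFrom nnet multinom
NULL

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's
# random state afterwards. All generators route their randomness through
# this so no call touches global RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a stream of child seeds from one parent seed, kept below 2^31.
child_seeds <- function(seed, n) {
  (as.numeric(seed) * 7919 + 104729 * seq_len(n)) %% .Machine$integer.max
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Bilinear rescale of a [rows, cols] or [rows, cols, channels] intensity
# array (0-255 scale) to new row/col dimensions. Thin wrapper over
# EBImage::resize; dimension order is preserved.
rescale_pixels <- function(px, new_rows, new_cols) {
  d <- dim(px)
  if (d[1] == new_rows && d[2] == new_cols) return(px)
  img <- EBImage::Image(px, dim = d)
  out <- EBImage::imageData(EBImage::resize(img, w = new_rows, h = new_cols,
                                            filter = "bilinear"))
  clamp(out, 0, 255)
}

n_channels <- function(px) if (length(dim(px)) == 3L) dim(px)[3] else 1L

is_rgb <- function(px) n_channels(px) == 3L

`%||%` <- function(a, b) if (is.null(a)) b else a
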