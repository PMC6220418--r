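#' Edge-count score of a night frame
#'
#' Counts pixels whose 3x3 Sobel gradient magnitude exceeds `threshold`.
#' Sharper, better-exposed captures resolve more spikelet outlines and
#' score higher; the score is invariant to a global intensity offset.
#' The one-pixel border is excluded (the operator is undefined there).
#'
#' @param frame Single-channel [taa_frame()] or matrix (0-255).
#' @param threshold Gradient-magnitude cutoff; default half the bit-depth
#'   maximum.
#' @return Integer edge-pixel count.
#' @export
score_edges <- function(frame, threshold = 127.5) {
  px <- if (inherits(frame, "taa_frame")) frame$pixels else frame
  if (is_rgb(px)) stop("score_edges() expects a single-channel frame")
  nr <- nrow(px); nc <- ncol(px)
  if (nr < 3 || nc < 3) return(0L)
  s <- function(dr, dc) px[(2:(nr - 1)) + dr, (2:(nc - 1)) + dc]
  gx <- (s(-1, 1) + 2 * s(0, 1) + s(1, 1)) -
        (s(-1, -1) + 2 * s(0, -1) + s(1, -1))
  gy <- (s(1, -1) + 2 * s(1, 0) + s(1, 1)) -
        (s(-1, -1) + 2 * s(-1, 0) + s(-1, 1))
  sum(sqrt(gx^2 + gy^2) > threshold)
}

#' Exhaustive capture-parameter search scored by edge count
#'
#' Evaluates every combination of the candidate capture options exactly
#' once — combinations are enumerated lexicographically in the given
#' option order — captures a frame through the injected `capture`
#' callable (hardware driver or simulator), scores it, and returns the
#' highest-scoring combination (ties broken by enumeration order). A
#' combination whose capture fails is skipped with a warning; if every
#' capture fails the search errors.
#'
#' @param options Named list of candidate value vectors, one entry per
#'   capture option.
#' @param capture Function taking a named list (one value per option) and
#'   returning a single-channel frame.
#' @param scorer Scoring function, default [score_edges()].
#' @param ... Passed on to `scorer`.
#' @return A `taa_capture_result`: `best` (named list), `score`, and the
#'   full `results` data frame sorted by descending score.
#' @export
optimize_capture <- function(options, capture, scorer = score_edges, ...) {
  stopifnot(is.list(options), length(options) >= 1,
            all(lengths(options) >= 1))
  if (is.null(names(options)) || any(names(options) == ""))
    stop("every capture option needs a name")
  # expand.grid varies the first factor fastest; reverse in and out so the
  # FIRST option is the most significant (lexicographic order).
  combos <- expand.grid(rev(options), stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)[, rev(seq_along(options)),
                                                drop = FALSE]
  names(combos) <- names(options)
  scores <- rep(NA_real_, nrow(combos))
  for (i in seq_len(nrow(combos))) {
    combo <- as.list(combos[i, , drop = FALSE])
    frame <- tryCatch(capture(combo), error = function(e) {
      warning(sprintf("capture failed for combination %d (%s): %s", i,
                      paste(names(combo), unlist(combo), sep = "=",
                            collapse = ", "),
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(frame)) scores[i] <- scorer(frame, ...)
  }
  if (all(is.na(scores))) stop("every capture attempt failed")
  best_i <- which(scores == max(scores, na.rm = TRUE))[1]
  results <- cbind(combos, score = scores)
  structure(list(best = as.list(combos[best_i, , drop = FALSE]),
                 score = scores[best_i],
                 results = results[order(-scores), , drop = FALSE],
                 n_evaluated = sum(!is.na(scores))),
            class = "taa_capture_result")
}

#' @export
print.taa_capture_result <- function(x, ...) {
  cat(sprintf("<taa_capture_result> best: %s (score %g; %d combinations scored)\n",
              paste(names(x$best), unlist(x$best), sep = "=", collapse = ", "),
              x$score, x$n_evaluated))
  invisible(x)
}
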