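#' Cumulative flower-opening counts over a time grid
#'
#' Combines the TAA timestamps of one panicle-night's opening calls into a
#' non-decreasing step function: the number of flowers open by each grid
#' time.
#'
#' @param calls List of `taa_opening_call`s (or a data frame from
#'   [opening_calls_df()]).
#' @param grid Numeric vector of minutes at which to evaluate the count.
#' @return List with `times` and `counts`.
#' @export
cumulative_curve <- function(calls, grid) {
  taa <- if (is.data.frame(calls)) calls$taa_minutes[calls$opened]
         else unlist(lapply(calls, function(x) if (x$opened) x$taa_timestamp))
  taa <- taa %||% numeric(0)
  counts <- vapply(grid, function(t) sum(taa <= t), numeric(1))
  list(times = grid, counts = counts)
}

#' Anchor a cumulative count curve to daytime open ratios
#'
#' Nighttime counts are unitless (the classifier cannot run on IR
#' frames), so the cumulative curve is affinely mapped onto the open
#' ratios measured on the last light image before dusk and the first
#' light image after dawn. A night with no openings maps to the constant
#' dusk ratio.
#'
#' @param counts Output of [cumulative_curve()] (or a numeric count
#'   vector with a parallel `times` argument).
#' @param dusk_ratio,dawn_ratio Open ratios in `[0, 1]` with
#'   `dawn_ratio >= dusk_ratio`.
#' @param times Minutes, required when `counts` is a bare vector.
#' @param start_clock Clock hours at experiment minute 0 (used to carry
#'   clock times on the curve).
#' @return A `taa_flowering_curve`: list with `times`, `clock`,
#'   `open_fraction` and `anchors`.
#' @export
anchor_scale <- function(counts, dusk_ratio, dawn_ratio, times = NULL,
                         start_clock = 8) {
  if (is.list(counts) && !is.null(counts$counts)) {
    times <- counts$times; counts <- counts$counts
  }
  if (is.null(times)) stop("`times` required when `counts` is a bare vector")
  if (dawn_ratio < dusk_ratio)
    stop(sprintf(paste0("dawn ratio (%.3f) below dusk ratio (%.3f): open ",
                        "fraction cannot decrease overnight; check the ",
                        "daytime classification"), dawn_ratio, dusk_ratio))
  if (any(diff(counts) < 0)) stop("`counts` must be non-decreasing")
  total <- max(counts)
  frac <- if (total == 0) rep(dusk_ratio, length(counts))
          else dusk_ratio + (dawn_ratio - dusk_ratio) * counts / total
  structure(list(times = times, clock = (start_clock + times / 60) %% 24,
                 open_fraction = frac,
                 anchors = c(dusk = dusk_ratio, dawn = dawn_ratio)),
            class = "taa_flowering_curve")
}

#' Fit a smoothing spline and its derivative to a flowering curve
#'
#' A cubic smoothing spline is fitted to the open fraction over time
#' (smoothness chosen by generalized cross-validation unless `df` is
#' given) and the flowering rate is its first derivative, normalised by
#' the panicle's maximum rate.
#'
#' @param curve A `taa_flowering_curve` (or list with `times` and
#'   `open_fraction`), with at least 4 distinct time points.
#' @param df Optional fixed equivalent degrees of freedom for the spline.
#' @param spar Optional smoothing parameter, passed to
#'   [stats::smooth.spline()].
#' @return A `taa_rate_curve`: `times`, `clock`, `smoothed_fraction`,
#'   `rate` (fraction per minute) and `normalized_rate` (peak 1 whenever
#'   any flowering occurred, all-zero otherwise).
#' @export
fit_rate <- function(curve, df = NULL, spar = NULL) {
  times <- curve$times; y <- curve$open_fraction
  if (length(unique(times)) < 4)
    stop("need at least 4 distinct time points to fit a smoothing spline")
  args <- list(x = times, y = y)
  if (!is.null(df)) args$df <- df
  if (!is.null(spar)) args$spar <- spar
  fit <- do.call(stats::smooth.spline, args)
  sm <- predict(fit, times)$y
  rate <- predict(fit, times, deriv = 1)$y
  peak <- max(rate)
  # a peak below ~1 flower per panicle-week is numerical noise on a flat
  # fit, not flowering; normalising by it would amplify garbage
  norm <- if (peak > 1e-9) rate / peak else rep(0, length(rate))
  structure(list(times = times, clock = curve$clock,
                 smoothed_fraction = sm, rate = rate, normalized_rate = norm,
                 spline = fit),
            class = "taa_rate_curve")
}

#' @export
plot.taa_rate_curve <- function(x, ...) {
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  graphics::plot(x$times, x$smoothed_fraction, type = "l",
                 xlab = "minutes", ylab = "open fraction", ...)
  graphics::plot(x$times, x$normalized_rate, type = "l",
                 xlab = "minutes", ylab = "normalised rate", ...)
  invisible(x)
}

#' Partition opening events into day / night / unopened percentages
#'
#' Over a stated horizon (canonically 3 days), each spikelet either opens
#' in the light, opens in the dark, or never opens; the three percentages
#' sum to 100.
#'
#' @param calls Data frame from [opening_calls_df()] (needs `opened` and
#'   `taa_clock`), or a list of `taa_opening_call`s plus `start_clock`.
#' @param n_spikelets Total number of spikelets monitored; defaults to
#'   `nrow(calls)`.
#' @param schedule A [photoperiod()].
#' @param start_clock Clock hours at minute 0 (used only for call lists).
#' @return List with `pct_day`, `pct_night`, `pct_unopened`.
#' @export
partition_day_night <- function(calls, n_spikelets = NULL,
                                schedule = photoperiod(), start_clock = 8) {
  if (!is.data.frame(calls)) calls <- opening_calls_df(calls, start_clock)
  n_spikelets <- n_spikelets %||% nrow(calls)
  if (n_spikelets == 0) stop("zero spikelets: partition undefined")
  opened <- calls$opened
  cond <- clock_condition(calls$taa_clock[opened], schedule)
  n_day <- sum(cond == "day"); n_night <- sum(cond == "night")
  list(pct_day = 100 * n_day / n_spikelets,
       pct_night = 100 * n_night / n_spikelets,
       pct_unopened = 100 * (n_spikelets - n_day - n_night) / n_spikelets)
}

#' Mean normalised flowering rate within a clock window
#'
#' Used to compare accessions in windows such as the 1.5 h after dusk
#' (clock 20:00-21:30) or after dawn (8:00-9:30). Windows may wrap past
#' midnight.
#'
#' @param rate A `taa_rate_curve` carrying clock times.
#' @param window `c(clock_start, clock_end)` in hours of day.
#' @return Mean of `normalized_rate` over grid points in the window.
#' @export
window_mean_rate <- function(rate, window) {
  stopifnot(length(window) == 2)
  span <- (window[2] - window[1]) %% 24
  off <- (rate$clock - window[1]) %% 24
  sel <- off >= 0 & off <= span
  if (!any(sel))
    stop(sprintf("clock window [%.2f, %.2f] h does not overlap the rate curve",
                 window[1], window[2]))
  mean(rate$normalized_rate[sel])
}

#' One-way ANOVA across accessions
#'
#' Classical fixed-effects one-way analysis of variance of one scalar
#' summary per replicate (e.g. the post-dusk window mean rate, one
#' panicle = one replicate). Degrees of freedom are `(k - 1, N - k)`.
#' When every group is the same constant the F ratio is 0/0; by
#' convention the function returns `F = 0`, `p = 1` with a warning.
#'
#' @param groups Named list of numeric vectors, one per group, each of
#'   length >= 2.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(groups) {
  check_groups(groups)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups) %||% seq_along(groups),
                  lengths(groups)))
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  F <- unname(ft$statistic); p <- ft$p.value
  if (!is.finite(F)) {
    within_ss <- sum(unlist(lapply(groups, function(v) sum((v - mean(v))^2))))
    means <- vapply(groups, mean, numeric(1))
    if (within_ss == 0 && max(means) - min(means) == 0) {
      warning("all groups identical constants: reporting F = 0, p = 1")
      F <- 0; p <- 1
    }
  }
  list(F = F, df1 = unname(ft$parameter[1]), df2 = unname(ft$parameter[2]),
       p = p)
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups")
  if (any(lengths(groups) < 2))
    stop("every group needs at least 2 replicates")
  invisible(groups)
}

#' Holm-adjusted pairwise t-tests between accessions
#'
#' All pairwise two-sample t-tests (pooled standard deviation by default,
#' matching the classical pairwise procedure; `pool_sd = FALSE` switches
#' to Welch) with Holm's step-down adjustment: raw p-values sorted
#' ascending, the i-th multiplied by `m - i + 1`, a running maximum
#' enforced, capped at 1.
#'
#' @inheritParams one_way_anova
#' @param pool_sd Use a pooled standard deviation across all groups.
#' @return Lower-triangular matrix of Holm-adjusted p-values, as returned
#'   by [stats::pairwise.t.test()].
#' @export
pairwise_holm <- function(groups, pool_sd = TRUE) {
  check_groups(groups)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups) %||% seq_along(groups), lengths(groups)))
  stats::pairwise.t.test(y, g, p.adjust.method = "holm",
                         pool.sd = pool_sd)$p.value
}
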