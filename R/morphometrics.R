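#' Binarise an RGB frame by hue/saturation/brightness thresholds
#'
#' Each pixel's HSB triple (each channel on the 0-255 scale, the ImageJ
#' convention) must fall inside all three closed ranges. The canonical
#' green-tissue window is hue 39-113, saturation 30-187, brightness
#' 0-255.
#'
#' @param frame A [taa_frame()] or RGB pixel array (0-255).
#' @param hue_range,sat_range,bright_range Length-2 inclusive ranges on
#'   the 0-255 scale.
#' @return A logical matrix mask with attribute `provenance` recording
#'   the thresholds.
#' @export
binarize_hsb <- function(frame, hue_range = c(39, 113),
                         sat_range = c(30, 187), bright_range = c(0, 255)) {
  for (r in list(hue_range, sat_range, bright_range))
    if (length(r) != 2 || r[1] > r[2])
      stop("threshold ranges must be length-2 with min <= max")
  px <- if (inherits(frame, "taa_frame")) frame$pixels else frame
  if (!is_rgb(px)) stop("binarize_hsb() needs an RGB frame")
  d <- dim(px)
  hsv <- grDevices::rgb2hsv(r = as.vector(px[, , 1]),
                            g = as.vector(px[, , 2]),
                            b = as.vector(px[, , 3]), maxColorValue = 255)
  h <- hsv[1, ] * 255; s <- hsv[2, ] * 255; v <- hsv[3, ] * 255
  mask <- h >= hue_range[1] & h <= hue_range[2] &
          s >= sat_range[1] & s <= sat_range[2] &
          v >= bright_range[1] & v <= bright_range[2]
  mask <- matrix(mask, d[1], d[2])
  attr(mask, "provenance") <- list(hue = hue_range, saturation = sat_range,
                                   brightness = bright_range)
  mask
}

# 8-connected component labelling of a logical matrix by two-pass
# union-find (EBImage::bwlabel is 4-connected, which would split diagonal
# bristle pixels).
label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  next_label <- 0L
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (!mask[rr, cc]) next
    nb <- integer(0)
    if (rr > 1 && labels[rr - 1, cc]) nb <- c(nb, labels[rr - 1, cc])
    if (cc > 1) {
      if (labels[rr, cc - 1]) nb <- c(nb, labels[rr, cc - 1])
      if (rr > 1 && labels[rr - 1, cc - 1]) nb <- c(nb, labels[rr - 1, cc - 1])
      if (rr < nr && labels[rr + 1, cc - 1]) nb <- c(nb, labels[rr + 1, cc - 1])
    }
    if (!length(nb)) {
      next_label <- next_label + 1L
      parent[next_label] <- next_label
      labels[rr, cc] <- next_label
    } else {
      roots <- vapply(nb, find, integer(1))
      r0 <- min(roots)
      labels[rr, cc] <- r0
      for (r in roots) parent[r] <- r0
    }
  }
  if (next_label > 0) {
    map <- vapply(seq_len(next_label), find, integer(1))
    map <- match(map, sort(unique(map)))
    pos <- labels > 0L
    labels[pos] <- map[labels[pos]]
  }
  labels
}

# Pixels of `a` having an 8-neighbour in `b`.
adjacent_to <- function(a, b) {
  grown <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(b * 1), EBImage::makeBrush(3, "box"))) > 0
  a & grown
}

#' Detect bristles on a binary panicle mask
#'
#' The panicle body is recovered by a morphological opening that erases
#' thin protrusions; every 8-connected component of the remaining white
#' pixels is a candidate bristle. A candidate is counted when it is a
#' thin branch (inscribed half-width at most `max_halfwidth`) whose base
#' (the body pixel it attaches to) connects to a tip (its farthest pixel
#' from the body) through continuous white pixels at least `min_length`
#' pixels out; components are disjoint, so no counted bristle path runs
#' through another. The thinness criterion rejects the slivers a
#' morphological opening shaves off convex body corners, which are wide
#' and shallow where bristles are narrow and long.
#'
#' @param mask Logical matrix (or 0/1), white = plant.
#' @param body_brush Odd diameter of the disc used to open the mask into
#'   the body; must exceed the bristle width (default 9).
#' @param min_length Minimum tip distance from the body, in pixels; the
#'   default, `body_brush / 2 + 2`, ignores one-pixel boundary specks.
#' @param max_halfwidth Maximum inscribed half-width of a bristle
#'   component, in pixels (default 2, i.e. bristles up to ~4 px wide).
#' @return A `taa_bristles` list: `count`, `bases` / `tips` data frames
#'   (0-based `row`/`col`), `body_mask`, `bristle_mask`. An empty mask
#'   yields zero bristles.
#' @export
detect_bristles <- function(mask, body_brush = 9,
                            min_length = body_brush / 2 + 2,
                            max_halfwidth = 2) {
  mask <- mask > 0
  empty <- structure(list(count = 0L,
                          bases = data.frame(row = numeric(0), col = numeric(0)),
                          tips = data.frame(row = numeric(0), col = numeric(0)),
                          body_mask = mask & FALSE, bristle_mask = mask & FALSE),
                     class = "taa_bristles")
  if (!any(mask)) return(empty)
  if (body_brush %% 2 == 0) body_brush <- body_brush + 1
  body <- EBImage::imageData(EBImage::opening(
    EBImage::Image(mask * 1), EBImage::makeBrush(body_brush, "disc"))) > 0
  if (!any(body)) { empty$bristle_mask <- mask; return(empty) }
  prot <- mask & !body
  labs <- label8(prot)
  dist_from_body <- EBImage::imageData(EBImage::distmap(
    EBImage::Image((!body) * 1)))
  bases <- tips <- list()
  bristle_mask <- prot & FALSE
  k <- 0L
  for (lab in seq_len(max(labs))) {
    comp <- labs == lab
    touch <- adjacent_to(comp, body)
    if (!any(touch)) next                    # floating speck: no base
    dmax <- max(dist_from_body[comp])
    if (dmax < min_length) next              # too stubby to have a tip
    halfw <- max(EBImage::imageData(EBImage::distmap(EBImage::Image(comp * 1))))
    if (halfw > max_halfwidth) next          # wide sliver, not a bristle
    k <- k + 1L
    # base = the attachment pixel ON the body (not the first bristle
    # pixel outside it), so base regressions track the true flank line
    attach <- adjacent_to(body, comp)
    bw <- unname(which(attach, arr.ind = TRUE)[1, ])
    tw <- unname(which(comp & dist_from_body == dmax, arr.ind = TRUE)[1, ])
    bases[[k]] <- c(row = bw[1] - 1, col = bw[2] - 1)
    tips[[k]] <- c(row = tw[1] - 1, col = tw[2] - 1)
    bristle_mask <- bristle_mask | comp
  }
  structure(list(count = k,
                 bases = as.data.frame(do.call(rbind, bases) %||%
                                         cbind(row = numeric(0), col = numeric(0))),
                 tips = as.data.frame(do.call(rbind, tips) %||%
                                        cbind(row = numeric(0), col = numeric(0))),
                 body_mask = body, bristle_mask = bristle_mask),
            class = "taa_bristles")
}

#' @export
print.taa_bristles <- function(x, ...) {
  cat(sprintf("<taa_bristles> %d bristles, body %d px\n", x$count,
              sum(x$body_mask)))
  invisible(x)
}

#' Panicle height from bristle bases
#'
#' Bristle bases are split into left and right flanks by the body's
#' centroid column and a least-squares line is fitted through each
#' flank's bases; the apex is the intersection row when the lines
#' intersect above the lowest base. Otherwise (parallel lines, too few
#' bases) the fallback is the first white non-bristle pixel row from the
#' top. Height is the image bottom row minus the apex row.
#'
#' @param mask Logical panicle mask.
#' @param bristles Result of [detect_bristles()] on the same mask.
#' @return Height in pixels (scalar), with attribute `method`
#'   (`"regression"` or `"first_white_row"`).
#' @export
panicle_height <- function(mask, bristles = detect_bristles(mask)) {
  mask <- mask > 0
  if (!any(mask)) stop("empty mask: panicle height undefined")
  bottom <- nrow(mask) - 1
  apex <- NULL
  b <- bristles$bases
  if (nrow(b) >= 4) {
    ctr <- mean(which(bristles$body_mask | mask, arr.ind = TRUE)[, 2] - 1)
    left <- b[b$col < ctr, ]; right <- b[b$col >= ctr, ]
    if (nrow(left) >= 2 && nrow(right) >= 2 &&
        length(unique(left$col)) > 1 && length(unique(right$col)) > 1) {
      fl <- stats::lm(row ~ col, data = left)
      fr <- stats::lm(row ~ col, data = right)
      bl <- stats::coef(fl); br <- stats::coef(fr)
      if (is.finite(bl[2]) && is.finite(br[2]) &&
          abs(bl[2] - br[2]) > 1e-9) {
        xi <- (br[1] - bl[1]) / (bl[2] - br[2])
        ri <- unname(bl[1] + bl[2] * xi)
        if (ri < max(b$row)) apex <- max(0, ri)   # intersects above lowest base
      }
    }
  }
  method <- "regression"
  if (is.null(apex)) {
    method <- "first_white_row"
    nonbristle <- mask & !bristles$bristle_mask
    if (!any(nonbristle)) nonbristle <- mask
    apex <- min(which(nonbristle, arr.ind = TRUE)[, 1]) - 1
  }
  structure(bottom - apex, method = method)
}

#' Bristle density of a panicle image series
#'
#' Density is the bristle count divided by the panicle height (bristles
#' per pixel of height), computed per image and averaged over the series
#' (all daytime images after panicle emergence, canonically).
#'
#' @param masks A list of binary panicle masks (or a single mask).
#' @param body_brush,min_length Passed to [detect_bristles()].
#' @return A `taa_panicle_morphometry`: per-image data frame
#'   (`bristle_count`, `height_px`, `density`) plus `mean_density`.
#' @export
bristle_density <- function(masks, body_brush = 9,
                            min_length = body_brush / 2 + 2) {
  if (is.matrix(masks) || (is.array(masks) && length(dim(masks)) == 2))
    masks <- list(masks)
  if (!length(masks)) stop("need at least one mask")
  rows <- lapply(seq_along(masks), function(i) {
    br <- detect_bristles(masks[[i]], body_brush, min_length)
    h <- as.numeric(panicle_height(masks[[i]], br))
    data.frame(image = i, bristle_count = br$count, height_px = h,
               density = if (h > 0) br$count / h else NA_real_)
  })
  per_image <- do.call(rbind, rows)
  if (any(per_image$height_px <= 0)) {
    warning(sum(per_image$height_px <= 0),
            " image(s) with zero panicle height excluded from the mean")
  }
  ok <- per_image$height_px > 0
  structure(list(per_image = per_image,
                 mean_density = mean(per_image$density[ok])),
            class = "taa_panicle_morphometry")
}

#' @export
print.taa_panicle_morphometry <- function(x, ...) {
  cat(sprintf("<taa_panicle_morphometry> %d image(s), mean density %.4f bristles/px\n",
              nrow(x$per_image), x$mean_density))
  invisible(x)
}

#' Leaf midline and its arc length
#'
#' For every mask row containing white pixels, the midpoint is the mean
#' of the leftmost and rightmost white columns; the leaf length is the
#' sum of Euclidean distances between successive midpoints (the distance
#' formula). Rows with no white pixels are bridged by the straight
#' distance between the nearest midpoints on either side.
#'
#' @param mask Logical leaf mask, leaf running vertically; use
#'   `orientation = "horizontal"` to transpose first.
#' @param orientation `"vertical"` (default) or `"horizontal"`.
#' @return A `taa_leaf_midline`: `midpoints` data frame (0-based `row`,
#'   `col`), `length` in pixels, `gaps_bridged`.
#' @export
leaf_midline <- function(mask, orientation = c("vertical", "horizontal")) {
  orientation <- match.arg(orientation)
  mask <- mask > 0
  if (orientation == "horizontal") mask <- t(mask)
  if (!any(mask)) stop("empty mask: no leaf to measure")
  rows <- which(rowSums(mask) > 0)
  mids <- vapply(rows, function(r) {
    w <- which(mask[r, ])
    (min(w) + max(w)) / 2
  }, numeric(1))
  midpoints <- data.frame(row = rows - 1, col = mids - 1)
  dr <- diff(midpoints$row); dc <- diff(midpoints$col)
  structure(list(midpoints = midpoints,
                 length = sum(sqrt(dr^2 + dc^2)),
                 gaps_bridged = sum(dr > 1)),
            class = "taa_leaf_midline")
}

#' @export
print.taa_leaf_midline <- function(x, ...) {
  cat(sprintf("<taa_leaf_midline> %d midpoint rows, length %.2f px (%d gap(s) bridged)\n",
              nrow(x$midpoints), x$length, x$gaps_bridged))
  invisible(x)
}

#' Partition leaf growth into day and night percentages
#'
#' Takes alternating dawn/dusk midline lengths (dawn first: dawn day 1,
#' dusk day 1, dawn day 2, ...). Day growth sums dusk minus same-day
#' dawn, night growth next-dawn minus dusk; both are reported as
#' percentages of total growth. Small negative increments (measurement
#' noise) are clipped to zero, with a warning beyond `tolerance`.
#'
#' @param lengths Numeric vector of alternating dawn/dusk lengths,
#'   starting at dawn, length >= 2.
#' @param tolerance Negative-increment magnitude tolerated silently.
#' @return List with `pct_day_growth`, `pct_night_growth`, and the raw
#'   `day_growth` / `night_growth` in pixels.
#' @export
growth_partition <- function(lengths, tolerance = 1e-6) {
  if (length(lengths) < 2) stop("need at least a dawn and a dusk measurement")
  inc <- diff(lengths)
  if (any(inc < -tolerance))
    warning("negative growth increment(s) clipped to 0 (measurement noise): ",
            paste(signif(inc[inc < -tolerance], 3), collapse = ", "))
  inc <- pmax(inc, 0)
  is_day <- seq_along(inc) %% 2 == 1           # dawn->dusk intervals
  day <- sum(inc[is_day]); night <- sum(inc[!is_day])
  total <- day + night
  if (total == 0) stop("no growth observed: percentages undefined")
  list(pct_day_growth = 100 * day / total,
       pct_night_growth = 100 * night / total,
       day_growth = day, night_growth = night)
}

#' Leaf emergence-time profile
#'
#' Bins emergence events (hour of day) into a 24-bin histogram normalised
#' to fractions, and fits a cubic smoothing spline with 3 equivalent
#' degrees of freedom to the per-hour fractions.
#'
#' @param events Numeric vector of event hours in `[0, 24)`, length >= 1.
#' @param spline_df Equivalent degrees of freedom of the spline
#'   (default 3).
#' @return A `taa_emergence_profile`: `hourly_fraction` (24 values
#'   summing to 1), `hours` (bin centres 0..23), `smoothed` (spline value
#'   per bin), `spline`, `n_events`.
#' @export
emergence_profile <- function(events, spline_df = 3) {
  if (!length(events)) stop("no emergence events")
  if (any(events < 0 | events >= 24)) stop("event hours must lie in [0, 24)")
  counts <- tabulate(floor(events) + 1, nbins = 24)
  frac <- counts / length(events)
  hours <- 0:23
  fit <- stats::smooth.spline(hours, frac, df = spline_df)
  structure(list(hourly_fraction = frac, hours = hours,
                 smoothed = predict(fit, hours)$y, spline = fit,
                 n_events = length(events)),
            class = "taa_emergence_profile")
}

#' @export
print.taa_emergence_profile <- function(x, ...) {
  cat(sprintf("<taa_emergence_profile> %d events, modal hour %d\n",
              x$n_events, x$hours[which.max(x$hourly_fraction)]))
  invisible(x)
}
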