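test_that("HSB binarisation applies the ImageJ-style 0-255 ranges", {
  px <- array(0, c(1, 3, 3))
  px[1, 1, ] <- c(100, 200, 100)   # moderate green: H=85, S=127.5, V=200
  px[1, 2, ] <- c(255, 0, 0)       # pure red: H=0
  px[1, 3, ] <- c(0, 0, 255)       # pure blue: H=170
  m <- binarize_hsb(px)
  expect_equal(as.vector(m), c(TRUE, FALSE, FALSE))

  full <- binarize_hsb(px, c(0, 255), c(0, 255), c(0, 255))
  expect_true(all(full))
  expect_error(binarize_hsb(px, hue_range = c(100, 50)), "min <= max")
  expect_error(binarize_hsb(matrix(0, 3, 3)), "RGB")
})

test_that("bristle counting is exact on synthetic panicles and mirror-invariant", {
  for (n in c(0, 5, 12, 20)) {
    pm <- make_panicle_mask(n_bristles = n, apex_row = 25, dims = c(300, 200),
                            seed = n + 1)
    br <- detect_bristles(pm$mask)
    expect_equal(br$count, n)
    mirrored <- pm$mask[, ncol(pm$mask):1]
    expect_equal(detect_bristles(mirrored)$count, n)
  }
  # a floating speck has no base connection and is not counted
  pm <- make_panicle_mask(3, 25, c(260, 170), seed = 2)
  speck <- pm$mask
  speck[5, 5] <- TRUE
  expect_equal(detect_bristles(speck)$count, 3)
  expect_equal(detect_bristles(matrix(FALSE, 20, 20))$count, 0)
})

test_that("panicle height uses the flank regressions, falling back to first white row", {
  pm <- make_panicle_mask(n_bristles = 8, apex_row = 30, dims = c(220, 170),
                          seed = 3)
  br <- detect_bristles(pm$mask)
  h <- panicle_height(pm$mask, br)
  expect_equal(attr(h, "method"), "regression")
  expect_lt(abs(as.numeric(h) - (219 - 30)), 2)

  # parallel flank lines: vertical-sided rectangle with bristles
  rect <- matrix(FALSE, 100, 80)
  rect[21:100, 20:60] <- TRUE
  for (r in c(40, 60, 80)) {
    rect[r, 61:70] <- TRUE    # right bristles
    rect[r, 10:19] <- TRUE    # left bristles
  }
  br2 <- detect_bristles(rect)
  h2 <- panicle_height(rect, br2)
  expect_equal(attr(h2, "method"), "first_white_row")
  expect_equal(as.numeric(h2), 99 - 20)

  # full-height rectangle: height = image height - 1
  full <- matrix(TRUE, 50, 30)
  expect_equal(as.numeric(panicle_height(full, detect_bristles(full))), 49)
  expect_error(panicle_height(matrix(FALSE, 5, 5)), "empty")
})

test_that("bristle density divides count by height and averages the series", {
  pm <- make_panicle_mask(5, 20, c(250, 180), seed = 7)
  res <- bristle_density(list(pm$mask, pm$mask))
  expect_equal(res$per_image$density,
               res$per_image$bristle_count / res$per_image$height_px)
  expect_equal(res$mean_density, res$per_image$density[1])
  expect_equal(mean(c(0.04, 0.06)), 0.05)      # arithmetic the series mean uses
  # monotonicity: same count over a taller panicle gives lower density
  tall <- make_panicle_mask(5, 20, c(400, 180), seed = 7)
  expect_lt(bristle_density(list(tall$mask))$mean_density, res$mean_density)
})

test_that("leaf midline length follows the distance formula", {
  # 100 white rows in a vertical strip: 99 unit steps
  strip <- make_leaf_mask(data.frame(row = c(10, 109), col = c(30, 30)),
                          width = 9, dims = c(130, 60))
  ml <- leaf_midline(strip$mask)
  expect_equal(ml$length, 99)
  expect_equal(nrow(ml$midpoints), 100)
  expect_gte(ml$length, nrow(ml$midpoints) - 1)

  # 45-degree band across 100 rows: length 99 * sqrt(2) within 1%
  diag <- make_leaf_mask(data.frame(row = c(0, 99), col = c(5, 104)),
                         width = 9, dims = c(100, 120))
  ml2 <- leaf_midline(diag$mask)
  expect_lt(abs(ml2$length - 99 * sqrt(2)) / (99 * sqrt(2)), 0.01)

  # a 5-row gap is bridged by the straight (here collinear) segment
  gap <- strip$mask
  gap[51:55, ] <- FALSE
  mlg <- leaf_midline(gap)
  expect_equal(mlg$length, 99)
  expect_equal(mlg$gaps_bridged, 1)

  # horizontal orientation transposes first
  expect_equal(leaf_midline(t(strip$mask), orientation = "horizontal")$length,
               99)
  # translation invariance
  shifted <- taatrack:::shift_matrix(strip$mask, 0, 12, fill = FALSE)
  expect_equal(leaf_midline(shifted > 0)$length, 99)
  expect_error(leaf_midline(matrix(FALSE, 5, 5)), "empty")
})

test_that("growth partitions into day and night percentages", {
  g <- growth_partition(c(10, 18, 20))
  expect_equal(g$pct_day_growth, 80)
  expect_equal(g$pct_night_growth, 20)
  g2 <- growth_partition(c(10, 20, 20, 30))
  expect_equal(g2$pct_day_growth + g2$pct_night_growth, 100)
  expect_equal(growth_partition(c(5, 9))$pct_day_growth, 100)
  expect_warning(g3 <- growth_partition(c(10, 9, 15)), "clipped")
  expect_equal(g3$pct_day_growth, 0)
  expect_error(growth_partition(c(10)), "at least")
  expect_error(suppressWarnings(growth_partition(c(10, 10, 10))), "no growth")
})

test_that("emergence profiles are probability vectors with a df-3 spline", {
  ev <- make_emergence_schedule(peak_hour = 8, concentration = Inf, n = 50,
                                seed = 1)
  expect_true(all(ev == 8))
  ep <- emergence_profile(ev)
  expect_equal(ep$hourly_fraction[9], 1)
  expect_equal(sum(ep$hourly_fraction), 1)
  expect_true(all(ep$hourly_fraction >= 0))

  spread <- emergence_profile(make_emergence_schedule(8, 0.25, 500, seed = 3))
  expect_equal(sum(spread$hourly_fraction), 1)
  expect_equal(spread$hours[which.max(spread$hourly_fraction)], 8,
               tolerance = 2)

  # uniform events: near-flat smoothed curve
  set.seed(42)
  flat <- emergence_profile(runif(5000, 0, 24))
  expect_lt(max(flat$smoothed) - min(flat$smoothed), 0.02)
  expect_error(emergence_profile(numeric(0)), "no emergence")
  expect_error(emergence_profile(c(3, 25)), "\\[0, 24\\)")
})
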