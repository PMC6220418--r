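test_that("cumulative curves step at TAA times and conserve the total", {
  calls <- data.frame(opened = c(TRUE, TRUE, FALSE),
                      taa_minutes = c(10, 20, NA))
  cc <- cumulative_curve(calls, grid = c(0, 9, 10, 15, 20, 30))
  expect_equal(cc$counts, c(0, 0, 1, 1, 2, 2))
  expect_equal(max(cc$counts), sum(calls$opened))
  none <- cumulative_curve(calls[3, ], grid = 0:5)
  expect_equal(none$counts, rep(0, 6))
})

test_that("anchoring maps counts affinely onto the day ratios", {
  cc <- list(times = 0:10, counts = 0:10)          # linear count growth
  fc <- anchor_scale(cc, 0.2, 0.6)
  expect_equal(fc$open_fraction[1], 0.2)
  expect_equal(fc$open_fraction[11], 0.6)
  expect_equal(fc$open_fraction[6], 0.4)           # midpoint of a linear rise
  expect_true(all(diff(fc$open_fraction) >= 0))

  flat <- anchor_scale(list(times = 0:5, counts = rep(0, 6)), 0.3, 0.7)
  expect_equal(flat$open_fraction, rep(0.3, 6))
  same <- anchor_scale(list(times = 0:5, counts = 0:5), 0.5, 0.5)
  expect_equal(same$open_fraction, rep(0.5, 6))

  expect_error(anchor_scale(cc, 0.6, 0.2), "cannot decrease")
  expect_error(anchor_scale(list(times = 0:2, counts = c(0, 2, 1)), 0.1, 0.5),
               "non-decreasing")
})

test_that("spline rate recovers a known slope within 1% and normalises to 1", {
  times <- seq(0, 720, by = 5)
  slope <- 0.4 / 720                                # fraction per minute
  curve <- structure(list(times = times, clock = (8 + times / 60) %% 24,
                          open_fraction = 0.2 + slope * times),
                     class = "taa_flowering_curve")
  rc <- fit_rate(curve)
  interior <- times > 30 & times < 690
  expect_true(all(abs(rc$rate[interior] - slope) / slope < 0.01))
  expect_equal(max(rc$normalized_rate), 1)

  const <- structure(list(times = times, clock = (8 + times / 60) %% 24,
                          open_fraction = rep(0.3, length(times))),
                     class = "taa_flowering_curve")
  rc0 <- fit_rate(const)
  expect_true(all(abs(rc0$rate) < 1e-6))
  expect_equal(rc0$normalized_rate, rep(0, length(times)))

  expect_error(fit_rate(list(times = 1:3, open_fraction = 1:3 / 10)),
               "4 distinct")
})

test_that("day/night/unopened percentages partition the spikelets", {
  calls <- data.frame(opened = c(rep(TRUE, 8), rep(FALSE, 2)),
                      taa_clock = c(9, 10, 21, 22, 23, 1, 3, 5, NA, NA))
  p <- partition_day_night(calls)
  expect_equal(p$pct_day, 20)
  expect_equal(p$pct_night, 60)
  expect_equal(p$pct_unopened, 20)
  expect_equal(p$pct_day + p$pct_night + p$pct_unopened, 100)

  all_night <- data.frame(opened = TRUE, taa_clock = c(21, 22, 2))
  pn <- partition_day_night(all_night)
  expect_equal(c(pn$pct_day, pn$pct_night, pn$pct_unopened), c(0, 100, 0))
  expect_error(partition_day_night(calls[0, ]), "zero spikelets")
})

test_that("window mean rate agrees with a trapezoid oracle and handles wrap", {
  times <- seq(0, 720, by = 1)                      # minutes from dusk
  clock <- (20 + times / 60) %% 24
  tri <- pmax(0, 1 - abs(times - 360) / 360)        # triangular profile
  rc <- structure(list(times = times, clock = clock, normalized_rate = tri),
                  class = "taa_rate_curve")
  got <- window_mean_rate(rc, c(20, 21.5))
  sel <- times <= 90
  expect_equal(got, oracle_trapezoid_mean(times[sel], tri[sel]),
               tolerance = 0.01)
  # midnight wrap: 23:30 -> 00:30
  expect_equal(window_mean_rate(rc, c(23.5, 0.5)),
               mean(tri[times >= 210 & times <= 270]))
  expect_error(window_mean_rate(rc, c(9, 10)), "does not overlap")

  flat <- structure(list(times = 0:10, clock = 20 + (0:10) / 60,
                         normalized_rate = rep(1, 11)),
                    class = "taa_rate_curve")
  expect_equal(window_mean_rate(flat, c(20, 20.1)), 1)
})

test_that("one-way ANOVA matches the sums-of-squares oracle to 1e-10", {
  set.seed(11)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(3:6, 1), mean = j))
    names(groups) <- paste0("g", seq_len(k))
    got <- one_way_anova(groups)
    want <- oracle_anova(groups)
    expect_equal(got$F, want$F, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    expect_equal(c(got$df1, got$df2), c(want$df1, want$df2))
  }
  # 3 groups of 3 -> the (2, 6) design
  g33 <- list(a = rnorm(3), b = rnorm(3), c = rnorm(3))
  got <- one_way_anova(g33)
  expect_equal(c(got$df1, got$df2), c(2, 6))

  expect_warning(res <- one_way_anova(list(a = c(1, 1), b = c(1, 1))),
                 "identical")
  expect_equal(c(res$F, res$p), c(0, 1))
  expect_error(one_way_anova(list(a = 1:3)), "2 groups")
  expect_error(one_way_anova(list(a = 1:3, b = 2)), "2 replicates")
})

test_that("Holm adjustment follows the step-down formula with monotonicity cap", {
  expect_equal(oracle_holm(c(0.01, 0.03, 0.04)), c(0.03, 0.06, 0.06))
  set.seed(5)
  groups <- list(a = rnorm(4), b = rnorm(4, 1), c = rnorm(4, 2))
  adj <- pairwise_holm(groups)
  raw <- stats::pairwise.t.test(unlist(groups),
                                rep(names(groups), lengths(groups)),
                                p.adjust.method = "none",
                                pool.sd = TRUE)$p.value
  rawv <- raw[lower.tri(raw, diag = TRUE)]
  adjv <- adj[lower.tri(adj, diag = TRUE)]
  expect_equal(sort(adjv), sort(oracle_holm(rawv)))
  expect_true(all(adjv >= rawv))
  # Holm never rejects more than unadjusted testing
  expect_lte(sum(adjv < 0.05), sum(rawv < 0.05))
  # single pair: adjusted equals raw
  two <- list(a = rnorm(3), b = rnorm(3, 1))
  expect_equal(unname(pairwise_holm(two)[1, 1]),
               stats::t.test(two$a, two$b, var.equal = TRUE)$p.value)
})

test_that("distinct accession opening-time distributions separate post-dusk", {
  make_rate <- function(peak_min, seed) {
    times <- seq(0, 720, by = 5)
    with(list(), {
      set.seed(seed)
      taa <- pmin(715, pmax(5, rnorm(40, peak_min, 60)))
      cc <- cumulative_curve(data.frame(opened = TRUE, taa_minutes = taa),
                             grid = times)
      fit_rate(anchor_scale(cc, 0.1, 0.7, start_clock = 20))
    })
  }
  early <- lapply(1:3, function(i) make_rate(60, 100 + i))   # peak after dusk
  late <- lapply(1:3, function(i) make_rate(500, 200 + i))   # peak after midnight
  res <- compare_accessions(list(early = early, late = late),
                            window = c(20, 21.5))
  expect_gt(res$means[["early"]], res$means[["late"]])
  expect_lt(res$anova$p, 0.05)
})
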