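test_that("density-mode centre locates residency clusters", {
  # degenerate: identical estimates give that point and zero-width intervals
  cen <- sp_centre(rep(4.5, 30), rep(12.3, 30))
  expect_equal(cen$centre[["lat"]], 4.5)
  expect_equal(cen$centre[["lon"]], 12.3)
  expect_equal(diff(cen$lat_q), 0)
  expect_equal(diff(cen$lon_q), 0)

  # unimodal scatter: mode within 0.2 degrees of the true centre
  set.seed(101)
  lats <- rnorm(500, 4.5, 0.8); lons <- rnorm(500, 12.3, 0.8)
  cen <- sp_centre(lats, lons)
  expect_lt(abs(cen$centre[["lat"]] - 4.5), 0.2)
  expect_lt(abs(cen$centre[["lon"]] - 12.3), 0.2)
  # mode lies within the data range, quantiles bracket it
  expect_gte(cen$centre[["lat"]], min(lats))
  expect_lte(cen$centre[["lat"]], max(lats))
  expect_lt(cen$lat_q[1], cen$lat_q[2])

  # 60/40 mixture of well-separated clusters: mode at the heavier cluster
  set.seed(102)
  lats <- c(rnorm(300, 4.5, 0.4), rnorm(200, -20, 0.4))
  lons <- c(rnorm(300, 12.3, 0.4), rnorm(200, 24, 0.4))
  cen <- sp_centre(lats, lons)
  expect_lt(abs(cen$centre[["lat"]] - 4.5), 0.3)
  expect_lt(abs(cen$centre[["lon"]] - 12.3), 0.3)
})

test_that("nearby stationary periods merge and recompute their centre", {
  mk <- function(start, days, lat, lon, sd = 0) {
    set.seed(start)
    stationary_period(start, start + days - 1,
                      lat + rnorm(days, 0, sd), lon + rnorm(days, 0, sd))
  }
  # 150 km apart (1.35 deg of latitude): merged into one period
  two <- merge_stationary_periods(list(mk(280, 30, 4.5, 12.3),
                                       mk(320, 30, 4.5 + 1.35, 12.3)))
  expect_length(two, 1)
  expect_equal(two[[1]]$start, 280)
  expect_equal(two[[1]]$end, 349)
  expect_length(two[[1]]$daily_lats, 60)

  # 250 km apart: left alone
  apart <- merge_stationary_periods(list(mk(280, 30, 4.5, 12.3),
                                         mk(320, 30, 4.5 + 2.25, 12.3)))
  expect_length(apart, 2)

  # chain at ~145 km steps with a dominant middle period: collapses to one
  # via iterative re-merging (fixed point), reproducing a by-hand pairwise
  # merge oracle
  chain <- list(mk(270, 20, 4.5, 12.3),
                mk(295, 60, 4.5 + 1.3, 12.3),
                mk(360, 40, 4.5 + 2.6, 12.3))
  merged <- merge_stationary_periods(chain)
  expect_length(merged, 1)
  expect_equal(merged[[1]]$start, 270)
  expect_equal(merged[[1]]$end, 399)
  # pooled mode sits at the dominant (60-day) cluster
  expect_lt(abs(merged[[1]]$centre[["lat"]] - (4.5 + 1.3)), 0.2)

  # empty input passes through
  expect_length(merge_stationary_periods(list()), 0)

  # after merge + filter, consecutive centres are >= 200 km apart and all
  # durations >= 14 d (joint fixed point)
  set.seed(9)
  sps <- lapply(1:5, function(i)
    mk(250 + 35 * i, sample(10:40, 1), 4.5 + 0.9 * i, 12.3, sd = 0.1))
  out <- filter_short_sps(merge_stationary_periods(sps))
  if (length(out) > 1)
    for (i in seq_len(length(out) - 1))
      expect_gte(great_circle_km(out[[i]]$centre, out[[i + 1]]$centre), 200)
  for (sp in out) expect_gte(sp$duration, 14)
})

test_that("duration filter drops stopovers shorter than 14 days", {
  mk <- function(days) stationary_period(100, 100 + days - 1,
                                         rep(4, days), rep(12, days))
  out <- filter_short_sps(list(mk(13), mk(14), mk(30)))
  expect_equal(vapply(out, function(s) s$duration, numeric(1)), c(14, 30))
  expect_length(filter_short_sps(list()), 0)
})

test_that("itinerancy classification picks the longest period as main", {
  mk <- function(start, days, lat = 4) stationary_period(
    start, start + days - 1, rep(lat, days), rep(12, days))

  one <- classify_itinerancy(list(mk(280, 120)))
  expect_false(one$itinerant)
  expect_equal(one$main, 1L)
  expect_equal(one$first, 1L)
  expect_equal(one$last, 1L)

  two <- classify_itinerancy(list(mk(280, 40), mk(330, 120)))
  expect_true(two$itinerant)
  expect_equal(two$main, 2L)
  expect_equal(two$first, 1L)
  expect_equal(two$last, 2L)

  # equal durations: earlier period is main
  tie <- classify_itinerancy(list(mk(280, 60), mk(350, 60)))
  expect_equal(tie$main, 1L)

  expect_error(classify_itinerancy(list()), "no stationary periods")
})
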