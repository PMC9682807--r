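test_that("great-circle distance matches independent formulas and bounds", {
  expect_equal(great_circle_km(geo_point(0, 0), geo_point(0, 0)), 0)

  # a 1.56 degree latitude shift is about 174 km
  d <- great_circle_km(geo_point(0, 10), geo_point(1.56, 10))
  expect_equal(d, 173.5, tolerance = 0.002)

  # along the 17th parallel, cross-check against the spherical law of cosines
  d2 <- great_circle_km(geo_point(17, 0), geo_point(17, 10))
  expect_equal(d2, slc_km(17, 0, 17, 10), tolerance = 1e-9)
  expect_equal(d2, 1062.7, tolerance = 1e-3)

  # agreement with geosphere's haversine at matched radius
  skip_if_not_installed("geosphere")
  p <- c(46.15, 8.92); q <- c(4.5, 12.3)
  expect_equal(great_circle_km(geo_point(p[1], p[2]), geo_point(q[1], q[2])),
               geosphere::distHaversine(c(p[2], p[1]), c(q[2], q[1]),
                                        r = R_EARTH * 1000) / 1000,
               tolerance = 1e-9)
})

test_that("great-circle distance is symmetric, bounded and triangular", {
  set.seed(42)
  for (rep in 1:50) {
    lat <- runif(3, -80, 80); lon <- runif(3, -180, 180)
    p <- geo_point(lat[1], lon[1]); q <- geo_point(lat[2], lon[2])
    r <- geo_point(lat[3], lon[3])
    dpq <- great_circle_km(p, q)
    expect_gte(dpq, 0)
    expect_lte(dpq, pi * R_EARTH + 1e-9)
    expect_equal(dpq, great_circle_km(q, p), tolerance = 1e-12)
    expect_lte(dpq, great_circle_km(p, r) + great_circle_km(r, q) + 1e-9 * dpq)
  }
})

test_that("path length is zero for a point, additive, and >= endpoint chord", {
  expect_equal(path_length_km(poly_track(10, 10, 1)), 0)
  expect_equal(path_length_km(poly_track(c(0, 0), c(0, 1), 1:2)),
               111.2, tolerance = 1e-3)
  # meridian collinearity: polyline length equals the single great circle
  mer <- poly_track(c(0, 5, 10), c(0, 0, 0), 1:3)
  expect_equal(path_length_km(mer),
               great_circle_km(geo_point(0, 0), geo_point(10, 0)),
               tolerance = 1e-9)
  set.seed(7)
  for (rep in 1:20) {
    tr <- random_track(15)
    expect_gte(path_length_km(tr) + 1e-9,
               great_circle_km(geo_point(tr$lat[1], tr$lon[1]),
                               geo_point(tr$lat[15], tr$lon[15])))
  }
})

test_that("latitude-band clipping truncates at interpolated boundaries", {
  inside <- poly_track(c(40, 30, 20), c(5, 6, 7), 1:3)
  expect_equal(as.data.frame(clip_to_lat_band(inside)),
               as.data.frame(inside))

  two <- clip_to_lat_band(poly_track(c(46, 16), c(0, 0), c(0, 30)))
  expect_equal(two$lat, c(45, 17))
  expect_equal(two$lon, c(0, 0))
  # day interpolated linearly with latitude on the crossing segment
  expect_equal(two$day, c(1, 29), tolerance = 1e-9)

  expect_error(clip_to_lat_band(poly_track(c(50, 48), c(0, 0), 1:2)),
               "does not intersect")

  # idempotence, including a track that exits and re-enters the band
  zig <- poly_track(c(50, 30, 10, 30, 50), c(0, 2, 4, 6, 8), 1:5)
  once <- clip_to_lat_band(zig)
  expect_equal(as.data.frame(clip_to_lat_band(once)), as.data.frame(once))
  expect_true(all(once$lat >= 17 & once$lat <= 45))
})

test_that("equal-arc resampling spans endpoints with even spacing", {
  tr <- poly_track(c(17, 45), c(3, 3), c(1, 20))
  expect_equal(unname(resample_equal_arc(tr, 2)),
               unname(cbind(c(17, 45), c(3, 3))))
  pts <- resample_equal_arc(tr, 20)
  expect_equal(pts[, "lat"], 17 + 28 * (0:19) / 19, tolerance = 1e-9)

  expect_error(resample_equal_arc(poly_track(5, 5, 1), 20), "zero-length")

  # reversal: resampling the reversed track yields the reversed sequence
  wt <- wiggle_track()
  rev_wt <- poly_track(rev(wt$lat), rev(wt$lon), wt$day)
  expect_equal(resample_equal_arc(rev_wt, 20),
               resample_equal_arc(wt, 20)[20:1, ], tolerance = 1e-9)

  # k = 20 captures a smooth route's length to within 2%
  for (phase in c(0, 1, 2)) {
    sm <- wiggle_track(phase = phase)
    pts20 <- resample_equal_arc(sm, 20)
    len20 <- path_length_km(poly_track(pts20[, 1], pts20[, 2], 1:20))
    expect_equal(len20, path_length_km(sm), tolerance = 0.02)
  }
})
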