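test_that("cohort generation is deterministic given config and seed", {
  cfg <- generator_config(n_individuals = 8, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$truth, b$truth)
  expect_identical(a$sp_candidates, b$sp_candidates)

  c2 <- generate_cohort(generator_config(n_individuals = 8, seed = 100))
  expect_false(identical(a$tracks$lat, c2$tracks$lat))
})

test_that("routes lie on the template when offset and jitter are zero", {
  colony <- geo_point(45.55, 8.73)
  sp <- geo_point(4.5, 12.3)
  tr <- generate_route(colony, sp, ROUTE_TEMPLATE_POST,
                       lateral_offset = 0, jitter_sd = 0, n_fixes = 60,
                       start_day = 250, end_day = 280)
  expect_equal(tr$lat[1], 45.55, tolerance = 1e-9)
  expect_equal(tr$lat[60], 4.5, tolerance = 1e-9)
  # every fix sits on the waypoint polyline: distance to it is ~0
  base <- poly_track(c(45.55, ROUTE_TEMPLATE_POST[, "lat"], 4.5),
                     c(8.73, ROUTE_TEMPLATE_POST[, "lon"], 12.3),
                     seq_len(nrow(ROUTE_TEMPLATE_POST) + 2))
  dense <- resample_equal_arc(base, 2000)
  for (i in seq(1, 60, by = 7)) {
    d <- min(great_circle_matrix_km(cbind(lat = tr$lat[i], lon = tr$lon[i]),
                                    dense))
    expect_lt(d, 2)
  }
  # path length always at least the endpoint great circle
  expect_gte(path_length_km(tr), great_circle_km(colony, sp))
})

test_that("lateral offsets separate routes the way OWD expects", {
  colony <- geo_point(45.55, 8.73)
  sp <- geo_point(4.5, 12.3)
  mk <- function(off) generate_route(colony, sp, ROUTE_TEMPLATE_POST,
                                     lateral_offset = off, jitter_sd = 0,
                                     n_fixes = 60, start_day = 250,
                                     end_day = 280)
  plus3a <- mk(3); plus3b <- mk(3); minus3 <- mk(-3)
  expect_gt(owd(plus3a, minus3)$owd, owd(plus3a, plus3b)$owd)
  expect_equal(owd(plus3a, plus3b)$owd, 0, tolerance = 1e-9)
})

test_that("observation noise is seeded, unbiased and half-normal in magnitude", {
  tr <- wiggle_track(n = 10000)
  expect_equal(as.data.frame(add_observation_noise(tr, 0, 0)),
               as.data.frame(tr))
  n1 <- add_observation_noise(tr, 1.5, 0.7, seed = 12)
  n2 <- add_observation_noise(tr, 1.5, 0.7, seed = 12)
  expect_identical(n1$lat, n2$lat)

  # mean |displacement| per axis approximates sd * sqrt(2 / pi)
  dl <- abs(n1$lat - tr$lat)
  dn <- abs(n1$lon - tr$lon)
  expect_equal(mean(dl), 1.5 * sqrt(2 / pi), tolerance = 0.03)
  expect_equal(mean(dn), 0.7 * sqrt(2 / pi), tolerance = 0.03)
})

test_that("carry-over chain regenerates its stated slopes at scale", {
  cfg <- generator_config(seed = 1)
  set.seed(202)
  tm <- simulate_carryover(20000, cfg)
  f1 <- stats::lm(ad_sp ~ dd_c, tm)
  expect_equal(unname(coef(f1)[2]), cfg$slope_ad_on_dd, tolerance = 0.05)
  f2 <- stats::lm(dd_sp ~ ad_sp, tm)
  expect_equal(unname(coef(f2)[2]), cfg$slope_ddsp_on_adsp, tolerance = 0.05)
  r_dd <- residualize(tm$dd_sp, data.frame(ad_sp = tm$ad_sp))
  f3 <- stats::lm(tm$ms_prb ~ r_dd)
  expect_equal(unname(coef(f3)[2]), cfg$slope_ms_on_rdd, tolerance = 0.05)
})

test_that("generated cohorts carry the advertised structure", {
  co <- generate_cohort(generator_config(n_individuals = 40, seed = 17))
  tr <- co$tracks
  expect_true(all(tr$lat >= -90 & tr$lat <= 90))
  expect_true(all(c("individual_id", "sex", "year", "study_area", "time",
                    "twilight", "lat", "lon") %in% names(tr)))
  # twilight cadence: about two fixes per tracked day on average
  cadence <- nrow(tr) / length(unique(paste(tr$individual_id, floor(tr$day))))
  expect_lte(cadence, 2.2)
  expect_gte(cadence, 1.6)
  # availability bookkeeping matches the events table
  both <- co$truth$availability == "both"
  expect_equal(!is.na(co$colony_events$dd_c),
               co$truth$availability %in% c("both", "post"))
  expect_equal(!is.na(co$colony_events$ad_c),
               co$truth$availability %in% c("both", "pre"))
  # southern outliers are male
  expect_true(all(co$truth$sex[co$truth$southern] == "M"))
})
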