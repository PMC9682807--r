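# Per-episode migration features and cohort exclusion rules.
#
# Feature symbols follow the field's convention for geolocator studies:
#   DD  departure date (day offset), AD  arrival date,
#   LMP length of migration path (km) - sum of step-by-step distances,
#   PS  path straightness (%)        - great-circle / LMP * 100,
#   DM  duration of migration (d)    - AD - DD,
#   MS  migration speed (km/day)     - LMP / DM.

#' Compute migration features for one episode
#'
#' The migration path runs from the breeding colony to the first stationary
#' period south of the Sahara (post-breeding) or from the last stationary
#' period to the colony (pre-breeding). The colony and the SP centre are
#' appended as virtual endpoints if the reconstructed track does not reach
#' them exactly, so LMP always spans the full colony-SP journey and PS is
#' never above 100.
#'
#' @param track a [poly_track()] covering the migration episode
#' @param colony breeding-colony [geo_point()]
#' @param sp_point terminal stationary-period centre ([geo_point()])
#' @param dd,ad departure and arrival day offsets (`ad > dd`)
#' @param season `"post"` or `"pre"`
#' @return list with `season`, `DD`, `AD`, `DM`, `LMP`, `PS`, `MS`
#' @export
compute_episode_features <- function(track, colony, sp_point, dd, ad,
                                     season = c("post", "pre")) {
  season <- match.arg(season)
  if (ad <= dd) stop("arrival date must be after departure date (AD > DD)")
  ends <- if (season == "post") list(colony, sp_point) else list(sp_point, colony)
  track <- append_endpoints(track, ends[[1]], ends[[2]])
  lmp <- path_length_km(track)
  if (lmp <= 0) stop("zero-length migration track")
  gc <- great_circle_km(ends[[1]], ends[[2]])
  dm <- ad - dd
  list(season = season, DD = dd, AD = ad, DM = dm,
       LMP = lmp, PS = 100 * gc / lmp, MS = lmp / dm)
}

append_endpoints <- function(track, origin, terminus, tol_km = 1) {
  lat <- track$lat; lon <- track$lon; day <- track$day
  if (great_circle_km(geo_point(lat[1], lon[1]), origin) > tol_km) {
    lat <- c(origin[["lat"]], lat); lon <- c(origin[["lon"]], lon)
    day <- c(day[1] - 1e-6, day)
  }
  n <- length(lat)
  if (great_circle_km(geo_point(lat[n], lon[n]), terminus) > tol_km) {
    lat <- c(lat, terminus[["lat"]]); lon <- c(lon, terminus[["lon"]])
    day <- c(day, day[n] + 1e-6)
  }
  poly_track(lat, lon, day)
}

#' Movement features of itinerant individuals between stationary periods
#'
#' Applies the episode formulas to the between-SP movement of an itinerant
#' individual: path length of the polyline through consecutive SP centres
#' (or of the observed inter-SP track when supplied), straightness relative
#' to the first-to-last SP great circle, and speed using the total gap in
#' days between SP occupancies.
#'
#' @param cls result of [classify_itinerancy()] for an itinerant individual
#' @param track optional [poly_track()] of the observed between-SP movement;
#'   when `NULL` the SP-centre polyline is used
#' @return list with `path_km`, `straightness_pct`, `gap_days`, `speed_km_day`
#' @export
itinerancy_movement_features <- function(cls, track = NULL) {
  if (!cls$itinerant) stop("individual is not itinerant")
  sps <- cls$sps
  centres_lat <- vapply(sps, function(s) s$centre[["lat"]], numeric(1))
  centres_lon <- vapply(sps, function(s) s$centre[["lon"]], numeric(1))
  if (is.null(track))
    track <- poly_track(centres_lat, centres_lon,
                        vapply(sps, function(s) s$start, numeric(1)))
  first <- sps[[1]]; last <- sps[[length(sps)]]
  track <- append_endpoints(track, first$centre, last$centre)
  path <- path_length_km(track)
  gc <- great_circle_km(first$centre, last$centre)
  gaps <- sum(vapply(seq_len(length(sps) - 1), function(i)
    sps[[i + 1]]$start - sps[[i]]$end, numeric(1)))
  if (gaps <= 0) stop("stationary periods must be separated by a positive gap")
  list(path_km = path,
       straightness_pct = 100 * gc / path,
       gap_days = gaps,
       speed_km_day = path / gaps)
}

#' Apply cohort exclusion rules
#'
#' Splits a cohort table into the analysis set and the descriptive-only
#' groups: individuals deployed in an excluded year (to keep the year
#' factor two-level) and individuals whose main non-breeding area lies
#' strictly south of a latitude cut (default 10 S - long-distance outliers
#' with distinct migration patterns).
#'
#' @param cohort data frame with at least `year` and `main_sp_lat` columns
#' @param exclude_years years dropped from analyses (default 2012)
#' @param southern_lat latitude cut in degrees (default -10); individuals
#'   with `main_sp_lat < southern_lat` are excluded (strict)
#' @return list of data frames: `analysis`, `excluded_year`,
#'   `excluded_southern`
#' @export
apply_exclusions <- function(cohort, exclude_years = 2012, southern_lat = -10) {
  yr <- cohort$year %in% exclude_years
  so <- !yr & !is.na(cohort$main_sp_lat) & cohort$main_sp_lat < southern_lat
  list(analysis = cohort[!yr & !so, , drop = FALSE],
       excluded_year = cohort[yr, , drop = FALSE],
       excluded_southern = cohort[so, , drop = FALSE])
}
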