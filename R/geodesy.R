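# Spherical-Earth geometry for twilight-resolution tracks.
#
# All distances use the haversine formula on a sphere of mean radius
# 6371.0088 km. Longitudes are normalized to (-180, 180]; the study domain
# (ca. 20 W - 50 E) is far from the antimeridian, which is not handled
# specially.

#' Mean Earth radius (km) used throughout the package
#' @keywords internal
EARTH_RADIUS_KM <- 6371.0088

#' Normalize longitudes to (-180, 180]
#' @param lon numeric vector of longitudes in degrees
#' @return numeric vector in (-180, 180]
#' @keywords internal
normalize_lon <- function(lon) {
  out <- ((lon + 180) %% 360) - 180
  out[out == -180] <- 180
  out
}

#' Construct a geographic point
#'
#' A `geo_point` is a named numeric vector `c(lat, lon)` with latitude in
#' `[-90, 90]` and longitude normalized to `(-180, 180]`.
#'
#' @param lat latitude in degrees
#' @param lon longitude in degrees
#' @return a `geo_point`
#' @export
geo_point <- function(lat, lon) {
  stopifnot(length(lat) == 1L, length(lon) == 1L,
            is.finite(lat), is.finite(lon))
  if (lat < -90 || lat > 90) stop("latitude out of [-90, 90]: ", lat)
  structure(c(lat = lat, lon = normalize_lon(lon)), class = "geo_point")
}

#' Construct an ordered, time-stamped track
#'
#' A `poly_track` is a data frame with columns `lat`, `lon` and `day`
#' (continuous day offset; day 1 is January 1st of the deployment year,
#' spring dates continue past 365). Times must be strictly increasing.
#'
#' @param lat,lon numeric vectors of coordinates in degrees
#' @param day strictly increasing numeric vector of day offsets
#' @return a `poly_track` data frame
#' @export
poly_track <- function(lat, lon, day = seq_along(lat)) {
  n <- length(lat)
  stopifnot(n >= 1L, length(lon) == n, length(day) == n,
            all(is.finite(lat)), all(is.finite(lon)), all(is.finite(day)))
  if (any(lat < -90 | lat > 90)) stop("latitude out of [-90, 90]")
  if (n > 1L && any(diff(day) <= 0)) stop("track times must be strictly increasing")
  structure(data.frame(lat = lat, lon = normalize_lon(lon), day = day),
            class = c("poly_track", "data.frame"))
}

#' @export
print.poly_track <- function(x, ...) {
  cat(sprintf("<poly_track: %d fixes, days %.2f-%.2f, lat %.2f-%.2f>\n",
              nrow(x), min(x$day), max(x$day), min(x$lat), max(x$lat)))
  invisible(x)
}

as_lonlat_matrix <- function(track) {
  cbind(track$lon, track$lat)
}

# vectorized haversine kernel; all package distances flow through here so
# that path lengths, merge thresholds and OWD sums are mutually consistent
haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad / 2
  dlon <- (lon2 - lon1) * rad / 2
  a <- sin(dlat)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon)^2
  a[a > 1] <- 1  # clamp rounding overshoot; keeps matrix dims
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Great-circle distance between two points (km)
#'
#' Haversine distance on a sphere of radius 6371.0088 km.
#'
#' @param p,q points: `geo_point` objects or `c(lat, lon)` vectors
#' @return distance in km
#' @examples
#' great_circle_km(geo_point(0, 0), geo_point(1.56, 0))  # ca. 174 km
#' @export
great_circle_km <- function(p, q) {
  haversine_km(p[["lat"]], p[["lon"]], q[["lat"]], q[["lon"]])
}

#' Pairwise great-circle distances (km) between two coordinate sets
#'
#' @param a,b matrices or data frames with columns `lat`, `lon`
#' @return an `nrow(a)` x `nrow(b)` matrix of distances in km
#' @export
great_circle_matrix_km <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  na <- nrow(a); nb <- nrow(b)
  haversine_km(matrix(a[, "lat"], na, nb), matrix(a[, "lon"], na, nb),
               matrix(b[, "lat"], na, nb, byrow = TRUE),
               matrix(b[, "lon"], na, nb, byrow = TRUE))
}

#' Cumulative step distances along a track (km)
#' @param track a `poly_track`
#' @return numeric vector of length `nrow(track)`; first element 0
#' @keywords internal
cum_path_km <- function(track) {
  n <- nrow(track)
  if (n == 1L) return(0)
  c(0, cumsum(haversine_km(track$lat[-n], track$lon[-n],
                           track$lat[-1], track$lon[-1])))
}

#' Total path length of a track (km)
#'
#' Sum of step-by-step great-circle distances along the polyline.
#'
#' @param track a `poly_track`
#' @return length in km (0 for a single-point track)
#' @export
path_length_km <- function(track) {
  cp <- cum_path_km(track)
  cp[length(cp)]
}

#' Clip a track to a latitude band
#'
#' Retains the sections of a track lying between `lat_min` and `lat_max`.
#' Segments crossing a band boundary are truncated at a boundary point
#' interpolated linearly in (lat, lon, day) on the crossing segment; every
#' in-band section is kept, concatenated in time order. The defaults bound
#' the Sahara's southern margin (17 N) and the southernmost breeding area
#' (45 N) so that route-similarity comparisons are not driven by differing
#' overall route lengths.
#'
#' @param track a `poly_track`
#' @param lat_min,lat_max band limits in degrees (default 17 and 45)
#' @return a clipped `poly_track`
#' @export
clip_to_lat_band <- function(track, lat_min = 17, lat_max = 45) {
  stopifnot(lat_min < lat_max)
  lat <- track$lat; lon <- track$lon; day <- track$day
  n <- length(lat)
  inb <- function(x) x >= lat_min & x <= lat_max

  out_lat <- numeric(0); out_lon <- numeric(0); out_day <- numeric(0)
  push <- function(la, lo, dy) {
    m <- length(out_lat)
    if (m > 0 && abs(out_lat[m] - la) < 1e-12 && abs(out_lon[m] - lo) < 1e-12) return()
    out_lat[m + 1] <<- la; out_lon[m + 1] <<- lo; out_day[m + 1] <<- dy
  }
  # interpolate the crossing of boundary latitude `b` on segment i -> i+1
  crossing <- function(i, b) {
    f <- (b - lat[i]) / (lat[i + 1] - lat[i])
    c(b, lon[i] + f * (lon[i + 1] - lon[i]), day[i] + f * (day[i + 1] - day[i]))
  }

  if (inb(lat[1])) push(lat[1], lon[1], day[1])
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      a <- lat[i]; b <- lat[i + 1]
      if (a == b) { if (inb(b)) push(b, lon[i + 1], day[i + 1]); next }
      # boundaries crossed by this segment, in traversal order
      for (bd in sort(c(lat_min, lat_max)[c(lat_min, lat_max) > min(a, b) &
                                          c(lat_min, lat_max) < max(a, b)],
                      decreasing = a > b)) {
        cr <- crossing(i, bd)
        push(cr[1], cr[2], cr[3])
      }
      if (inb(b)) push(b, lon[i + 1], day[i + 1])
    }
  }
  if (length(out_lat) == 0)
    stop("track does not intersect latitude band [", lat_min, ", ", lat_max, "]")
  # strictly increasing days can collapse at duplicated boundary points
  keep <- c(TRUE, diff(out_day) > 0)
  poly_track(out_lat[keep], out_lon[keep], out_day[keep])
}

#' Resample a track to k points equally spaced in arc length
#'
#' Returns `k` points at cumulative arc distances `i * L / (k - 1)`,
#' `i = 0 .. k-1`, along the polyline (both endpoints included). Points
#' falling inside a segment are obtained by fractional linear interpolation
#' along that segment.
#'
#' @param track a `poly_track` with positive path length
#' @param k number of points (>= 2); default 20
#' @return a `k` x 2 matrix with columns `lat`, `lon`
#' @export
resample_equal_arc <- function(track, k = 20) {
  stopifnot(k >= 2)
  cp <- cum_path_km(track)
  L <- cp[length(cp)]
  if (L <= 0) stop("cannot resample a zero-length track")
  targets <- L * (seq_len(k) - 1) / (k - 1)
  lat <- numeric(k); lon <- numeric(k)
  j <- 1L
  for (i in seq_len(k)) {
    d <- targets[i]
    while (j < length(cp) - 1L && cp[j + 1] < d) j <- j + 1L
    seg <- cp[j + 1] - cp[j]
    f <- if (seg > 0) (d - cp[j]) / seg else 0
    f <- min(max(f, 0), 1)
    lat[i] <- track$lat[j] + f * (track$lat[j + 1] - track$lat[j])
    lon[i] <- track$lon[j] + f * (track$lon[j + 1] - track$lon[j])
  }
  cbind(lat = lat, lon = lon)
}
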