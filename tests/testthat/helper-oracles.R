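# Independent oracles used across the suite. These deliberately re-derive
# quantities through different code paths (explicit loops, closed forms)
# than the package implementation.

R_EARTH <- 6371.0088

# spherical law of cosines - independent closed form for great-circle km
slc_km <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  cd <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  R_EARTH * acos(pmin(1, pmax(-1, cd)))
}

# scalar haversine written independently of the package kernel
hav_km <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  a <- sin((lat2 - lat1) * r / 2)^2 +
    cos(lat1 * r) * cos(lat2 * r) * sin((lon2 - lon1) * r / 2)^2
  2 * R_EARTH * asin(min(1, sqrt(a)))
}

# brute-force OWD oracle: explicit k x k loops, no shared code with owd()
owd_oracle <- function(track_a, track_b, k = 20, lat_min = 17, lat_max = 45) {
  clip_rs <- function(tr) {
    cl <- clip_to_lat_band(tr, lat_min, lat_max)
    pts <- resample_equal_arc(cl, k)
    len <- 0
    for (i in seq_len(k - 1))
      len <- len + hav_km(pts[i, 1], pts[i, 2], pts[i + 1, 1], pts[i + 1, 2])
    list(pts = pts, len = len)
  }
  a <- clip_rs(track_a); b <- clip_rs(track_b)
  dm <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    dm[i, j] <- hav_km(a$pts[i, 1], a$pts[i, 2], b$pts[j, 1], b$pts[j, 2])
  d_ab <- sum(vapply(seq_len(k), function(i) min(dm[i, ]), numeric(1))) / a$len
  d_ba <- sum(vapply(seq_len(k), function(j) min(dm[, j]), numeric(1))) / b$len
  list(d_ab = d_ab, d_ba = d_ba, owd = (d_ab + d_ba) / 2)
}

# a smooth synthetic migration-like track for geometry tests
wiggle_track <- function(lat_from = 46, lat_to = 4, lon0 = 10, amp = 2,
                         n = 80, phase = 0) {
  lat <- seq(lat_from, lat_to, length.out = n)
  lon <- lon0 + amp * sin(seq(0, 3 * pi, length.out = n) + phase)
  poly_track(lat, lon, seq_len(n))
}

# random jagged track crossing the band, for property tests
random_track <- function(n = 30) {
  lat <- sort(runif(n, 0, 50), decreasing = TRUE)
  lon <- cumsum(c(runif(1, -5, 15), runif(n - 1, -1.5, 1.5)))
  poly_track(lat, lon, seq_len(n))
}

# small zero-noise generator configuration for exact round-trip checks
zero_noise_config <- function(n = 10, seed = 5, ...) {
  generator_config(
    n_individuals = n, seed = seed,
    lateral_offset_sd_post = 0, lateral_offset_sd_pre = 0,
    route_jitter_sd = 0, residency_scatter_sd = 0,
    obs_sd_lat = 0, obs_sd_lon = 0, ...)
}
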