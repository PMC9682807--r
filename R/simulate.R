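# Seeded generator of synthetic loop-migration cohorts.
#
# Emulates a geolocator study of barn swallows breeding in three areas of
# the Po plain / pre-Alps that winter around (4.5 N, 12.3 E) in the Congo
# basin and follow a clockwise loop: a central-Mediterranean flyway
# southbound (Corsica - Sardinia - Tunisia - central Sahara) and a western
# detour northbound (Atlantic coast of West Africa - Iberia - western
# Mediterranean). Timing follows a linear-Gaussian carry-over chain
# DD_c -> AD_sp -> DD_sp -> MS_prb -> AD_c whose slopes are config-exposed
# so null cohorts are obtained by zeroing them. A truth table records all
# latent draws for parameter-recovery tests.

#' Breeding-colony coordinates of the three study areas
#' @keywords internal
STUDY_COLONIES <- list(
  N = c(lat = 46.150, lon = 8.9167),   # Magadino, southern Switzerland
  SW = c(lat = 45.550, lon = 8.7333),  # Piedmont
  SE = c(lat = 45.3167, lon = 9.6667)) # Lombardy

# Southbound template: central Mediterranean and central Sahara.
ROUTE_TEMPLATE_POST <- cbind(
  lat = c(43.5, 41.5, 39.0, 36.6, 32.0, 26.0, 20.0, 15.0, 10.0),
  lon = c(9.2, 9.2, 9.0, 10.2, 10.8, 11.2, 11.6, 12.0, 12.2))

# Northbound template: a western detour over the Atlantic side of West
# Africa, Morocco and Iberia, re-entering Europe via the western
# Mediterranean (about 7% longer than the southbound route).
ROUTE_TEMPLATE_PRE <- cbind(
  lat = c(5.5, 8.0, 12.0, 17.0, 23.0, 29.0, 34.0, 38.5, 41.5, 43.5),
  lon = c(10.0, 6.0, 2.0, -1.5, -3.5, -3.5, -2.0, 0.0, 2.5, 5.5))

#' Default configuration of the synthetic-cohort generator
#'
#' Defaults reproduce the study conditions the analysis assumes: cohort of
#' 85 individuals across three breeding areas and two main deployment years
#' (plus a small 2012 contingent), winter centroid near (4.5 N, 12.3 E),
#' carry-over slopes 0.41 (arrival on departure), 1.0 (winter departure on
#' arrival) and 5.12 km/day per day (spring speed on winter-departure
#' residual), about 8/85 itinerant individuals and 4/85 southern-Africa
#' outliers (males only), and post-breeding routes less laterally variable
#' than pre-breeding ones.
#'
#' @param n_individuals cohort size (default 85)
#' @param seed root seed for all randomness
#' @param ... overrides for any other config entry
#' @return a `generator_config` list
#' @export
generator_config <- function(n_individuals = 85, seed = 1L, ...) {
  cfg <- list(
    n_individuals = n_individuals,
    seed = seed,
    sex_ratio = 0.5,                       # P(male)
    year_probs = c("2010" = 58, "2011" = 23, "2012" = 2) / 83,
    area_probs = c(N = 38, SW = 30, SE = 15) / 83,
    # season availability: both routes, post only, pre only, neither
    avail_probs = c(both = 58, post = 15, pre = 2, none = 10) / 85,
    # winter quarters
    sp_lat_mean = 4.5, sp_lat_sd = 3.6,
    sp_lon_mean = 12.3, sp_lon_sd = 5.1,
    southern_frac = 4 / 85,                # males only, main SP lat < -10
    southern_lat_mean = -24, southern_lat_sd = 3,
    southern_lon_mean = 24, southern_lon_sd = 3,
    itinerant_frac = 8 / 85,
    itinerant_shift_km = c(300, 900),      # centre displacement range
    itinerant_gap_days = c(5, 15),
    # carry-over timing chain (means from the cohort the generator emulates)
    dd_c_mean = 250.8, dd_c_sd = 6.75,
    slope_ad_on_dd = 0.41, ad_sp_resid_sd = 5,
    ad_sp_mean = 280.1,
    slope_ddsp_on_adsp = 1.0, dd_sp_resid_sd = 9,
    dd_sp_mean = 80.1 + 365,               # continuous day offset
    ms_prb_mean = 296, slope_ms_on_rdd = 5.12, ms_prb_resid_sd = 40,
    # route geometry
    lateral_offset_sd_post = 2.0,          # degrees, per individual-season
    lateral_offset_sd_pre = 3.0,
    offset_correlation = 0,                # post/pre corridor correlation
    route_jitter_sd = 0.15,                # per-fix route wobble, degrees
    residency_scatter_sd = 0.35,           # daily SP scatter, degrees
    obs_sd_lat = 0.3, obs_sd_lon = 0.15,   # GLS-like position noise
    split_sp_frac = 0.3,                   # emit some SPs as two candidates
    stopover_frac = 0.25,                  # emit a short (<14 d) candidate
    fixes_per_day = 2)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$n_individuals >= 1,
            all(unlist(cfg[c("sp_lat_sd", "sp_lon_sd", "route_jitter_sd",
                             "residency_scatter_sd", "obs_sd_lat",
                             "obs_sd_lon")]) >= 0))
  structure(cfg, class = "generator_config")
}

#' Simulate the carry-over timing chain
#'
#' Draws, per individual, colony departure (DD_c), arrival to the first
#' winter stationary period (AD_sp), departure from the last one (DD_sp, as
#' a continuous day offset past 365) and pre-breeding migration speed
#' (MS_prb), following the linear-Gaussian chain with the configured
#' slopes. Returned residuals (`e_ad`, `e_dd`) are the latent draws that
#' the residualization workflow is meant to recover.
#'
#' @param n number of individuals
#' @param cfg a [generator_config()]
#' @return data frame with one row per individual
#' @export
simulate_carryover <- function(n, cfg = generator_config()) {
  dd_c <- stats::rnorm(n, cfg$dd_c_mean, cfg$dd_c_sd)
  e_ad <- stats::rnorm(n, 0, cfg$ad_sp_resid_sd)
  ad_sp <- cfg$ad_sp_mean + cfg$slope_ad_on_dd * (dd_c - cfg$dd_c_mean) + e_ad
  e_dd <- stats::rnorm(n, 0, cfg$dd_sp_resid_sd)
  dd_sp <- cfg$dd_sp_mean +
    cfg$slope_ddsp_on_adsp * (ad_sp - cfg$ad_sp_mean) + e_dd
  ms_prb <- pmax(100, cfg$ms_prb_mean + cfg$slope_ms_on_rdd * e_dd +
                   stats::rnorm(n, 0, cfg$ms_prb_resid_sd))
  data.frame(dd_c = dd_c, ad_sp = ad_sp, dd_sp = dd_sp, ms_prb = ms_prb,
             e_ad = e_ad, e_dd = e_dd)
}

#' Generate one migration route as a track
#'
#' Builds the polyline origin - template waypoints - terminus, displaces it
#' perpendicular to the local route direction by `lateral_offset` degrees
#' (tapered to zero at the endpoints so origin and terminus are fixed),
#' discretizes it into `n_fixes` positions equally spaced in arc length
#' (constant travel speed), and adds independent per-fix jitter.
#'
#' @param origin,terminus [geo_point()]s or `c(lat, lon)` vectors
#' @param template waypoint matrix with columns `lat`, `lon`
#' @param lateral_offset signed offset in degrees
#' @param jitter_sd per-fix Gaussian jitter sd in degrees
#' @param n_fixes number of fixes (>= 2)
#' @param start_day,end_day day offsets of the first and last fix
#' @return a [poly_track()]
#' @export
generate_route <- function(origin, terminus, template, lateral_offset = 0,
                           jitter_sd = 0, n_fixes = 40,
                           start_day = 0, end_day = 1) {
  stopifnot(nrow(template) >= 2, n_fixes >= 2, end_day > start_day)
  lat <- c(origin[["lat"]], template[, "lat"], terminus[["lat"]])
  lon <- c(origin[["lon"]], template[, "lon"], terminus[["lon"]])
  base <- poly_track(lat, lon, seq_along(lat))
  dense <- resample_equal_arc(base, 200)
  if (lateral_offset != 0) {
    m <- nrow(dense)
    dlat <- c(dense[2, 1] - dense[1, 1], dense[-1, 1] - dense[-m, 1])
    dlon <- c(dense[2, 2] - dense[1, 2], dense[-1, 2] - dense[-m, 2])
    nrm <- sqrt(dlat^2 + dlon^2)
    nrm[nrm == 0] <- 1
    taper <- sin(pi * (seq_len(m) - 1) / (m - 1))
    dense[, 1] <- dense[, 1] + lateral_offset * taper * (-dlon / nrm)
    dense[, 2] <- dense[, 2] + lateral_offset * taper * (dlat / nrm)
  }
  shaped <- poly_track(dense[, 1], dense[, 2], seq_len(nrow(dense)))
  pts <- resample_equal_arc(shaped, n_fixes)
  la <- pts[, "lat"]; lo <- pts[, "lon"]
  if (jitter_sd > 0) {
    la <- la + stats::rnorm(n_fixes, 0, jitter_sd)
    lo <- lo + stats::rnorm(n_fixes, 0, jitter_sd)
  }
  poly_track(pmin(90, pmax(-90, la)), lo,
             seq(start_day, end_day, length.out = n_fixes))
}

#' Add GLS-like observation noise to a track
#'
#' Independent Gaussian perturbation per fix; latitudinal error exceeds
#' longitudinal error, as typical for light-level geolocation. A zero sd is
#' the identity.
#'
#' @param track a [poly_track()]
#' @param sd_lat,sd_lon noise sd in degrees (defaults 1.5 and 0.7)
#' @param seed optional seed; when `NULL` the current RNG state is used
#' @return a perturbed [poly_track()]
#' @export
add_observation_noise <- function(track, sd_lat = 1.5, sd_lon = 0.7,
                                  seed = NULL) {
  stopifnot(sd_lat >= 0, sd_lon >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(track)
  lat <- track$lat + if (sd_lat > 0) stats::rnorm(n, 0, sd_lat) else 0
  lon <- track$lon + if (sd_lon > 0) stats::rnorm(n, 0, sd_lon) else 0
  poly_track(pmin(90, pmax(-90, lat)), lon, track$day)
}

#' Generate a synthetic loop-migration cohort
#'
#' Draws a cohort under the configured study conditions and returns fix-level
#' tracks, candidate stationary-period intervals (as an upstream
#' twilight-trend detector would supply them, including split and short
#' stopover candidates that exercise the merge and duration filters),
#' colony departure/arrival events, and the truth table. Deterministic
#' given `(cfg, cfg$seed)`.
#'
#' @param cfg a [generator_config()]
#' @return a `track_cohort` list: `tracks`, `sp_candidates`, `colony_events`,
#'   `truth`, `config`
#' @export
generate_cohort <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  n <- cfg$n_individuals
  ids <- sprintf("BS%03d", seq_len(n))
  sex <- ifelse(stats::runif(n) < cfg$sex_ratio, "M", "F")
  year <- as.integer(sample(names(cfg$year_probs), n, TRUE, cfg$year_probs))
  area <- sample(names(cfg$area_probs), n, TRUE, cfg$area_probs)
  avail <- sample(names(cfg$avail_probs), n, TRUE, cfg$avail_probs)
  southern <- sex == "M" & stats::runif(n) < cfg$southern_frac / cfg$sex_ratio
  itin <- stats::runif(n) < ifelse(southern, 0.75, cfg$itinerant_frac)

  timing <- simulate_carryover(n, cfg)
  sp_lat <- ifelse(southern,
                   stats::rnorm(n, cfg$southern_lat_mean, cfg$southern_lat_sd),
                   stats::rnorm(n, cfg$sp_lat_mean, cfg$sp_lat_sd))
  sp_lat <- pmin(sp_lat, 15)  # all winter SPs lie south of the Sahara margin
  sp_lon <- ifelse(southern,
                   stats::rnorm(n, cfg$southern_lon_mean, cfg$southern_lon_sd),
                   stats::rnorm(n, cfg$sp_lon_mean, cfg$sp_lon_sd))
  off_post <- stats::rnorm(n, 0, cfg$lateral_offset_sd_post)
  rho <- cfg$offset_correlation
  z_post <- if (cfg$lateral_offset_sd_post > 0)
    off_post / cfg$lateral_offset_sd_post else numeric(n)
  off_pre <- cfg$lateral_offset_sd_pre *
    (rho * z_post + sqrt(1 - rho^2) * stats::rnorm(n))

  tracks <- list(); cands <- list(); truth_rows <- list()
  for (i in seq_len(n)) {
    colony <- STUDY_COLONIES[[area[i]]]
    sp1 <- c(lat = sp_lat[i], lon = sp_lon[i])
    ad_sp <- timing$ad_sp[i]; dd_sp <- timing$dd_sp[i]

    # winter stationary structure; itinerancy needs room for two >= 14-day
    # periods plus the travel gap, otherwise the bird stays stationary
    stay <- dd_sp - ad_sp
    gap <- stats::runif(1, cfg$itinerant_gap_days[1], cfg$itinerant_gap_days[2])
    if (itin[i] && stay - gap < 32) itin[i] <- FALSE
    if (itin[i]) {
      shift_km <- stats::runif(1, cfg$itinerant_shift_km[1],
                               cfg$itinerant_shift_km[2])
      ang <- stats::runif(1, 0, 2 * pi)
      sp2 <- c(lat = sp1[["lat"]] + shift_km / 111.195 * cos(ang),
               lon = sp1[["lon"]] + shift_km / 111.195 * sin(ang) /
                 cos(sp1[["lat"]] * pi / 180))
      t1 <- ad_sp + stats::runif(1, 15, stay - gap - 15)
      sp_int <- rbind(c(ad_sp, t1), c(t1 + gap, dd_sp))
      sp_cen <- rbind(sp1, sp2)
    } else {
      sp_int <- rbind(c(ad_sp, dd_sp))
      sp_cen <- rbind(sp1)
    }
    first_sp <- sp_cen[1, ]; last_sp <- sp_cen[nrow(sp_cen), ]

    fix_rows <- list(); cand_rows <- list()
    add_fixes <- function(tr) fix_rows[[length(fix_rows) + 1L]] <<- tr

    has_post <- avail[i] %in% c("both", "post")
    has_pre <- avail[i] %in% c("both", "pre")

    # post-breeding migration: colony -> first SP
    dd_c <- timing$dd_c[i]; ad_c <- NA_real_; lmp_post <- NA_real_
    if (has_post) {
      dm <- ad_sp - dd_c
      route <- generate_route(colony, first_sp, ROUTE_TEMPLATE_POST,
                              off_post[i], cfg$route_jitter_sd,
                              n_fixes = max(2, round(dm * cfg$fixes_per_day)),
                              start_day = dd_c, end_day = ad_sp - 1e-3)
      lmp_post <- path_length_km(route)
      add_fixes(route)
    }
    # winter residency fixes (daily scatter around the SP centre)
    for (s in seq_len(nrow(sp_int))) {
      days <- seq(sp_int[s, 1], sp_int[s, 2], by = 1 / cfg$fixes_per_day)
      m <- length(days)
      add_fixes(poly_track(
        pmin(90, pmax(-90, sp_cen[s, "lat"] +
                        stats::rnorm(m, 0, cfg$residency_scatter_sd))),
        sp_cen[s, "lon"] + stats::rnorm(m, 0, cfg$residency_scatter_sd),
        days))
      # candidate intervals as upstream detection would emit them
      if (nrow(sp_int) == 1L && stats::runif(1) < cfg$split_sp_frac &&
          sp_int[s, 2] - sp_int[s, 1] > 40) {
        mid <- (sp_int[s, 1] + sp_int[s, 2]) / 2
        cand_rows[[length(cand_rows) + 1L]] <-
          rbind(c(sp_int[s, 1], mid), c(mid + 0.5, sp_int[s, 2]))
      } else {
        cand_rows[[length(cand_rows) + 1L]] <- sp_int[s, , drop = FALSE]
      }
    }
    # a short (< 14 d) Sahel stopover candidate late in the post-breeding
    # migration, dropped by the duration filter downstream
    if (has_post && stats::runif(1) < cfg$stopover_frac && ad_sp - dd_c > 16) {
      en <- ad_sp - stats::runif(1, 0.5, 2)
      st <- en - stats::runif(1, 3, 10)
      cand_rows[[length(cand_rows) + 1L]] <- matrix(c(st, en), 1)
    }

    # pre-breeding migration: last SP -> colony
    ms_prb <- timing$ms_prb[i]; lmp_pre <- NA_real_
    if (has_pre) {
      pre_base <- poly_track(
        c(last_sp[["lat"]], ROUTE_TEMPLATE_PRE[, "lat"], colony[["lat"]]),
        c(last_sp[["lon"]], ROUTE_TEMPLATE_PRE[, "lon"], colony[["lon"]]),
        seq_len(nrow(ROUTE_TEMPLATE_PRE) + 2))
      dm_pre <- path_length_km(pre_base) / ms_prb
      ad_c <- dd_sp + dm_pre
      route <- generate_route(last_sp, colony, ROUTE_TEMPLATE_PRE,
                              off_pre[i], cfg$route_jitter_sd,
                              n_fixes = max(2, round(dm_pre * cfg$fixes_per_day)),
                              start_day = dd_sp + 1e-3, end_day = ad_c)
      lmp_pre <- path_length_km(route)
      add_fixes(route)
    }

    tr <- do.call(rbind, lapply(fix_rows, as.data.frame))
    tr <- tr[order(tr$day), , drop = FALSE]
    noisy <- add_observation_noise(poly_track(tr$lat, tr$lon, tr$day),
                                   cfg$obs_sd_lat, cfg$obs_sd_lon)
    tracks[[i]] <- data.frame(
      individual_id = ids[i], sex = sex[i], year = year[i],
      study_area = area[i],
      time = day_to_iso(noisy$day, year[i]),
      twilight = ifelse(noisy$day %% 1 < 0.5, "rise", "set"),
      lat = noisy$lat, lon = noisy$lon, day = noisy$day)

    cand <- do.call(rbind, cand_rows)
    cands[[i]] <- data.frame(individual_id = ids[i],
                             start_day = cand[, 1], end_day = cand[, 2])
    truth_rows[[i]] <- data.frame(
      individual_id = ids[i], sex = sex[i], year = year[i],
      study_area = area[i], availability = avail[i],
      itinerant = itin[i], southern = southern[i],
      dd_c = if (has_post) dd_c else NA_real_,
      ad_sp = ad_sp, dd_sp = dd_sp,
      ad_c = if (has_pre) ad_c else NA_real_,
      ms_prb = ms_prb, e_ad = timing$e_ad[i], e_dd = timing$e_dd[i],
      sp1_lat = sp_cen[1, "lat"], sp1_lon = sp_cen[1, "lon"],
      sp2_lat = if (itin[i]) sp_cen[2, "lat"] else NA_real_,
      sp2_lon = if (itin[i]) sp_cen[2, "lon"] else NA_real_,
      main_sp = if (itin[i]) which.max(sp_int[, 2] - sp_int[, 1]) else 1L,
      lmp_post = lmp_post, lmp_pre = lmp_pre,
      offset_post = off_post[i], offset_pre = off_pre[i])
  }
  structure(list(tracks = do.call(rbind, tracks),
                 sp_candidates = do.call(rbind, cands),
                 colony_events = data.frame(
                   individual_id = ids,
                   dd_c = ifelse(avail %in% c("both", "post"),
                                 timing$dd_c, NA_real_),
                   ad_c = vapply(truth_rows, function(r) r$ad_c, numeric(1))),
                 truth = do.call(rbind, truth_rows),
                 config = cfg),
            class = "track_cohort")
}

#' @export
print.track_cohort <- function(x, ...) {
  cat(sprintf("<track_cohort: %d individuals, %d fixes, seed %d>\n",
              nrow(x$truth), nrow(x$tracks), x$config$seed))
  invisible(x)
}

# continuous day offset -> ISO 8601 UTC timestamp (day 1 = Jan 1)
day_to_iso <- function(day, year) {
  origin <- as.POSIXct(paste0(year, "-01-01 00:00:00"), tz = "UTC")
  format(origin + (day - 1) * 86400, "%Y-%m-%dT%H:%M:%SZ")
}
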