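# Stationary-period processing: density-mode centres, merging of nearby
# periods, duration filtering, and itinerancy classification.
#
# A stationary period (SP) is a residency interval during the non-breeding
# season. Candidate intervals come from upstream twilight-trend detection
# (outside this package's scope); here they are located, merged when their
# density-mode centres fall within a threshold distance, filtered by a
# minimum duration, and classified.

#' Density mode and 90% quantile interval of daily position estimates
#'
#' The centre of an SP is the per-axis mode of a Gaussian kernel density
#' (Silverman's rule-of-thumb bandwidth) of the daily latitude and longitude
#' estimates, evaluated on a 0.05-degree grid; the spread is the 5th-95th
#' percentile interval per axis. With fewer than two distinct values the
#' mode is the (single) value itself.
#'
#' @param daily_lats,daily_lons numeric vectors of daily position estimates
#' @param grid_step mode-search grid resolution in degrees (default 0.05)
#' @return list with `centre` (a [geo_point()]), `lat_q` and `lon_q`
#'   (each `c(q05, q95)`)
#' @export
sp_centre <- function(daily_lats, daily_lons, grid_step = 0.05) {
  stopifnot(length(daily_lats) >= 1, length(daily_lons) >= 1)
  list(centre = geo_point(axis_mode(daily_lats, grid_step),
                          axis_mode(daily_lons, grid_step)),
       lat_q = unname(stats::quantile(daily_lats, c(0.05, 0.95))),
       lon_q = unname(stats::quantile(daily_lons, c(0.05, 0.95))))
}

axis_mode <- function(x, grid_step = 0.05) {
  ux <- unique(x)
  if (length(ux) == 1L) return(ux)
  bw <- stats::bw.nrd0(x)
  if (!is.finite(bw) || bw <= 0) return(stats::median(x))
  lo <- min(x); hi <- max(x)
  grid <- seq(lo, hi, by = grid_step)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  d <- stats::density(x, bw = bw, from = lo, to = hi, n = 2048)
  dens <- stats::approx(d$x, d$y, xout = grid)$y
  grid[which.max(dens)]
}

#' Construct a stationary period from daily position estimates
#'
#' @param start,end day offsets (start <= end); duration is `end - start + 1`
#' @param daily_lats,daily_lons daily position estimates within the interval
#' @return a `stationary_period` list
#' @export
stationary_period <- function(start, end, daily_lats, daily_lons) {
  stopifnot(start <= end, length(daily_lats) == length(daily_lons),
            length(daily_lats) >= 1)
  cen <- sp_centre(daily_lats, daily_lons)
  structure(list(start = start, end = end,
                 duration = end - start + 1,
                 centre = cen$centre, lat_q = cen$lat_q, lon_q = cen$lon_q,
                 daily_lats = daily_lats, daily_lons = daily_lons),
            class = "stationary_period")
}

#' @export
print.stationary_period <- function(x, ...) {
  cat(sprintf("<SP days %.1f-%.1f (%.0f d), centre %.2fN %.2fE>\n",
              x$start, x$end, x$duration, x$centre[["lat"]], x$centre[["lon"]]))
  invisible(x)
}

#' Merge consecutive stationary periods with nearby centres
#'
#' Consecutive periods whose density-mode centres lie closer than
#' `threshold_km` are merged: the merged period spans both intervals, pools
#' the daily positions of both, and its centre and quantiles are
#' recalculated on the merged data. Merging proceeds left-to-right in time
#' and repeats until no two consecutive centres are closer than the
#' threshold.
#'
#' @param sps list of [stationary_period()]s, time-ordered, non-overlapping
#' @param threshold_km merge threshold in km (default 200)
#' @return list of merged `stationary_period`s
#' @export
merge_stationary_periods <- function(sps, threshold_km = 200) {
  if (length(sps) <= 1L) return(sps)
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < length(sps)) {
      d <- great_circle_km(sps[[i]]$centre, sps[[i + 1]]$centre)
      if (d < threshold_km) {
        sps[[i]] <- stationary_period(
          sps[[i]]$start, sps[[i + 1]]$end,
          c(sps[[i]]$daily_lats, sps[[i + 1]]$daily_lats),
          c(sps[[i]]$daily_lons, sps[[i + 1]]$daily_lons))
        sps[[i + 1]] <- NULL
        merged <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!merged) break
  }
  sps
}

#' Drop stationary periods shorter than a minimum duration
#'
#' Periods shorter than `min_days` are treated as migration stopovers and
#' removed; the comparison is strict (a 14-day period is retained under the
#' default).
#'
#' @param sps list of [stationary_period()]s
#' @param min_days minimum duration in days (default 14)
#' @return filtered list
#' @export
filter_short_sps <- function(sps, min_days = 14) {
  Filter(function(sp) sp$duration >= min_days, sps)
}

#' Classify itinerancy and identify the main/first/last stationary periods
#'
#' An individual with two or more retained stationary periods is classified
#' as itinerant; the longest period is the main one (ties broken in favour
#' of the earlier period), and the temporally first and last periods are
#' recorded.
#'
#' @param sps list of merged, filtered [stationary_period()]s (time-ordered)
#' @return list with `itinerant` (logical), `main`, `first`, `last` (indices
#'   into `sps`) and `sps` itself
#' @export
classify_itinerancy <- function(sps) {
  if (length(sps) == 0L)
    stop("no stationary periods remain; record invalid for feature extraction")
  durs <- vapply(sps, function(sp) sp$duration, numeric(1))
  list(itinerant = length(sps) >= 2L,
       main = which.max(durs),   # which.max takes the earliest on ties
       first = 1L,
       last = length(sps),
       sps = sps)
}
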