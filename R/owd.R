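# One-Way-Distance (OWD) route similarity.
#
# Two tracks are compared only over their sections between two latitudes
# (default 17 N - 45 N) so that differing overall route lengths do not
# drive the metric. Each clipped track is reduced to k = 20 points equally
# spaced in arc length. The directed distance d_AB is the sum, over the 20
# points of A, of the great-circle distance to the nearest of B's 20
# points, divided by the total length of A's clipped resampled polyline;
# OWD is the mean of d_AB and d_BA (dimensionless).

#' Directed One-Way-Distance between two resampled point sequences
#'
#' For each point of `a_pts`, the corresponding position on the other track
#' is the point of `b_pts` at minimum great-circle distance (ties broken by
#' lowest index); the directed distance is the sum of these minima divided
#' by `len_a`.
#'
#' @param a_pts,b_pts k x 2 matrices with columns `lat`, `lon`
#'   (from [resample_equal_arc()])
#' @param len_a total length (km) of the polyline through `a_pts`; must be
#'   positive
#' @return dimensionless directed distance
#' @export
directed_owd <- function(a_pts, b_pts, len_a) {
  if (len_a <= 0) stop("len_a must be positive")
  dm <- great_circle_matrix_km(a_pts, b_pts)
  sum(row_mins(dm)) / len_a
}

# minimum of each row; ties resolved to the lowest column index by max.col
row_mins <- function(m) {
  m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
}

polyline_length_km <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(0)
  sum(haversine_km(pts[-n, "lat"], pts[-n, "lon"],
                   pts[-1, "lat"], pts[-1, "lon"]))
}

#' Prepare a track for OWD comparison: clip to band and resample
#'
#' @param track a [poly_track()]
#' @param k number of resampled points (default 20)
#' @param lat_min,lat_max comparison band (default 17-45 N)
#' @return list with `pts` (k x 2 matrix) and `len` (polyline length, km)
#' @export
owd_prepare <- function(track, k = 20, lat_min = 17, lat_max = 45) {
  clipped <- clip_to_lat_band(track, lat_min, lat_max)
  pts <- resample_equal_arc(clipped, k)
  list(pts = pts, len = polyline_length_km(pts))
}

#' One-Way-Distance between two tracks
#'
#' Clips both tracks to the latitude band, resamples each to `k` equal-arc
#' points, computes the two directed distances (each normalized by its own
#' source polyline's length) and returns their mean. Deterministic.
#'
#' @param track_a,track_b [poly_track()]s intersecting the band
#' @param k number of resampled points per track (default 20)
#' @param lat_min,lat_max comparison band (default 17-45 N)
#' @return an `owd_result` list: `d_ab`, `d_ba`, `owd`, `k`, `band`
#' @export
owd <- function(track_a, track_b, k = 20, lat_min = 17, lat_max = 45) {
  pa <- owd_prepare(track_a, k, lat_min, lat_max)
  pb <- owd_prepare(track_b, k, lat_min, lat_max)
  owd_from_prepared(pa, pb, k = k, band = c(lat_min, lat_max))
}

owd_from_prepared <- function(pa, pb, k = nrow(pa$pts), band = c(17, 45)) {
  dm <- great_circle_matrix_km(pa$pts, pb$pts)
  d_ab <- sum(row_mins(dm)) / pa$len
  d_ba <- sum(row_mins(t(dm))) / pb$len
  structure(list(d_ab = d_ab, d_ba = d_ba, owd = (d_ab + d_ba) / 2,
                 k = k, band = band),
            class = "owd_result")
}

#' @export
print.owd_result <- function(x, ...) {
  cat(sprintf("<OWD %.4f (d_ab %.4f, d_ba %.4f), k = %d, band %g-%g>\n",
              x$owd, x$d_ab, x$d_ba, x$k, x$band[1], x$band[2]))
  invisible(x)
}

#' Pairwise OWD matrices for a cohort of routes
#'
#' `routes` is a named list of [poly_track()]s per individual, with elements
#' `post` and/or `pre`. Individuals missing a required season are reported
#' and skipped.
#'
#' In `within_season` mode the result holds the OWD for every ordered pair
#' `(i, j)`, `i != j`, of the requested season's routes (`n * (n - 1)`
#' comparisons; the OWD itself is symmetric). In `cross_season` mode it
#' holds, for each individual, the within-individual post-vs-pre OWD and,
#' across individuals, every ordered pair of post-of-i vs pre-of-j.
#'
#' @param routes named list: `routes[[id]]$post`, `routes[[id]]$pre`
#' @param mode `"within_post"`, `"within_pre"` or `"cross_season"`
#' @param k,lat_min,lat_max OWD parameters (see [owd()])
#' @return an `owd_matrix` list with `ids`, `skipped`, and a data frame
#'   `pairs` (`id_a`, `season_a`, `id_b`, `season_b`, `d_ab`, `d_ba`, `owd`,
#'   `within_individual`)
#' @export
owd_matrix <- function(routes, mode = c("within_post", "within_pre",
                                        "cross_season"),
                       k = 20, lat_min = 17, lat_max = 45) {
  mode <- match.arg(mode)
  need <- switch(mode, within_post = "post", within_pre = "pre",
                 cross_season = c("post", "pre"))
  ids <- names(routes)
  has <- vapply(ids, function(id) all(need %in% names(routes[[id]])) &&
                  !any(vapply(routes[[id]][need], is.null, logical(1))),
                logical(1))
  skipped <- ids[!has]
  ids <- ids[has]
  prep <- lapply(ids, function(id)
    lapply(routes[[id]][need],
           function(tr) owd_prepare(tr, k, lat_min, lat_max)))
  names(prep) <- ids
  n <- length(ids)

  rows <- list()
  add <- function(ia, sa, ib, sb, res, within) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id_a = ia, season_a = sa, id_b = ib, season_b = sb,
      d_ab = res$d_ab, d_ba = res$d_ba, owd = res$owd,
      within_individual = within)
  }
  if (mode %in% c("within_post", "within_pre")) {
    season <- need
    for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
      add(ids[i], season, ids[j], season,
          owd_from_prepared(prep[[i]][[season]], prep[[j]][[season]],
                            k, c(lat_min, lat_max)), FALSE)
  } else {
    for (i in seq_len(n)) for (j in seq_len(n))
      add(ids[i], "post", ids[j], "pre",
          owd_from_prepared(prep[[i]]$post, prep[[j]]$pre,
                            k, c(lat_min, lat_max)), i == j)
  }
  pairs <- do.call(rbind, rows)
  structure(list(ids = ids, skipped = skipped, mode = mode, k = k,
                 band = c(lat_min, lat_max), pairs = pairs),
            class = "owd_matrix")
}

#' @export
print.owd_matrix <- function(x, ...) {
  cat(sprintf("<owd_matrix [%s]: %d individuals, %d comparisons%s>\n",
              x$mode, length(x$ids), nrow(x$pairs),
              if (length(x$skipped)) paste0(", ", length(x$skipped), " skipped")
              else ""))
  invisible(x)
}
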