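# End-to-end orchestration: tracks + candidate stationary periods +
# colony events -> per-individual features -> OWD matrices -> permutation
# tests -> cohort report.

#' Default pipeline configuration
#'
#' All thresholds of the analysis in one place; every value is serialized
#' with the run outputs.
#'
#' @param seed root seed for permutation tests
#' @param ... overrides (see defaults in the function body)
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(seed = seed,
              lat_min = 17, lat_max = 45,      # OWD comparison band
              merge_km = 200,                  # SP merge threshold
              min_sp_days = 14,                # SP duration filter
              sahara_lat = 17,                 # winter SPs lie south of this
              k = 20,                          # OWD resampling count
              n_perm = 10000,
              exclude_years = 2012,
              southern_lat = -10,
              mode_grid_deg = 0.05)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Build per-individual records from tracks, SP candidates and colony events
#'
#' For each individual: daily position estimates inside each candidate
#' interval are located ([sp_centre()]), candidates north of the Sahara
#' margin are dropped, nearby periods merged ([merge_stationary_periods()]),
#' short ones filtered ([filter_short_sps()]), and itinerancy classified.
#' Episode features are computed for each available season, with the colony
#' and the terminal SP centre as path endpoints.
#'
#' @param tracks fix-level data frame (`individual_id`, `sex`, `year`,
#'   `study_area`, `lat`, `lon`, `day`)
#' @param sp_candidates data frame `individual_id`, `start_day`, `end_day`
#' @param colony_events data frame `individual_id`, `dd_c`, `ad_c` (NA for
#'   missing seasons)
#' @param cfg a [pipeline_config()]
#' @return list with `features` (one row per individual), `sps` (one row per
#'   retained SP), `routes` (per-individual list of post/pre episode
#'   [poly_track()]s), `dropped` (ids with no retained SP)
#' @export
build_individual_records <- function(tracks, sp_candidates, colony_events,
                                     cfg = pipeline_config()) {
  ids <- unique(tracks$individual_id)
  feat_rows <- list(); sp_rows <- list(); routes <- list(); dropped <- character(0)
  for (id in ids) {
    tr <- tracks[tracks$individual_id == id, , drop = FALSE]
    tr <- tr[order(tr$day), , drop = FALSE]
    meta <- tr[1, c("sex", "year", "study_area")]
    colony <- STUDY_COLONIES[[meta$study_area]]
    ev <- colony_events[colony_events$individual_id == id, , drop = FALSE]
    dd_c <- if (nrow(ev)) ev$dd_c[1] else NA_real_
    ad_c <- if (nrow(ev)) ev$ad_c[1] else NA_real_

    cand <- sp_candidates[sp_candidates$individual_id == id, , drop = FALSE]
    cand <- cand[order(cand$start_day), , drop = FALSE]
    sps <- list()
    for (r in seq_len(nrow(cand))) {
      sel <- tr$day >= cand$start_day[r] & tr$day <= cand$end_day[r]
      if (!any(sel)) next
      sp <- stationary_period(cand$start_day[r], cand$end_day[r],
                              tr$lat[sel], tr$lon[sel])
      if (sp$centre[["lat"]] < cfg$sahara_lat) sps[[length(sps) + 1L]] <- sp
    }
    sps <- merge_stationary_periods(sps, cfg$merge_km)
    sps <- filter_short_sps(sps, cfg$min_sp_days)
    if (length(sps) == 0L) { dropped <- c(dropped, id); next }
    cls <- classify_itinerancy(sps)
    sp_f <- sps[[cls$first]]; sp_l <- sps[[cls$last]]; sp_m <- sps[[cls$main]]
    ad_sp <- sp_f$start; dd_sp <- sp_l$end

    for (s in seq_along(sps))
      sp_rows[[length(sp_rows) + 1L]] <- data.frame(
        individual_id = id, sp_index = s,
        start_day = sps[[s]]$start, end_day = sps[[s]]$end,
        duration = sps[[s]]$duration,
        lat_mode = sps[[s]]$centre[["lat"]], lon_mode = sps[[s]]$centre[["lon"]],
        lat_q05 = sps[[s]]$lat_q[1], lat_q95 = sps[[s]]$lat_q[2],
        lon_q05 = sps[[s]]$lon_q[1], lon_q95 = sps[[s]]$lon_q[2])

    post <- pre <- NULL
    routes[[id]] <- list()
    if (!is.na(dd_c)) {
      sel <- tr$day >= dd_c & tr$day < ad_sp
      if (sum(sel) >= 2) {
        ep_tr <- append_endpoints(poly_track(tr$lat[sel], tr$lon[sel],
                                             tr$day[sel]),
                                  geo_point(colony[["lat"]], colony[["lon"]]),
                                  sp_f$centre)
        post <- compute_episode_features(
          ep_tr, geo_point(colony[["lat"]], colony[["lon"]]), sp_f$centre,
          dd_c, ad_sp, "post")
        routes[[id]]$post <- ep_tr
      }
    }
    if (!is.na(ad_c)) {
      sel <- tr$day > dd_sp & tr$day <= ad_c
      if (sum(sel) >= 2) {
        ep_tr <- append_endpoints(poly_track(tr$lat[sel], tr$lon[sel],
                                             tr$day[sel]),
                                  sp_l$centre,
                                  geo_point(colony[["lat"]], colony[["lon"]]))
        pre <- compute_episode_features(
          ep_tr, geo_point(colony[["lat"]], colony[["lon"]]), sp_l$centre,
          dd_sp, ad_c, "pre")
        routes[[id]]$pre <- ep_tr
      }
    }
    itin_feats <- if (cls$itinerant)
      itinerancy_movement_features(cls) else NULL

    g <- function(x, f) if (is.null(x)) NA_real_ else x[[f]]
    feat_rows[[length(feat_rows) + 1L]] <- data.frame(
      individual_id = id, sex = meta$sex, year = meta$year,
      study_area = meta$study_area,
      n_sps = length(sps), itinerant = cls$itinerant,
      main_sp_lat = sp_m$centre[["lat"]], main_sp_lon = sp_m$centre[["lon"]],
      first_sp_lat = sp_f$centre[["lat"]], first_sp_lon = sp_f$centre[["lon"]],
      last_sp_lat = sp_l$centre[["lat"]], last_sp_lon = sp_l$centre[["lon"]],
      dd_c = dd_c, ad_sp = ad_sp, dd_sp = dd_sp, ad_c = ad_c,
      stay_days = dd_sp - ad_sp,
      lmp_post = g(post, "LMP"), ps_post = g(post, "PS"),
      dm_post = g(post, "DM"), ms_post = g(post, "MS"),
      lmp_pre = g(pre, "LMP"), ps_pre = g(pre, "PS"),
      dm_pre = g(pre, "DM"), ms_pre = g(pre, "MS"),
      itin_path_km = g(itin_feats, "path_km"),
      itin_speed = g(itin_feats, "speed_km_day"),
      itin_straightness = g(itin_feats, "straightness_pct"))
  }
  list(features = do.call(rbind, feat_rows),
       sps = do.call(rbind, sp_rows),
       routes = routes, dropped = dropped)
}

#' Grouped summary of cohort migration features
#'
#' Mean and standard error (sd / sqrt(n)) of the timing, route and movement
#' features, in separate blocks for the analysis set and for the
#' descriptive-only groups (excluded year; southern winter areas). SE is
#' blank for single-individual groups.
#'
#' @param features feature table from [build_individual_records()]
#' @param cfg a [pipeline_config()]
#' @return data frame: `group`, `variable`, `mean`, `se`, `n`
#' @export
summarize_cohort <- function(features, cfg = pipeline_config()) {
  ex <- apply_exclusions(features, cfg$exclude_years, cfg$southern_lat)
  vars <- c("dd_c", "lmp_post", "ps_post", "ms_post", "dm_post",
            "first_sp_lat", "first_sp_lon", "ad_sp",
            "main_sp_lat", "main_sp_lon", "stay_days",
            "itin_path_km", "itin_speed", "itin_straightness",
            "last_sp_lat", "last_sp_lon", "dd_sp",
            "lmp_pre", "ps_pre", "ms_pre", "dm_pre", "ad_c")
  blk <- function(df, label) {
    if (nrow(df) == 0) return(NULL)
    do.call(rbind, lapply(vars, function(v) {
      x <- df[[v]][!is.na(df[[v]])]
      n <- length(x)
      if (n == 0) return(NULL)
      data.frame(group = label, variable = v, mean = mean(x),
                 se = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_, n = n)
    }))
  }
  rbind(blk(ex$analysis, "analysis"),
        blk(ex$excluded_southern, "southern"),
        blk(ex$excluded_year, "excluded_year"))
}

#' Run the full analysis pipeline on a cohort
#'
#' Features -> OWD matrices -> permutation tests -> report. When `out_dir`
#' is given, writes feature, SP, OWD and test CSVs, the report, and the
#' configuration (with seed) as YAML.
#'
#' @param cohort a `track_cohort` from [generate_cohort()], or a list with
#'   elements `tracks`, `sp_candidates`, `colony_events`
#' @param cfg a [pipeline_config()]
#' @param out_dir optional output directory
#' @return list with `records`, `exclusions`, `report`, `owd`
#'   (post/pre/cross matrices), `tests`
#' @export
run_pipeline <- function(cohort, cfg = pipeline_config(), out_dir = NULL) {
  rec <- build_individual_records(cohort$tracks, cohort$sp_candidates,
                                  cohort$colony_events, cfg)
  ex <- apply_exclusions(rec$features, cfg$exclude_years, cfg$southern_lat)
  ana <- ex$analysis
  report <- summarize_cohort(rec$features, cfg)

  # route-consistency comparisons use the individuals with both routes
  routes_ana <- rec$routes[ana$individual_id]
  complete <- vapply(routes_ana, function(r)
    all(c("post", "pre") %in% names(r)), logical(1))
  routes_ana <- routes_ana[complete]
  owd_post <- owd_matrix(routes_ana, "within_post",
                         cfg$k, cfg$lat_min, cfg$lat_max)
  owd_pre <- owd_matrix(routes_ana, "within_pre",
                        cfg$k, cfg$lat_min, cfg$lat_max)
  owd_cross <- owd_matrix(routes_ana, "cross_season",
                          cfg$k, cfg$lat_min, cfg$lat_max)

  tests <- list()
  # carry-over: arrival to the winter grounds vs colony departure
  d_post <- ana[!is.na(ana$dd_c) & !is.na(ana$ad_sp), , drop = FALSE]
  if (nrow(d_post) >= 12 && length(unique(d_post$year)) > 1) {
    d_post$c_dd <- group_centre(d_post$dd_c, d_post$year)
    tests$ad_sp <- permutation_lm(
      ad_sp ~ sex + year + study_area + c_dd, transform_factors(d_post),
      n_perm = cfg$n_perm, seed = cfg$seed)
    cf <- summary(tests$ad_sp$fit)$coefficients
    tests$ad_sp_slope_vs_one <- c(
      slope = cf["c_dd", 1], se = cf["c_dd", 2],
      unlist(slope_vs_one_test(cf["c_dd", 1], cf["c_dd", 2],
                               tests$ad_sp$fit$df.residual)))
  }
  # spring speed vs residual winter departure date
  d_pre <- ana[!is.na(ana$ms_pre) & !is.na(ana$dd_sp) & !is.na(ana$ad_sp), ,
               drop = FALSE]
  if (nrow(d_pre) >= 12 && length(unique(d_pre$year)) > 1) {
    d_pre$r_dd <- residualize(d_pre$dd_sp, data.frame(ad_sp = d_pre$ad_sp))
    tests$ms_pre <- permutation_lm(
      ms_pre ~ sex + year + study_area + r_dd, transform_factors(d_pre),
      n_perm = cfg$n_perm, seed = cfg$seed)
  }
  # paired post/pre comparisons
  paired <- ana[!is.na(ana$lmp_post) & !is.na(ana$lmp_pre), , drop = FALSE]
  if (nrow(paired) >= 10) {
    long <- to_paired_long(paired)
    for (v in c("lmp", "ps", "ms", "dm"))
      tests[[paste0("paired_", v)]] <- paired_two_step_perm(
        stats::as.formula(paste(v, "~ period + sex + year + study_area")),
        long, n_perm = cfg$n_perm, seed = cfg$seed)
  }
  if (length(owd_cross$ids) >= 3) {
    tests$owd_within_among <- owd_within_vs_among_test(
      owd_cross, n_perm = cfg$n_perm, seed = cfg$seed)
    tests$owd_season_spread <- owd_season_spread_test(
      owd_post, owd_pre, owd_cross, n_perm = cfg$n_perm, seed = cfg$seed)
  }

  out <- list(records = rec, exclusions = ex, report = report,
              owd = list(post = owd_post, pre = owd_pre, cross = owd_cross),
              tests = tests, config = cfg)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  invisible(out)
}

transform_factors <- function(df) {
  for (v in c("sex", "year", "study_area"))
    if (v %in% names(df)) df[[v]] <- factor(df[[v]])
  df
}

to_paired_long <- function(paired) {
  long <- do.call(rbind, lapply(c("post", "pre"), function(season) {
    data.frame(individual = paired$individual_id, period = season,
               sex = paired$sex, year = factor(paired$year),
               study_area = paired$study_area,
               lmp = paired[[paste0("lmp_", season)]],
               ps = paired[[paste0("ps_", season)]],
               ms = paired[[paste0("ms_", season)]],
               dm = paired[[paste0("dm_", season)]])
  }))
  long$period <- factor(long$period, levels = c("post", "pre"))
  long
}
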