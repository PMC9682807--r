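# File formats: fix-level track CSV, stationary-period and feature CSVs,
# OWD and test result CSVs, GeoJSON export, YAML configuration.

#' Write / read fix-level tracks
#'
#' One row per fix: `individual_id`, `sex`, `year`, `study_area`, `time`
#' (ISO 8601 UTC), `twilight` (`rise`/`set`), `lat`, `lon`. The continuous
#' `day` offset (day 1 = Jan 1 of the deployment year) is recomputed from
#' `time` on read.
#'
#' @param tracks fix-level data frame
#' @param path CSV path
#' @return `read_tracks_csv` returns the data frame with a `day` column
#' @export
write_tracks_csv <- function(tracks, path) {
  cols <- c("individual_id", "sex", "year", "study_area", "time", "twilight",
            "lat", "lon")
  utils::write.csv(tracks[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "sex", "year", "study_area", "time", "lat", "lon")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("track CSV missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$lat) | !is.finite(df$lon) |
                 df$lat < -90 | df$lat > 90)
  if (length(bad)) stop("invalid coordinates at rows: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  t <- as.POSIXct(df$time, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")
  origin <- as.POSIXct(paste0(df$year, "-01-01"), tz = "UTC")
  df$day <- as.numeric(difftime(t, origin, units = "days")) + 1
  df
}

#' Export individual-season routes as a GeoJSON FeatureCollection
#'
#' One LineString feature per individual and season, with `individual_id`
#' and `season` properties.
#'
#' @param routes per-individual route list (as in
#'   [build_individual_records()]'s `routes`)
#' @param path output path
#' @export
write_routes_geojson <- function(routes, path) {
  feats <- list()
  for (id in names(routes)) for (season in names(routes[[id]])) {
    tr <- routes[[id]][[season]]
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      properties = list(individual_id = id, season = season),
      geometry = list(type = "LineString",
                      coordinates = unname(
                        lapply(seq_len(nrow(tr)),
                               function(i) c(tr$lon[i], tr$lat[i])))))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write all pipeline artifacts to a directory
#'
#' Emits features.csv, stationary_periods.csv, owd_{post,pre,cross}.csv,
#' tests.csv, report.csv, report.md, routes.geojson and config.yaml (with
#' the seed and a config hash embedded). On failure, partial outputs are
#' removed.
#'
#' @param result value of [run_pipeline()]
#' @param out_dir output directory (created if needed)
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) { unlink(written); stop(e) }
  tryCatch({
    w <- function(df, name) {
      p <- file.path(out_dir, name)
      utils::write.csv(df, p, row.names = FALSE)
      written <<- c(written, p)
    }
    w(result$records$features, "features.csv")
    w(result$records$sps, "stationary_periods.csv")
    for (m in c("post", "pre", "cross"))
      w(result$owd[[m]]$pairs, paste0("owd_", m, ".csv"))
    w(tests_to_df(result$tests), "tests.csv")
    w(result$report, "report.csv")
    writeLines(report_markdown(result), file.path(out_dir, "report.md"))
    written <- c(written, file.path(out_dir, "report.md"))
    p <- file.path(out_dir, "routes.geojson")
    write_routes_geojson(result$records$routes, p)
    written <- c(written, p)
    cfg <- unclass(result$config)
    cfg$config_hash <- config_hash(cfg)
    yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  }, error = on_fail)
  invisible(out_dir)
}

config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(x) paste(x, collapse = ","),
                                character(1)),
             sep = "=", collapse = ";")
  # small rolling hash; enough to fingerprint a config in the outputs
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% 1e9
}

tests_to_df <- function(tests) {
  rows <- list()
  for (nm in names(tests)) {
    t <- tests[[nm]]
    if (inherits(t, "perm_lm")) {
      tab <- t$table
      rows[[nm]] <- data.frame(model = nm, term = tab$term,
                               statistic = "F", observed = tab$F,
                               p_perm = tab$p_perm,
                               n_perm = t$n_perm, seed = t$seed)
    } else if (inherits(t, "perm_paired")) {
      tab <- t$table
      rows[[nm]] <- data.frame(model = nm, term = tab$term,
                               statistic = "LRT", observed = tab$LRT,
                               p_perm = tab$p_perm,
                               n_perm = t$n_perm, seed = t$seed)
    } else if (inherits(t, "perm_test")) {
      rows[[nm]] <- data.frame(model = nm, term = t$statistic,
                               statistic = "mean difference",
                               observed = t$observed, p_perm = t$p,
                               n_perm = t$n_perm, seed = t$seed)
    } else if (is.numeric(t)) {
      rows[[nm]] <- data.frame(model = nm, term = names(t),
                               statistic = "value", observed = unname(t),
                               p_perm = NA_real_, n_perm = NA_integer_,
                               seed = NA_integer_)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

report_markdown <- function(result) {
  rep <- result$report
  ow <- result$owd
  lines <- c("# Cohort report", "",
             sprintf("Seed: %d; config hash: %d", result$config$seed,
                     config_hash(unclass(result$config))), "",
             sprintf("Individuals with retained stationary periods: %d",
                     nrow(result$records$features)),
             sprintf("Analysis set: %d (excluded: %d year, %d southern)",
                     nrow(result$exclusions$analysis),
                     nrow(result$exclusions$excluded_year),
                     nrow(result$exclusions$excluded_southern)),
             sprintf("Itinerant individuals: %d",
                     sum(result$records$features$itinerant)), "")
  if (length(ow$cross$ids)) {
    within <- ow$cross$pairs[ow$cross$pairs$within_individual, "owd"]
    among <- ow$cross$pairs[!ow$cross$pairs$within_individual, "owd"]
    mse <- function(x) sprintf("%.2f +/- %.2f SE (n = %d)", mean(x),
                               stats::sd(x) / sqrt(length(x)), length(x))
    lines <- c(lines, "## OWD summary", "",
               paste0("- post-breeding pairwise: ", mse(ow$post$pairs$owd)),
               paste0("- pre-breeding pairwise: ", mse(ow$pre$pairs$owd)),
               paste0("- within-individual post vs pre: ", mse(within)),
               paste0("- among-individual post vs pre: ", mse(among)), "")
  }
  lines <- c(lines, "## Feature summaries (mean +/- SE)", "")
  for (g in unique(rep$group)) {
    lines <- c(lines, paste0("### ", g), "")
    sub <- rep[rep$group == g, ]
    lines <- c(lines, sprintf("- %s: %.2f%s (n = %d)", sub$variable, sub$mean,
                              ifelse(is.na(sub$se), "",
                                     sprintf(" +/- %.2f", sub$se)), sub$n))
    lines <- c(lines, "")
  }
  lines
}
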