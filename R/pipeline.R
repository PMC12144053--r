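#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run: either synthetic generation
#' (a [cohort_config()]) or paths to raw sensor log files, plus the
#' processing thresholds.
#'
#' @param synthetic logical; generate a cohort instead of reading files.
#' @param cohort `sm_cohort_config` used when `synthetic = TRUE`.
#' @param log_paths character vector of sensor log files (long dialect)
#'   used when `synthetic = FALSE`.
#' @param key_path category key file; default is the packaged reference key.
#' @param out_dir output directory for artifacts (`NULL` = don't write).
#' @param tz IANA zone for all local binning.
#' @param episode_cap_minutes usage-episode duration cap.
#' @param valid_hour_min_minutes valid-hour threshold (minutes of sensing
#'   coverage needed to trust a zero).
#' @param day_max_missing_hours day exclusion threshold.
#' @param categories category scopes to compute.
#' @return validated list of class `sm_pipeline_config`.
#' @export
pipeline_config <- function(synthetic = TRUE, cohort = cohort_config(),
                            log_paths = NULL, key_path = NULL,
                            out_dir = NULL, tz = "UTC",
                            episode_cap_minutes = 120,
                            valid_hour_min_minutes = 30,
                            day_max_missing_hours = 12,
                            categories = SM_CATEGORIES) {
  if (episode_cap_minutes <= 0) stop("episode_cap_minutes must be positive",
                                     call. = FALSE)
  if (valid_hour_min_minutes < 0 || valid_hour_min_minutes > 60)
    stop("valid_hour_min_minutes must be in [0, 60]", call. = FALSE)
  if (day_max_missing_hours < 0 || day_max_missing_hours > 24)
    stop("day_max_missing_hours must be in [0, 24]", call. = FALSE)
  bad <- setdiff(categories, SM_CATEGORIES)
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!synthetic && is.null(log_paths))
    stop("log_paths required when synthetic = FALSE", call. = FALSE)
  .check_tz(tz)
  structure(as.list(environment())[c("synthetic", "cohort", "log_paths",
                                     "key_path", "out_dir", "tz",
                                     "episode_cap_minutes",
                                     "valid_hour_min_minutes",
                                     "day_max_missing_hours", "categories")],
            class = "sm_pipeline_config")
}

#' Run the full sensing-to-statistics pipeline
#'
#' Orchestrates generate/ingest, episode reconstruction, valid-minute and
#' yield computation, hourly and daily feature extraction per category,
#' per-app descriptives, and the statistical surfaces (grain summaries,
#' between-person variance fractions, cross-category repeated-measures
#' correlations, duration-versus-checking coupling). When `out_dir` is set,
#' writes the yield report, feature tables, per-app table, a stats JSON, a
#' run manifest (config, seed, package version) and per-participant daily
#' time-series plots of duration and checks by category and for the popular
#' apps.
#'
#' @param config `sm_pipeline_config` from [pipeline_config()].
#' @return object of class `sm_pipeline` bundling all intermediate and
#'   final artifacts.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "sm_pipeline_config"))
    stop("config must come from pipeline_config()", call. = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  key <- stage("key", if (is.null(config$key_path)) load_key()
               else load_key(config$key_path))

  if (config$synthetic) {
    cohort <- stage("generate", generate_cohort(config$cohort))
    logs <- list(foreground = cohort$foreground, screen = cohort$screen,
                 aux = cohort$aux)
    enrollment <- cohort$truth$enrollment
  } else {
    cohort <- NULL
    logs <- stage("ingest", read_sensor_tables(config$log_paths,
                                               tz = config$tz))
    enrollment <- NULL
  }
  message(sprintf("[ingest] %d foreground events, %d screen events, %d aux rows",
                  nrow(logs$foreground), nrow(logs$screen),
                  nrow(logs$aux)))

  episodes <- stage("episodes",
                    build_episodes(logs$foreground, logs$screen,
                                   cap_minutes = config$episode_cap_minutes))
  message(sprintf("[episodes] %d usage episodes", nrow(episodes)))

  bins <- stage("yield", hour_bins(logs, tz = config$tz,
                                   enrollment = enrollment))
  yield <- stage("yield", yield_summary(bins))
  message(sprintf("[yield] %.1f%% pooled over %d bins",
                  100 * yield$study_pooled, nrow(bins)))

  hourly <- list(); daily <- list()
  for (cat in config$categories) {
    hourly[[cat]] <- stage(paste0("features:", cat),
      hourly_features(episodes, logs$foreground, bins, scope = cat,
                      key = key, tz = config$tz,
                      min_valid_minutes = config$valid_hour_min_minutes))
    daily[[cat]] <- stage(paste0("features:", cat),
      daily_features(hourly[[cat]],
                     max_missing_hours = config$day_max_missing_hours))
  }
  n_missing <- if (length(hourly)) sum(hourly[[1L]]$status == "missing")
               else 0L
  message(sprintf("[features] %d hourly cells per category, %d missing",
                  if (length(hourly)) nrow(hourly[[1L]]) else 0L, n_missing))

  apps <- stage("apps", per_app_table(
    episodes, logs$foreground, bins, key = key, tz = config$tz,
    min_valid_minutes = config$valid_hour_min_minutes,
    max_missing_hours = config$day_max_missing_hours))

  stats_out <- stage("stats", .pipeline_stats(hourly, daily,
                                              config$categories))

  res <- structure(list(config = config, cohort = cohort, logs = logs,
                        episodes = episodes, bins = bins, yield = yield,
                        hourly = hourly, daily = daily, apps = apps,
                        stats = stats_out, key = key),
                   class = "sm_pipeline")
  if (!is.null(config$out_dir)) stage("write", .write_bundle(res))
  res
}

.pipeline_stats <- function(hourly, daily, categories) {
  blocks <- list()
  for (cat in categories) {
    for (f in c("duration", "checks")) {
      blocks[[length(blocks) + 1L]] <-
        summarize_usage(daily[[cat]], "between_person", f)
      blocks[[length(blocks) + 1L]] <- summarize_usage(daily[[cat]],
                                                       "daily", f)
      blocks[[length(blocks) + 1L]] <- summarize_usage(hourly[[cat]],
                                                       "hourly", f)
    }
  }
  summaries <- do.call(rbind, blocks)

  icc <- lapply(stats::setNames(categories, categories), function(cat) {
    d <- daily[[cat]][excluded == FALSE]
    list(duration = icc_between_fraction(d$daily_sum, d$participant_id),
         checks = icc_between_fraction(d$daily_checks, d$participant_id))
  })

  cross <- list()
  if (length(categories) > 1L) {
    prs <- utils::combn(categories, 2, simplify = FALSE)
    for (pr in prs) {
      a <- daily[[pr[1L]]][excluded == FALSE]
      b <- daily[[pr[2L]]][excluded == FALSE]
      m <- merge(a[, .(participant_id, date, x = daily_sum,
                       xc = daily_checks)],
                 b[, .(participant_id, date, y = daily_sum,
                       yc = daily_checks)],
                 by = c("participant_id", "date"))
      nm <- paste(pr, collapse = "_vs_")
      cross[[nm]] <- list(
        duration = tryCatch(rm_correlation(m$x, m$y, m$participant_id),
                            error = function(e) NULL),
        checks = tryCatch(rm_correlation(m$xc, m$yc, m$participant_id),
                          error = function(e) NULL))
    }
  }

  dur_chk <- lapply(stats::setNames(categories, categories), function(cat) {
    tryCatch(duration_checks_correlation(daily[[cat]]),
             error = function(e) NULL)
  })

  list(summaries = summaries, icc = icc, cross_category = cross,
       duration_vs_checks = dur_chk)
}

.write_bundle <- function(res) {
  out <- res$config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(res$yield$participants, file.path(out, "yield.csv"))
  data.table::fwrite(data.table::rbindlist(res$hourly),
                     file.path(out, "features_hourly.csv"))
  data.table::fwrite(data.table::rbindlist(res$daily),
                     file.path(out, "features_daily.csv"))
  data.table::fwrite(res$apps, file.path(out, "per_app.csv"))
  data.table::fwrite(as.data.table(res$stats$summaries),
                     file.path(out, "summaries.csv"))

  to_num <- function(o) if (is.null(o)) NULL else unclass(o)
  jsonlite::write_json(list(
    yield = list(study_pooled = res$yield$study_pooled,
                 study_participant_mean = res$yield$study_participant_mean),
    icc = lapply(res$stats$icc, function(x) lapply(x, to_num)),
    cross_category = lapply(res$stats$cross_category,
                            function(x) lapply(x, to_num)),
    duration_vs_checks = lapply(res$stats$duration_vs_checks, to_num)),
    file.path(out, "stats.json"), digits = NA, auto_unbox = TRUE)

  manifest <- list(
    package = "smsense",
    version = as.character(utils::packageVersion("smsense")),
    r_version = as.character(getRversion()),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = .manifest_config(res$config))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")

  dir.create(file.path(out, "plots"), showWarnings = FALSE)
  .plot_daily(res, "daily_sum", file.path(out, "plots",
                                          "daily_duration_by_category.png"))
  .plot_daily(res, "daily_checks",
              file.path(out, "plots", "daily_checks_by_category.png"))
  .plot_apps(res, "minutes", file.path(out, "plots",
                                       "daily_duration_popular_apps.png"))
  .plot_apps(res, "checks", file.path(out, "plots",
                                      "daily_checks_popular_apps.png"))
  invisible(out)
}

.manifest_config <- function(cfg) {
  out <- unclass(cfg)
  if (!is.null(out$cohort)) {
    cc <- unclass(out$cohort)
    cc$app_weights <- as.list(cc$app_weights)
    out$cohort <- cc
  }
  out
}

# matrix of per-participant daily series, one panel per participant
.plot_daily <- function(res, what, path) {
  dd <- data.table::rbindlist(res$daily)
  if (!nrow(dd)) return(invisible())
  ids <- unique(dd$participant_id)
  n <- length(ids)
  cats <- res$config$categories
  cols <- hcl.colors(max(length(cats), 2L), "Dark 3")
  grDevices::png(path, width = 1400, height = 250 * ceiling(n / 4),
                 res = 96)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(ceiling(n / 4), min(n, 4)),
                mar = c(2.5, 3.5, 2, 0.5))
  for (id in ids) {
    pd <- dd[participant_id == id]
    wide <- data.table::dcast(pd, date ~ scope, value.var = what)
    graphics::matplot(wide$date, as.matrix(wide[, -1L]), type = "l",
                      lty = 1, col = cols, xlab = "", ylab = what,
                      main = id)
  }
  graphics::legend("topright", legend = cats, col = cols, lty = 1,
                   cex = 0.7, bty = "n")
  invisible(path)
}

.plot_apps <- function(res, what, path) {
  apps <- as.data.table(res$apps)
  pop <- apps[grepl("popular", apps$categories)][seq_len(min(4, .N))]
  if (!nrow(pop)) return(invisible())
  col <- if (what == "minutes") "daily_sum" else "daily_checks"
  series <- lapply(pop$package_name, function(p) {
    hf <- hourly_features(res$episodes, res$logs$foreground, res$bins,
                          scope = p, key = res$key, tz = res$config$tz,
                          min_valid_minutes =
                            res$config$valid_hour_min_minutes)
    df <- daily_features(hf, res$config$day_max_missing_hours)
    df[, .(v = mean(get(col))), by = date]
  })
  grDevices::png(path, width = 1000, height = 600, res = 96)
  on.exit(grDevices::dev.off())
  cols <- hcl.colors(nrow(pop), "Dark 3")
  rng <- range(unlist(lapply(series, `[[`, "v")), na.rm = TRUE)
  plot(series[[1L]]$date, series[[1L]]$v, type = "l", col = cols[1L],
       ylim = rng, xlab = "date",
       ylab = paste("cohort mean daily", what),
       main = "Popular social media apps")
  if (nrow(pop) > 1L) {
    for (i in 2:nrow(pop)) {
      graphics::lines(series[[i]]$date, series[[i]]$v, col = cols[i])
    }
  }
  graphics::legend("topright", legend = pop$app_label, col = cols, lty = 1,
                   bty = "n")
  invisible(path)
}

#' @export
print.sm_pipeline <- function(x, ...) {
  cat("Social-media sensing pipeline run\n")
  cat(sprintf("  participants: %d | hourly bins: %d | episodes: %d\n",
              length(unique(x$bins$participant_id)), nrow(x$bins),
              nrow(x$episodes)))
  cat(sprintf("  data yield: %.1f%% pooled\n", 100 * x$yield$study_pooled))
  cat("  categories:", paste(x$config$categories, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.sm_pipeline <- function(object, ...) {
  print(object)
  cat("\nGrain summaries:\n")
  print(object$stats$summaries, digits = 4, row.names = FALSE)
  cat("\nBetween-person variance fractions (ICC):\n")
  for (cat_ in names(object$stats$icc)) {
    ic <- object$stats$icc[[cat_]]
    cat(sprintf("  %-12s duration %.2f | checks %.2f\n", cat_,
                ic$duration$between_fraction, ic$checks$between_fraction))
  }
  cat("\nDuration vs checks (within-person r):\n")
  for (cat_ in names(object$stats$duration_vs_checks)) {
    dc <- object$stats$duration_vs_checks[[cat_]]
    if (!is.null(dc)) cat(sprintf("  %-12s r = %.2f\n", cat_, dc$r))
  }
  invisible(object)
}

#' Daily usage time-series plot
#'
#' Cohort-mean daily duration (or checks) by category over the study period.
#'
#' @param x `sm_pipeline` object.
#' @param what `"duration"` or `"checks"`.
#' @param ... ignored.
#' @export
plot.sm_pipeline <- function(x, what = c("duration", "checks"), ...) {
  what <- match.arg(what)
  col <- if (what == "duration") "daily_sum" else "daily_checks"
  dd <- data.table::rbindlist(x$daily)
  m <- dd[excluded == FALSE, .(v = mean(get(col))), by = .(date, scope)]
  wide <- data.table::dcast(m, date ~ scope, value.var = "v")
  cats <- setdiff(names(wide), "date")
  cols <- hcl.colors(max(length(cats), 2L), "Dark 3")
  graphics::matplot(wide$date, as.matrix(wide[, -1L]), type = "l", lty = 1,
                    col = cols, xlab = "date",
                    ylab = paste("cohort mean daily", what))
  graphics::legend("topright", legend = cats, col = cols, lty = 1,
                   bty = "n")
  invisible(x)
}
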