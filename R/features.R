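#' Hourly behavioral features for a category or app
#'
#' Computes the three behavioral features per participant-hour cell for a
#' usage scope: `sum_duration` (foreground minutes, episode durations
#' apportioned to hours by exact half-open interval intersection, so an
#' episode spanning a boundary contributes to both hours), `count_event`
#' (launches, each counted once in the hour containing its start instant —
#' opening an app is instantaneous), and `count_episode` (0/1 indicator of
#' any launch in the hour). Cells inherit their zero-versus-missing status
#' from the bin via [apply_valid_hour_rule()], applied to the scope's own
#' captured usage: an under-sensed hour with no captured usage *of this
#' scope* is missing, an hour with captured usage is observed.
#'
#' Category features are the sums of their member apps' features (episodes
#' of one participant cannot overlap, so summing cannot double count);
#' `count_episode` for a category is the max over members.
#'
#' @param episodes `sm_episodes` from [build_episodes()].
#' @param events launch events (`participant_id`, `timestamp`,
#'   `package_name`): the foreground table.
#' @param bins `sm_bins` grid from [hour_bins()].
#' @param scope one of `"sns"`, `"broad"`, `"google_play"`, `"popular"`
#'   (requires `key`), `"all"` (every package), or a single package name.
#' @param key `sm_key`, required for category scopes.
#' @param tz IANA zone for hour assignment.
#' @param min_valid_minutes valid-hour threshold passed to
#'   [apply_valid_hour_rule()].
#' @return data.table `participant_id`, `date`, `hour`, `scope_type`,
#'   `scope`, `sum_duration`, `count_event`, `count_episode`, `status`,
#'   `value` (the status-resolved duration: captured, 0, or NA),
#'   `valid_minutes`, classed `sm_hourly`.
#' @export
hourly_features <- function(episodes, events, bins, scope = "broad",
                            key = NULL, tz = "UTC",
                            min_valid_minutes = 30) {
  .check_tz(tz)
  if (scope %in% SM_CATEGORIES) {
    if (is.null(key)) key <- load_key()
    .check_key(key)
    members <- category_members(key, scope)
    scope_type <- "category"
  } else if (identical(scope, "all")) {
    members <- NULL
    scope_type <- "all"
  } else {
    members <- scope
    scope_type <- "package"
  }
  ep <- as.data.table(episodes)
  ev <- as.data.table(events)
  if (scope_type == "package") {
    known <- c(unique(ev$package_name),
               if (!is.null(key)) key$package_name)
    if (!scope %in% known) {
      stop("unknown scope '", scope, "': not a category, not 'all', and ",
           "not a package in the key or the event log", call. = FALSE)
    }
  }
  if (!is.null(members)) {
    ep <- ep[package_name %in% members]
    ev <- ev[package_name %in% members]
  }

  grid <- as.data.table(bins)[, .(participant_id, date, hour, valid_minutes)]
  grid[, slot := as.numeric(date) * 24 + hour]

  if (nrow(ep)) {
    s_loc <- ep$start + .offset_ms(ep$start, tz)
    e_loc <- ep$end + .offset_ms(ep$end, tz)
    h0 <- floor(s_loc / MS_PER_HOUR)
    h1 <- floor((e_loc - 1) / MS_PER_HOUR)  # half-open: last ms is end - 1
    nh <- as.integer(h1 - h0 + 1L)
    idx <- rep.int(seq_len(nrow(ep)), nh)
    sl <- h0[idx] + (sequence(nh) - 1L)
    ov <- (pmin(e_loc[idx], (sl + 1) * MS_PER_HOUR) -
             pmax(s_loc[idx], sl * MS_PER_HOUR)) / MS_PER_MIN
    dur <- data.table(participant_id = ep$participant_id[idx], slot = sl,
                      sum_duration = ov)[, .(sum_duration =
                                               sum(sum_duration)),
                                         by = .(participant_id, slot)]
  } else {
    dur <- data.table(participant_id = character(), slot = numeric(),
                      sum_duration = numeric())
  }
  if (nrow(ev)) {
    cnt <- data.table(participant_id = ev$participant_id,
                      slot = .local_hour_slot(ev$timestamp, tz))[
      , .(count_event = .N), by = .(participant_id, slot)]
  } else {
    cnt <- data.table(participant_id = character(), slot = numeric(),
                      count_event = integer())
  }

  out <- merge(grid, dur, by = c("participant_id", "slot"), all.x = TRUE)
  out <- merge(out, cnt, by = c("participant_id", "slot"), all.x = TRUE)
  out[is.na(sum_duration), sum_duration := 0]
  out[is.na(count_event), count_event := 0L]
  out[, count_episode := as.integer(count_event > 0L)]
  captured <- out$sum_duration + out$count_event  # > 0 iff any usage seen
  rule <- apply_valid_hour_rule(out$valid_minutes, captured,
                                min_valid_minutes)
  out[, status := rule$status]
  out[, value := ifelse(status == "missing", NA_real_, sum_duration)]
  out[, `:=`(scope_type = scope_type, scope = scope, slot = NULL)]
  data.table::setcolorder(out, c("participant_id", "date", "hour",
                                 "scope_type", "scope", "sum_duration",
                                 "count_event", "count_episode", "status",
                                 "value", "valid_minutes"))
  data.table::setorder(out, participant_id, date, hour)
  data.table::setattr(out, "class", c("sm_hourly", class(out)))
  out[]
}

#' Daily features from hourly cells
#'
#' Sums hourly usage to the civil day (00:00–23:59): `daily_sum` is the sum
#' of the status-resolved hourly durations over non-missing hours,
#' `daily_checks` the corresponding launch count. `n_missing_hours` counts
#' hours of the day that are missing (including hours outside the
#' enrollment window on partial first/last days), and a day is flagged
#' `excluded` for downstream statistics when more than `max_missing_hours`
#' of its 24 are missing — the day-level analogue of the hour-level 50%
#' convention.
#'
#' @param hourly `sm_hourly` table from [hourly_features()] (one scope).
#' @param max_missing_hours exclusion threshold, default 12.
#' @return data.table `participant_id`, `date`, `scope_type`, `scope`,
#'   `daily_sum`, `daily_checks`, `n_missing_hours`, `excluded`, classed
#'   `sm_daily`.
#' @export
daily_features <- function(hourly, max_missing_hours = 12) {
  h <- as.data.table(hourly)
  if (anyDuplicated(h[, .(participant_id, date, hour, scope)])) {
    stop("duplicate (participant, date, hour, scope) cells", call. = FALSE)
  }
  out <- h[, {
    miss <- sum(status == "missing") + (24L - .N)
    .(scope_type = scope_type[1L], scope = scope[1L],
      daily_sum = sum(value, na.rm = TRUE),
      daily_checks = sum(count_event[status != "missing"]),
      n_missing_hours = as.integer(miss))
  }, by = .(participant_id, date)]
  out[, excluded := n_missing_hours > max_missing_hours]
  data.table::setorder(out, participant_id, date)
  data.table::setattr(out, "class", c("sm_daily", class(out)))
  out[]
}

#' Per-app descriptive usage table
#'
#' For each app in the key that appears in the logs: number and share of
#' participants who used it, and mean/SD of per-participant mean daily
#' minutes and daily checks — computed both over *all* participants
#' (non-users contribute zero days) and over *users only*, the two variants
#' conventionally reported side by side. SDs over a single participant are
#' NA. Excluded days (see [daily_features()]) are dropped.
#'
#' @param episodes `sm_episodes` table.
#' @param events launch event table.
#' @param bins `sm_bins` grid.
#' @param key `sm_key`; apps outside the key are not tabulated.
#' @param tz,min_valid_minutes,max_missing_hours passed through to the
#'   feature extraction.
#' @return data.table, one row per used app, with usage stats and the app's
#'   category memberships, ordered by number of users, classed `sm_apps`.
#' @export
per_app_table <- function(episodes, events, bins, key = load_key(),
                          tz = "UTC", min_valid_minutes = 30,
                          max_missing_hours = 12) {
  .check_key(key)
  used <- intersect(key$package_name,
                    unique(as.data.table(events)$package_name))
  cohort <- unique(as.data.table(bins)$participant_id)
  n_cohort <- length(cohort)
  rows <- lapply(used, function(p) {
    hf <- hourly_features(episodes, events, bins, scope = p, key = key,
                          tz = tz, min_valid_minutes = min_valid_minutes)
    df <- daily_features(hf, max_missing_hours = max_missing_hours)
    df <- df[excluded == FALSE]
    per <- df[, .(mean_daily_minutes = mean(daily_sum),
                  mean_daily_checks = mean(daily_checks)),
              by = participant_id]
    users <- per[mean_daily_minutes > 0 | mean_daily_checks > 0,
                 participant_id]
    # all-participant variant: participants with no use count as zeros
    allv <- merge(data.table(participant_id = cohort), per,
                  by = "participant_id", all.x = TRUE)
    allv[is.na(mean_daily_minutes), mean_daily_minutes := 0]
    allv[is.na(mean_daily_checks), mean_daily_checks := 0]
    uv <- allv[participant_id %in% users]
    i <- match(p, key$package_name)
    data.table(
      app_label = key$app_label[i], package_name = p,
      n_users = length(users), pct_users = 100 * length(users) / n_cohort,
      mean_daily_minutes_all = mean(allv$mean_daily_minutes),
      sd_daily_minutes_all = sd(allv$mean_daily_minutes),
      mean_daily_checks_all = mean(allv$mean_daily_checks),
      sd_daily_checks_all = sd(allv$mean_daily_checks),
      mean_daily_minutes_users = if (nrow(uv)) mean(uv$mean_daily_minutes)
                                 else NA_real_,
      sd_daily_minutes_users = if (nrow(uv) > 1) sd(uv$mean_daily_minutes)
                               else NA_real_,
      mean_daily_checks_users = if (nrow(uv)) mean(uv$mean_daily_checks)
                                else NA_real_,
      sd_daily_checks_users = if (nrow(uv) > 1) sd(uv$mean_daily_checks)
                              else NA_real_,
      categories = paste(SM_CATEGORIES[c(key$sns[i], key$broad[i],
                                         key$google_play[i],
                                         key$popular[i])],
                         collapse = ";"))
  })
  out <- data.table::rbindlist(rows)
  if (nrow(out)) data.table::setorder(out, -n_users, -mean_daily_minutes_all)
  data.table::setattr(out, "class", c("sm_apps", class(out)))
  out[]
}
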