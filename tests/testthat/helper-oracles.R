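# Independent oracles and small fixture builders. Everything here avoids the
# package's own vectorized code paths: brute-force scans and per-second
# accumulation only.

ts_ms <- function(s, tz = "UTC") as.numeric(as.POSIXct(s, tz = tz)) * 1000

# brute-force valid-minute count for one local hour: scan the 60
# clock-aligned windows one by one
brute_valid_minutes <- function(timestamps_ms, hour_start_ms) {
  n <- 0L
  for (m in 0:59) {
    lo <- hour_start_ms + m * 60000
    if (any(timestamps_ms >= lo & timestamps_ms < lo + 60000)) n <- n + 1L
  }
  n
}

# per-second accumulation of episode durations and launch counts into UTC
# hour slots; episodes must sit on whole seconds
brute_hourly <- function(episodes, events) {
  acc <- new.env(parent = emptyenv())
  bump <- function(key, dur, cnt) {
    cur <- if (!is.null(acc[[key]])) acc[[key]] else c(0, 0)
    acc[[key]] <- cur + c(dur, cnt)
  }
  for (i in seq_len(nrow(episodes))) {
    s <- episodes$start[i] / 1000
    e <- episodes$end[i] / 1000
    for (sec in seq(s, e - 1)) {
      slot <- floor(sec / 3600)
      bump(paste(episodes$participant_id[i], slot), 1 / 60, 0)
    }
  }
  for (i in seq_len(nrow(events))) {
    slot <- floor(events$timestamp[i] / 1000 / 3600)
    bump(paste(events$participant_id[i], slot), 0, 1)
  }
  keys <- ls(acc)
  out <- data.frame(
    participant_id = sub(" .*", "", keys),
    slot = as.numeric(sub(".* ", "", keys)),
    sum_duration = vapply(keys, function(k) acc[[k]][1], numeric(1)),
    count_event = vapply(keys, function(k) acc[[k]][2], numeric(1)),
    row.names = NULL)
  out[order(out$participant_id, out$slot), ]
}

# random non-overlapping whole-second episode set (plus matching launch
# events and a full-coverage bin grid) inside a few days after the epoch
random_episode_set <- function(n_episodes = 5, n_participants = 2,
                               window_hours = 72) {
  pid <- sprintf("P%d", sample.int(n_participants, n_episodes,
                                   replace = TRUE))
  start <- floor(runif(n_episodes, 0, window_hours * 3600 - 7500)) * 1000
  dur <- sample.int(7200, n_episodes, replace = TRUE) * 1000
  d <- data.frame(participant_id = pid, start = start,
                  end = start + dur,
                  package_name = "com.snapchat.android")
  # resolve overlaps per participant by pushing episodes right
  d <- d[order(d$participant_id, d$start), ]
  for (p in unique(d$participant_id)) {
    idx <- which(d$participant_id == p)
    cur <- -Inf
    for (i in idx) {
      if (d$start[i] < cur) {
        shift <- cur - d$start[i]
        d$start[i] <- d$start[i] + shift
        d$end[i] <- d$end[i] + shift
      }
      cur <- d$end[i]
    }
  }
  d$duration <- (d$end - d$start) / 60000
  d$n_events <- 1L
  events <- data.frame(participant_id = d$participant_id,
                       timestamp = d$start,
                       package_name = d$package_name)
  max_slot <- ceiling(max(d$end) / 3600000)
  grid <- expand.grid(participant_id = unique(d$participant_id),
                      slot = 0:max_slot, stringsAsFactors = FALSE)
  bins <- data.frame(participant_id = grid$participant_id,
                     date = as.Date(grid$slot %/% 24,
                                    origin = "1970-01-01"),
                     hour = grid$slot %% 24,
                     valid_minutes = 60L)
  list(episodes = d, events = events, bins = bins)
}

# hand-build an sm_daily-shaped table for the stats functions
daily_fixture <- function(participant_id, daily_sum,
                          daily_checks = daily_sum) {
  data.table::data.table(participant_id = participant_id,
                         date = as.Date("2020-04-01") +
                           seq_along(participant_id),
                         scope_type = "category", scope = "broad",
                         daily_sum = daily_sum,
                         daily_checks = daily_checks,
                         n_missing_hours = 0L, excluded = FALSE)
}

# event-log csv writer in the long dialect
write_log_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
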