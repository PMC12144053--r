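make_bins <- function(pids, dates, vm = 60L) {
  g <- expand.grid(participant_id = pids, date = as.Date(dates),
                   hour = 0:23, stringsAsFactors = FALSE)
  data.table::data.table(g, valid_minutes = vm)
}

test_that("episode durations are apportioned to hours by exact intersection", {
  key <- load_key()
  bins <- make_bins("P1", "2020-06-01")
  ep <- data.frame(participant_id = "P1",
                   package_name = "com.snapchat.android",
                   start = ts_ms("2020-06-01 10:15:00"),
                   end = ts_ms("2020-06-01 10:45:00"),
                   duration = 30, n_events = 1L)
  ev <- data.frame(participant_id = "P1", timestamp = ep$start,
                   package_name = ep$package_name)
  hf <- hourly_features(ep, ev, bins, scope = "broad", key = key)
  h10 <- hf[hf$hour == 10, ]
  expect_equal(h10$sum_duration, 30)
  expect_equal(h10$count_event, 1L)
  expect_equal(h10$count_episode, 1L)
  expect_equal(as.character(h10$status), "observed")

  # boundary-spanning episode: duration split, launch counted in start bin
  ep2 <- transform(ep, start = ts_ms("2020-06-01 10:50:00"),
                   end = ts_ms("2020-06-01 11:10:00"), duration = 20)
  ev2 <- transform(ev, timestamp = ep2$start)
  hf2 <- hourly_features(ep2, ev2, bins, scope = "broad", key = key)
  expect_equal(hf2$sum_duration[hf2$hour == 10], 10)
  expect_equal(hf2$sum_duration[hf2$hour == 11], 10)
  expect_equal(hf2$count_event[hf2$hour == 10], 1L)
  expect_equal(hf2$count_event[hf2$hour == 11], 0L)

  # valid hour without member-app usage: zero-filled
  h9 <- hf[hf$hour == 9, ]
  expect_equal(h9$sum_duration, 0)
  expect_equal(as.character(h9$status), "zero_filled")
  expect_error(hourly_features(ep, ev, bins, scope = "sns ", key = key),
               "unknown scope")
})

test_that("hourly features equal the per-second brute-force accumulator", {
  set.seed(101)
  for (trial in 1:100) {
    fx <- random_episode_set(n_episodes = sample(1:6, 1))
    hf <- hourly_features(fx$episodes, fx$events, fx$bins, scope = "all")
    got <- hf[hf$sum_duration > 0 | hf$count_event > 0, ]
    got$slot <- as.numeric(got$date) * 24 + got$hour
    ref <- brute_hourly(fx$episodes, fx$events)
    got <- got[order(got$participant_id, got$slot), ]
    expect_equal(nrow(got), nrow(ref))
    expect_equal(got$sum_duration, ref$sum_duration, tolerance = 1e-9)
    expect_equal(got$count_event, as.integer(ref$count_event))
  }
})

test_that("daily features sum non-missing hours and track missingness", {
  key <- load_key()
  bins <- make_bins("P1", "2020-06-01")
  # 2 minutes of use in each of the 24 hours
  eps <- data.frame(participant_id = "P1",
                    package_name = "com.snapchat.android",
                    start = ts_ms("2020-06-01 00:10:00") +
                      (0:23) * 3600000,
                    n_events = 1L)
  eps$end <- eps$start + 120000
  eps$duration <- 2
  evs <- data.frame(participant_id = "P1", timestamp = eps$start,
                    package_name = eps$package_name)
  hf <- hourly_features(eps, evs, bins, scope = "broad", key = key)
  df <- daily_features(hf)
  expect_equal(df$daily_sum, 48)
  expect_equal(df$daily_checks, 24L)
  expect_equal(df$n_missing_hours, 0L)
  expect_false(df$excluded)

  # drop usage in hour 23 and kill its sensing: one missing hour
  bins2 <- data.table::copy(bins)[hour == 23, valid_minutes := 0L]
  hf2 <- hourly_features(eps[1:23, ], evs[1:23, ], bins2, scope = "broad",
                         key = key)
  df2 <- daily_features(hf2)
  expect_equal(df2$daily_sum, 46)
  expect_equal(df2$n_missing_hours, 1L)

  # exclusion policy: >12 missing hours drops the day from statistics
  bins3 <- data.table::copy(bins)[hour >= 11, valid_minutes := 0L]
  hf3 <- hourly_features(eps[1:2, ], evs[1:2, ], bins3, scope = "broad",
                         key = key)
  df3 <- daily_features(hf3)
  expect_equal(df3$n_missing_hours, 13L)
  expect_true(df3$excluded)
  expect_false(daily_features(hf3, max_missing_hours = 13)$excluded)

  expect_error(daily_features(rbind(hf, hf)), "duplicate")
})

test_that("category features are sums of member apps and nest correctly", {
  set.seed(59)
  cfg <- cohort_config(n_participants = 4, n_days = 5, seed = 31,
                       outage_rate = 0.5)
  co <- generate_cohort(cfg)
  ep <- build_episodes(co$foreground, co$screen)
  bins <- hour_bins(list(co$foreground, co$screen, co$aux),
                    enrollment = co$truth$enrollment)
  key <- load_key()
  hb <- hourly_features(ep, co$foreground, bins, "broad", key)
  hs <- hourly_features(ep, co$foreground, bins, "sns", key)
  hp <- hourly_features(ep, co$foreground, bins, "popular", key)
  hall <- hourly_features(ep, co$foreground, bins, "all", key)

  # cellwise nesting (tables share the same bin grid ordering)
  expect_true(all(hs$sum_duration <= hb$sum_duration + 1e-9))
  expect_true(all(hp$sum_duration <= hb$sum_duration + 1e-9))
  expect_true(all(hs$count_event <= hb$count_event))
  # broad equals the sum over its member apps
  members <- intersect(category_members(key, "broad"),
                       unique(co$foreground$package_name))
  per_app <- Reduce(`+`, lapply(members, function(p) {
    hourly_features(ep, co$foreground, bins, p, key)$sum_duration
  }))
  expect_equal(hb$sum_duration, per_app, tolerance = 1e-9)
  # an hour has at most 60 minutes across ALL apps combined
  expect_true(all(hall$sum_duration <= 60 + 1e-9))
  expect_true(all(hall$count_event >= hall$count_episode))
  expect_true(all(hall$count_episode %in% c(0L, 1L)))
  # zero launches if and only if zero events counted
  expect_equal(hall$count_event == 0L, hall$count_episode == 0L)
})

test_that("doubling episode durations changes duration but not launch counts", {
  set.seed(77)
  fx <- random_episode_set(n_episodes = 6)
  hf1 <- hourly_features(fx$episodes, fx$events, fx$bins, "all")
  doubled <- fx$episodes
  doubled$end <- doubled$end + (doubled$end - doubled$start)
  # re-resolve overlaps by pushing
  doubled <- doubled[order(doubled$participant_id, doubled$start), ]
  for (p in unique(doubled$participant_id)) {
    idx <- which(doubled$participant_id == p)
    cur <- -Inf
    for (i in idx) {
      if (doubled$start[i] < cur) {
        sh <- cur - doubled$start[i]
        doubled$start[i] <- doubled$start[i] + sh
        doubled$end[i] <- doubled$end[i] + sh
      }
      cur <- doubled$end[i]
    }
  }
  ev2 <- data.frame(participant_id = doubled$participant_id,
                    timestamp = doubled$start,
                    package_name = doubled$package_name)
  grid2 <- make_bins(unique(doubled$participant_id),
                     seq(as.Date("1970-01-01"), by = 1, length.out = 8))
  hf2 <- hourly_features(doubled, ev2, grid2, "all")
  expect_equal(sum(hf2$sum_duration), 2 * sum(hf1$sum_duration),
               tolerance = 1e-9)
  expect_equal(sum(hf2$count_event), sum(hf1$count_event))
})

test_that("per-app table computes both all-participant and users-only means", {
  key <- load_key()
  bins <- make_bins(c("P1", "P2"), "2020-06-01")
  # Snapchat used by P1 only, 10 min / 1 launch on the single day
  ep <- data.frame(participant_id = "P1",
                   package_name = "com.snapchat.android",
                   start = ts_ms("2020-06-01 12:00:00"),
                   end = ts_ms("2020-06-01 12:10:00"),
                   duration = 10, n_events = 1L)
  ev <- data.frame(participant_id = "P1", timestamp = ep$start,
                   package_name = ep$package_name)
  tab <- per_app_table(ep, ev, bins, key)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$app_label, "Snapchat")
  expect_equal(tab$n_users, 1L)
  expect_equal(tab$pct_users, 50)
  expect_equal(tab$mean_daily_minutes_all, 5)      # (10 + 0) / 2
  expect_equal(tab$mean_daily_minutes_users, 10)
  expect_true(is.na(tab$sd_daily_minutes_users))   # single user
  expect_match(tab$categories, "popular")

  # both participants use it at 10 min/day: the two variants coincide
  ep2 <- rbind(ep, transform(ep, participant_id = "P2"))
  ev2 <- rbind(ev, transform(ev, participant_id = "P2"))
  tab2 <- per_app_table(ep2, ev2, bins, key)
  expect_equal(tab2$n_users, 2L)
  expect_equal(tab2$pct_users, 100)
  expect_equal(tab2$mean_daily_minutes_all, 10)
  expect_equal(tab2$mean_daily_minutes_users, 10)
})

test_that("user prevalence ordering reflects generator app weights", {
  w <- c("com.google.android.youtube" = 0.5,
         "com.snapchat.android" = 0.3,
         "com.pinterest" = 0.15,
         "com.tinder" = 0.05)
  counts <- numeric(length(w))
  for (seed in 1:6) {
    cfg <- cohort_config(n_participants = 8, n_days = 3, seed = seed,
                         app_weights = w, repertoire_mean = 2,
                         repertoire_sd = 1, outage_rate = 0,
                         mean_daily_checks = 40, check_between_sd = 5,
                         check_within_sd = 5)
    co <- generate_cohort(cfg)
    counts <- counts + vapply(names(w), function(p) {
      length(unique(co$foreground$participant_id[
        co$foreground$package_name == p]))
    }, numeric(1))
  }
  # heavier apps reach more participants across seeds
  expect_true(counts[1] > counts[3])
  expect_true(counts[2] > counts[4])
  expect_equal(cor(counts, w, method = "spearman"), 1)
})
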