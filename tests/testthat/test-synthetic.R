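test_that("generation is deterministic given the config seed", {
  cfg <- cohort_config(n_participants = 3, n_days = 4, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a$foreground), as.data.frame(b$foreground))
  expect_identical(as.data.frame(a$aux), as.data.frame(b$aux))
  expect_identical(as.data.frame(a$truth$days), as.data.frame(b$truth$days))
  # and sensitive to the seed
  c2 <- generate_cohort(cohort_config(n_participants = 3, n_days = 4,
                                      seed = 8))
  expect_false(identical(as.data.frame(a$foreground),
                         as.data.frame(c2$foreground)))
})

test_that("a zero-usage cohort emits aux rows but no foreground events", {
  cfg <- cohort_config(n_participants = 2, n_days = 2, seed = 1,
                       mean_daily_minutes = 0, between_sd = 0,
                       within_sd = 0, mean_daily_checks = 0,
                       check_between_sd = 0, check_within_sd = 0,
                       outage_rate = 0)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$foreground), 0L)
  expect_gt(nrow(co$aux), 0L)
})

test_that("without outages every enrolled hour has full sensing coverage", {
  cfg <- cohort_config(n_participants = 1, n_days = 1, seed = 2,
                       outage_rate = 0)
  co <- generate_cohort(cfg)
  bins <- hour_bins(list(co$foreground, co$screen, co$aux),
                    enrollment = co$truth$enrollment)
  expect_equal(nrow(bins), 24L)
  expect_true(all(bins$valid_minutes == 60L))
})

test_that("generated days hit their duration and launch targets", {
  # fixed targets: 60 minutes across 12 launches, no variance components
  cfg <- cohort_config(n_participants = 1, n_days = 10, seed = 2,
                       mean_daily_minutes = 60, between_sd = 0,
                       within_sd = 0, mean_daily_checks = 12,
                       check_between_sd = 0, check_within_sd = 0,
                       outage_rate = 0)
  co <- generate_cohort(cfg)
  days <- as.data.frame(co$truth$days)
  expect_true(all(abs(days$realized_minutes - 60) <= 1))
  expect_true(all(days$realized_checks == 12L))
  # realized totals equal direct sums over the emitted event stream
  ep <- build_episodes(co$foreground, co$screen)
  by_day <- tapply(ep$duration,
                   as.Date(floor(ep$start / 86400000),
                           origin = "1970-01-01"), sum)
  expect_equal(sort(as.numeric(by_day)), sort(days$realized_minutes),
               tolerance = 1e-6)
})

test_that("pipeline-recovered daily sums equal generator ground truth", {
  cfg <- cohort_config(n_participants = 3, n_days = 6, seed = 3,
                       outage_rate = 0)
  co <- generate_cohort(cfg)
  ep <- build_episodes(co$foreground, co$screen)
  bins <- hour_bins(list(co$foreground, co$screen, co$aux),
                    enrollment = co$truth$enrollment)
  df <- daily_features(hourly_features(ep, co$foreground, bins, "all"))
  m <- merge(as.data.frame(df), as.data.frame(co$truth$days),
             by = c("participant_id", "date"))
  expect_equal(nrow(m), 18L)
  expect_true(all(abs(m$daily_sum - m$realized_minutes) < 0.1))
  expect_equal(m$daily_checks, m$realized_checks)
})

test_that("diurnal profile controls session start placement", {
  # zero weight overnight: no session may start in hours 0-6
  prof <- c(rep(0, 7), rep(1 / 17, 17))
  cfg <- cohort_config(n_participants = 2, n_days = 10, seed = 4,
                       diurnal_profile = prof, outage_rate = 0)
  co <- generate_cohort(cfg)
  start_hours <- (floor(co$foreground$timestamp / 3600000) %% 24)
  expect_true(all(start_hours >= 7))

  # flat profile, 24 ten-minute sessions/day: about one start per hour
  cfg2 <- cohort_config(n_participants = 1, n_days = 120, seed = 5,
                        diurnal_profile = rep(1 / 24, 24),
                        mean_daily_minutes = 240, between_sd = 0,
                        within_sd = 0, mean_daily_checks = 24,
                        check_between_sd = 0, check_within_sd = 0,
                        outage_rate = 0)
  co2 <- generate_cohort(cfg2)
  sh <- floor(co2$foreground$timestamp / 3600000) %% 24
  per_hour_per_day <- as.numeric(table(factor(sh, levels = 0:23))) / 120
  se <- sd(per_hour_per_day) / sqrt(24)
  expect_lt(abs(mean(per_hour_per_day) - 1), 3 * max(se, 1e-3))
  # every hour is populated under a flat profile
  expect_true(all(per_hour_per_day > 0))
})

test_that("sessions of one participant never overlap", {
  cfg <- cohort_config(n_participants = 3, n_days = 5, seed = 6,
                       outage_rate = 0)
  co <- generate_cohort(cfg)
  ep <- build_episodes(co$foreground, co$screen)
  for (p in unique(ep$participant_id)) {
    e <- ep[ep$participant_id == p, ][order(start)]
    expect_true(all(e$start[-1] >= e$end[-nrow(e)]))
  }
})

test_that("outage injection removes all rows inside outage windows", {
  cfg <- cohort_config(n_participants = 2, n_days = 3, seed = 9,
                       outage_rate = 0)
  co <- generate_cohort(cfg)
  logs <- list(foreground = co$foreground, screen = co$screen,
               aux = co$aux)
  # empty schedule: identity
  same <- inject_outages(logs, data.frame(participant_id = character(),
                                          start = numeric(),
                                          end = numeric()))
  expect_identical(as.data.frame(same$aux), as.data.frame(logs$aux))

  # outage covering one full hour: no rows survive in it, bin goes to 0
  day0 <- co$truth$enrollment$start[1]
  sch <- data.frame(participant_id = "P001", start = day0 + 10 * 3600000,
                    end = day0 + 11 * 3600000)
  cut <- inject_outages(logs, sch)
  for (tab in cut) {
    inside <- tab$participant_id == "P001" &
      tab$timestamp >= sch$start & tab$timestamp < sch$end
    expect_equal(sum(inside), 0L)
  }
  bins <- hour_bins(cut, enrollment = co$truth$enrollment)
  b <- bins[bins$participant_id == "P001" &
              bins$date == as.Date("2020-04-01") & bins$hour == 10, ]
  expect_equal(b$valid_minutes, 0L)

  # partial-hour outage (minutes 0-39) with no usage: downstream NA
  sch2 <- data.frame(participant_id = "P001",
                     start = day0 + 3 * 3600000,
                     end = day0 + 3 * 3600000 + 40 * 60000)
  cut2 <- inject_outages(logs, sch2)
  # strip any real usage from that hour so the rule sees usage = 0
  h3 <- function(x) x >= sch2$start & x < sch2$start + 3600000
  cut2$foreground <- cut2$foreground[!(cut2$foreground$participant_id ==
    "P001" & h3(cut2$foreground$timestamp))]
  ep <- build_episodes(cut2$foreground, cut2$screen)
  bins2 <- hour_bins(cut2, enrollment = co$truth$enrollment)
  hf <- hourly_features(ep, cut2$foreground, bins2, "all")
  cell <- hf[hf$participant_id == "P001" &
               hf$date == as.Date("2020-04-01") & hf$hour == 3, ]
  expect_equal(cell$valid_minutes, 20L)
  expect_equal(as.character(cell$status), "missing")
  expect_true(is.na(cell$value))

  # overlapping schedules are rejected
  bad <- data.frame(participant_id = "P001",
                    start = c(day0, day0 + 30 * 60000),
                    end = c(day0 + 3600000, day0 + 3600000))
  expect_error(inject_outages(logs, bad), "overlap")
})

test_that("generated outage schedules are disjoint and inside enrollment", {
  cfg <- cohort_config(n_participants = 5, n_days = 10, seed = 10)
  co <- generate_cohort(cfg)
  sch <- as.data.frame(co$truth$outages)
  expect_gt(nrow(sch), 0L)
  enr <- as.data.frame(co$truth$enrollment)
  for (p in unique(sch$participant_id)) {
    s <- sch[sch$participant_id == p, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1) expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
    e <- enr[enr$participant_id == p, ]
    expect_true(all(s$start >= e$start & s$end <= e$end))
  }
})

test_that("realized daily durations reproduce the configured variance split", {
  # between 30^2 / (30^2 + 24.4949^2) = 0.600; truncation negligible at
  # mean 120, so the empirical fraction should sit near 0.6
  cfg <- cohort_config(n_participants = 40, n_days = 60, seed = 12,
                       mean_daily_minutes = 120, between_sd = 30,
                       within_sd = 24.4949, mean_daily_checks = 5,
                       check_between_sd = 1, check_within_sd = 1,
                       outage_rate = 0)
  co <- generate_cohort(cfg)
  days <- as.data.frame(co$truth$days)
  fr <- icc_between_fraction(days$realized_minutes,
                             days$participant_id)$between_fraction
  # bootstrap participants for an honest SE of the fraction estimate
  set.seed(99)
  ids <- unique(days$participant_id)
  boot <- replicate(200, {
    take <- sample(ids, replace = TRUE)
    d <- do.call(rbind, lapply(seq_along(take), function(i) {
      s <- days[days$participant_id == take[i], ]
      s$participant_id <- paste0("b", i)
      s
    }))
    icc_between_fraction(d$realized_minutes,
                         d$participant_id)$between_fraction
  })
  expect_lt(abs(fr - co$truth$between_fraction_duration), 3 * sd(boot))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(cohort_config(n_participants = 0), "n_participants")
  expect_error(cohort_config(n_days = 2.5), "n_days")
  expect_error(cohort_config(between_sd = -1), "between_sd")
  expect_error(cohort_config(duration_check_cor = 1.5),
               "duration_check_cor")
  expect_error(cohort_config(app_weights = c(a = 0.5, b = 0.4)),
               "app_weights")
  expect_error(cohort_config(diurnal_profile = rep(1 / 23, 23)),
               "diurnal_profile")
  expect_error(cohort_config(aux_sensor_rows_per_min = 0.5),
               "aux_sensor_rows_per_min")
  expect_error(cohort_config(tz = "Not/AZone"), "timezone")
  expect_error(generate_cohort(list(n_participants = 2)), "cohort_config")
})

test_that("cohorts round-trip through the delimited log dialect", {
  cfg <- cohort_config(n_participants = 2, n_days = 2, seed = 14,
                       outage_rate = 0.3)
  co <- generate_cohort(cfg)
  dir <- tempfile()
  paths <- write_cohort(co, dir)
  logs <- read_sensor_tables(file.path(dir, c("foreground.csv",
                                              "screen.csv", "aux.csv")))
  expect_equal(as.data.frame(logs$foreground),
               as.data.frame(co$foreground[order(participant_id,
                                                 timestamp)]),
               tolerance = 1e-9)
  expect_equal(nrow(logs$aux), nrow(co$aux))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$between_fraction_duration,
               co$truth$between_fraction_duration)
  expect_equal(nrow(truth$days), nrow(co$truth$days))
})
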