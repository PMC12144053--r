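# Default app launch weights, proportional to the observed user counts of
# the most-used social apps in a one-month adolescent pilot cohort.
.default_app_weights <- function() {
  w <- c("com.google.android.youtube" = 18, "com.snapchat.android" = 16,
         "com.instagram.android" = 15, "com.discord" = 11,
         "com.zhiliaoapp.musically" = 11, "com.twitter.android" = 7,
         "com.facebook.katana" = 6, "com.reddit.frontpage" = 6,
         "tv.twitch.android.app" = 6, "com.popshow.yolo" = 5,
         "com.pinterest" = 4, "com.narvii.amino.master" = 2)
  w / sum(w)
}

# Diurnal launch-rate profile: near-silent overnight, evening peak.
.default_diurnal <- function() {
  w <- c(rep(0.15, 6),          # 00-05 overnight
         0.4, 0.8, 1.0,         # 06-08 morning
         rep(1.0, 6),           # 09-14 school hours
         rep(1.7, 6),           # 15-20 after school / evening peak
         1.2, 0.9, 0.4)         # 21-23 wind-down
  w / sum(w)
}

#' Configuration of a synthetic sensing cohort
#'
#' Parameters of the virtual cohort emulating a one-month adolescent
#' mobile-sensing deployment: 19 participants followed for 31 days, with a
#' sensor-outage schedule leaving roughly a quarter of enrolled time
#' unobserved (~74% data yield). The usage parameters describe the
#' *latent* usage process; what the pipeline observes is this process
#' filtered through outages and the valid-hour rule, which removes ~20% of
#' usage, adds day-level observation noise, and attenuates correlations.
#' The defaults are therefore deconvolved so that the *observed* cohort
#' reproduces the reference regime: observed broad-category daily duration
#' around 95 min/day (between-person SD near 60, between-person variance
#' fraction in the 0.5--0.65 band), observed daily checking around 150--160
#' events/day, and an observed within-person duration--checking correlation
#' near 0.5 (latent coupling 0.65). The derivation is laid out in the
#' methods vignette.
#'
#' Day-level realized targets are drawn normal and truncated at zero, so
#' the nominal variance fractions hold exactly only while the truncation
#' mass is negligible (means comfortably above the SDs). Session lengths
#' are log-normal, truncated at `session_cap` minutes. Each participant
#' draws an app repertoire (mean ~8 apps, SD ~3) with inclusion biased by
#' `app_weights`, and launches are multinomial over the repertoire.
#'
#' @param n_participants,n_days cohort dimensions (both >= 1).
#' @param seed integer root seed; per-participant child streams are derived
#'   from it, so generation is reproducible and participant-parallel.
#' @param start_date first enrollment date (local civil date).
#' @param tz IANA zone of all generated instants. The default (UTC) has no
#'   daylight-saving transitions, which keeps binning ground truth exact;
#'   calendar pathologies are exercised separately in ingest tests.
#' @param mean_daily_minutes,between_sd,within_sd grand mean and variance
#'   components of true daily usage duration (minutes/day).
#' @param mean_daily_checks,check_between_sd,check_within_sd the same for
#'   daily launch counts (events/day).
#' @param duration_check_cor within-person correlation between a day's
#'   duration deviation and checks deviation, in [-1, 1].
#' @param app_weights named nonnegative vector over package names, summing
#'   to 1: relative launch rates.
#' @param repertoire_mean,repertoire_sd size distribution of each
#'   participant's app repertoire.
#' @param diurnal_profile 24 nonnegative weights summing to 1: probability
#'   that a session starts in each local hour.
#' @param outage_rate expected sensor-outage episodes per participant-day.
#' @param outage_meanlog,outage_sdlog log-normal parameters of outage
#'   length in minutes.
#' @param aux_sensor_rows_per_min auxiliary sensor row rate (>= 1); rows
#'   are emitted on a regular per-minute lattice with sub-minute jitter, so
#'   with no outage every enrolled minute is a valid minute by construction.
#' @param session_meanlog,session_sdlog log-normal session-length
#'   parameters (minutes); `session_cap` truncates single sessions.
#' @return validated list of class `sm_cohort_config`.
#' @export
cohort_config <- function(n_participants = 19, n_days = 31, seed = 1L,
                          start_date = "2020-04-01", tz = "UTC",
                          mean_daily_minutes = 115, between_sd = 72,
                          within_sd = 38, mean_daily_checks = 220,
                          check_between_sd = 168, check_within_sd = 55,
                          duration_check_cor = 0.65,
                          app_weights = .default_app_weights(),
                          repertoire_mean = 8, repertoire_sd = 3,
                          diurnal_profile = .default_diurnal(),
                          outage_rate = 1.25,
                          outage_meanlog = log(240), outage_sdlog = 1,
                          aux_sensor_rows_per_min = 1,
                          session_meanlog = log(4), session_sdlog = 1,
                          session_cap = 120) {
  cfg <- as.list(environment())
  .fail <- function(field, msg) stop("invalid cohort config field '", field,
                                     "': ", msg, call. = FALSE)
  pos_int <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 ||
        v != floor(v)) .fail(field, "must be an integer >= 1")
  }
  nonneg <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      .fail(field, "must be a nonnegative number")
  }
  pos_int("n_participants"); pos_int("n_days")
  for (f in c("mean_daily_minutes", "between_sd", "within_sd",
              "mean_daily_checks", "check_between_sd", "check_within_sd",
              "outage_rate", "repertoire_sd")) nonneg(f)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    .fail("seed", "must be a single integer")
  if (abs(cfg$duration_check_cor) > 1)
    .fail("duration_check_cor", "must be in [-1, 1]")
  if (is.null(names(app_weights)) || any(app_weights < 0) ||
      abs(sum(app_weights) - 1) > 1e-9)
    .fail("app_weights", "must be a named nonnegative vector summing to 1")
  if (length(diurnal_profile) != 24L || any(diurnal_profile < 0) ||
      abs(sum(diurnal_profile) - 1) > 1e-9)
    .fail("diurnal_profile", "must be 24 nonnegative weights summing to 1")
  if (aux_sensor_rows_per_min < 1)
    .fail("aux_sensor_rows_per_min", "must be >= 1")
  if (cfg$session_cap <= 0) .fail("session_cap", "must be positive")
  if (cfg$repertoire_mean < 1) .fail("repertoire_mean", "must be >= 1")
  .check_tz(tz)
  tryCatch(as.Date(start_date),
           error = function(e) .fail("start_date", "not a date"))
  structure(cfg, class = "sm_cohort_config")
}

# gamma person means (right-skewed, positive), affine-standardized so the
# *realized* cohort carries exactly the configured mean and between-person
# SD: ground-truth recovery tests then measure pipeline fidelity, not the
# luck of a small person-level draw. Degenerate cases fall back to
# constants / truncated normals.
.draw_person_means <- function(n, m, s) {
  if (s == 0) return(rep(m, n))
  if (m <= 0) return(pmax(0, rnorm(n, m, s)))
  shape <- (m / s)^2
  mu <- stats::rgamma(n, shape = shape, rate = shape / m)
  if (n >= 3 && sd(mu) > 0) {
    mu <- m + (mu - mean(mu)) * s / sd(mu)
    mu <- pmax(mu, 0.01 * m)
  }
  mu
}

# child stream seed for participant i under root seed (kept below 2^31)
.child_seed <- function(seed, i) {
  (as.numeric(seed) * 7919 + i * 104729) %% 2147483647
}

#' Generate a synthetic multi-sensor cohort with known ground truth
#'
#' Produces AWARE-like sensor logs for a virtual cohort: a foreground
#' event table (one row per app launch), a screen event table (a screen-off
#' row closing each usage session), and an auxiliary sensor row table on a
#' per-minute lattice covering enrollment — except during sensor outages,
#' during which *no* rows of any kind are emitted (usage in an outage is
#' unobserved, emulating the sensing app being down). The returned truth
#' object records the per-participant true means, per-day targets and
#' realized (post-placement, pre-outage) totals, the app repertoires, the
#' outage schedule, and the variance fraction implied by the configuration,
#' enabling exact recovery tests of every downstream stage.
#'
#' Generation is deterministic given the config (which includes the seed).
#'
#' @param config an `sm_cohort_config` from [cohort_config()].
#' @return list of class `sm_cohort`: `foreground`, `screen`, `aux`
#'   data.tables (outages already removed), `truth` (class
#'   `sm_cohort_truth`), and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "sm_cohort_config"))
    stop("config must come from cohort_config()", call. = FALSE)
  cfg <- config
  n <- cfg$n_participants
  ids <- sprintf("P%03d", seq_len(n))
  day_starts <- as.numeric(as.POSIXct(paste(
    as.Date(cfg$start_date) + seq_len(cfg$n_days) - 1L, "00:00:00"),
    tz = cfg$tz)) * 1000
  enroll <- data.table(participant_id = ids,
                       start = day_starts[1L],
                       end = day_starts[cfg$n_days] + 86400000)

  # person-level truth under the root seed; person means are log-normal
  # (moment-matched) so the configured between-person variance is carried
  # exactly on positive support -- daily usage means are right-skewed
  set.seed(cfg$seed %% 2147483647)
  mu_dur <- .draw_person_means(n, cfg$mean_daily_minutes, cfg$between_sd)
  mu_chk <- .draw_person_means(n, cfg$mean_daily_checks,
                               cfg$check_between_sd)
  reps <- lapply(seq_len(n), function(i) {
    size <- max(1L, min(length(cfg$app_weights),
                        round(rnorm(1, cfg$repertoire_mean,
                                    cfg$repertoire_sd))))
    sample(names(cfg$app_weights), size, prob = cfg$app_weights)
  })

  fg_l <- vector("list", n); sc_l <- vector("list", n)
  aux_l <- vector("list", n); day_l <- vector("list", n)
  out_l <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(.child_seed(cfg$seed, i))
    pd <- .generate_participant(cfg, ids[i], mu_dur[i], mu_chk[i],
                                reps[[i]], day_starts)
    fg_l[[i]] <- pd$foreground; sc_l[[i]] <- pd$screen
    aux_l[[i]] <- pd$aux; day_l[[i]] <- pd$days
    out_l[[i]] <- pd$outages
  }
  fg <- data.table::rbindlist(fg_l)
  if (!ncol(fg)) fg <- data.table(participant_id = character(),
                                  timestamp = numeric(),
                                  package_name = character())
  sc <- data.table::rbindlist(sc_l)
  if (!ncol(sc)) sc <- data.table(participant_id = character(),
                                  timestamp = numeric(),
                                  state = character())
  aux <- data.table::rbindlist(aux_l)
  schedule <- data.table::rbindlist(out_l)

  logs <- inject_outages(list(foreground = fg, screen = sc, aux = aux),
                         schedule)

  truth <- structure(list(
    participants = data.table(participant_id = ids,
                              mean_daily_minutes = mu_dur,
                              mean_daily_checks = mu_chk,
                              n_apps = lengths(reps)),
    repertoires = stats::setNames(reps, ids),
    days = data.table::rbindlist(day_l),
    outages = schedule,
    enrollment = enroll,
    between_fraction_duration =
      cfg$between_sd^2 / (cfg$between_sd^2 + cfg$within_sd^2),
    between_fraction_checks =
      cfg$check_between_sd^2 /
        (cfg$check_between_sd^2 + cfg$check_within_sd^2)),
    class = "sm_cohort_truth")

  structure(list(foreground = logs$foreground, screen = logs$screen,
                 aux = logs$aux, truth = truth, config = cfg),
            class = "sm_cohort")
}

# one participant's full event stream (RNG already seeded by caller)
.generate_participant <- function(cfg, id, mu_d, mu_c, repertoire,
                                  day_starts) {
  nd <- cfg$n_days
  rho <- cfg$duration_check_cor
  z1 <- rnorm(nd); z2 <- rnorm(nd)
  tgt_min <- pmax(0, mu_d + cfg$within_sd * z1)
  tgt_chk <- pmax(0L, as.integer(round(
    mu_c + cfg$check_within_sd * (rho * z1 + sqrt(1 - rho^2) * z2))))
  tgt_min[tgt_chk == 0L] <- 0

  fg <- vector("list", nd); sc <- vector("list", nd)
  real_min <- numeric(nd); real_chk <- integer(nd)
  for (d in seq_len(nd)) {
    s <- generate_participant_day(cfg, tgt_min[d], tgt_chk[d])
    if (nrow(s)) {
      t0 <- day_starts[d]
      start_ms <- round(t0 + s$start_s * 1000)
      end_ms <- round(t0 + s$end_s * 1000)
      ok <- end_ms > start_ms   # sub-ms sessions vanish entirely
      start_ms <- start_ms[ok]; end_ms <- end_ms[ok]
      fg[[d]] <- data.table(participant_id = id,
                            timestamp = start_ms,
                            package_name = sample(repertoire,
                                                  length(start_ms),
                                                  replace = TRUE))
      sc[[d]] <- data.table(participant_id = id,
                            timestamp = end_ms,
                            state = "off")
      real_min[d] <- sum(end_ms - start_ms) / 60000
      real_chk[d] <- length(start_ms)
    }
  }

  # aux lattice: round(rate) rows per minute, jittered inside the spacing
  rate <- max(1L, as.integer(round(cfg$aux_sensor_rows_per_min)))
  spacing <- 60 / rate
  n_slots <- 1440L * rate
  aux <- data.table::rbindlist(lapply(seq_len(nd), function(d) {
    off <- (seq_len(n_slots) - 1L) * spacing +
      runif(n_slots, 0, spacing - 1e-2)
    data.table(participant_id = id,
               timestamp = round(day_starts[d] + off * 1000),
               sensor = "accelerometer")
  }))

  # outage schedule: Poisson count over enrollment, log-normal lengths,
  # overlapping draws dropped (keep earlier) so intervals are disjoint
  outages <- data.table(participant_id = character(), start = numeric(),
                        end = numeric())
  k <- rpois(1, cfg$outage_rate * nd)
  if (k > 0) {
    enr_start <- day_starts[1L]
    enr_end <- day_starts[nd] + 86400000
    st <- sort(runif(k, enr_start, enr_end))
    len <- rlnorm(k, cfg$outage_meanlog, cfg$outage_sdlog) * 60000
    en <- pmin(st + len, enr_end)
    keep <- logical(k); last_end <- -Inf
    for (j in seq_len(k)) {
      if (st[j] >= last_end) { keep[j] <- TRUE; last_end <- en[j] }
    }
    outages <- data.table(participant_id = id, start = st[keep],
                          end = en[keep])
  }

  fg_all <- data.table::rbindlist(fg)
  if (!ncol(fg_all)) fg_all <- data.table(participant_id = character(),
                                          timestamp = numeric(),
                                          package_name = character())
  sc_all <- data.table::rbindlist(sc)
  if (!ncol(sc_all)) sc_all <- data.table(participant_id = character(),
                                          timestamp = numeric(),
                                          state = character())
  list(foreground = fg_all,
       screen = sc_all,
       aux = aux,
       days = data.table(participant_id = id, day_index = seq_len(nd),
                         date = as.Date(cfg$start_date) + seq_len(nd) - 1L,
                         target_minutes = tgt_min, target_checks = tgt_chk,
                         realized_minutes = real_min,
                         realized_checks = real_chk),
       outages = outages)
}

#' Generate one participant-day of usage sessions
#'
#' Places `target_checks` sessions within a civil day so that session starts
#' follow the diurnal profile and total foreground time matches
#' `target_minutes` within rounding. Session lengths are log-normal
#' truncated at `session_cap` and rescaled to the day total; candidate
#' starts are sampled per-hour from the diurnal profile and laid out
#' left-to-right, pushing a session that would overlap its predecessor to
#' the predecessor's end (sessions of one participant never overlap: one
#' app is in the foreground at a time). Sessions running past midnight are
#' truncated at the day boundary.
#'
#' Uses the current RNG state; [generate_cohort()] seeds a per-participant
#' child stream before calling it.
#'
#' @param config `sm_cohort_config`.
#' @param target_minutes total foreground minutes for the day.
#' @param target_checks number of launches for the day.
#' @return data.table with `start_s`, `end_s` (seconds since local
#'   midnight), one row per session.
#' @export
generate_participant_day <- function(config, target_minutes,
                                     target_checks) {
  n <- as.integer(target_checks)
  if (n <= 0L || target_minutes <= 0) {
    return(data.table(start_s = numeric(), end_s = numeric()))
  }
  len <- pmin(rlnorm(n, config$session_meanlog, config$session_sdlog),
              config$session_cap)
  # rescale to the day target, re-truncating at the cap (a couple of
  # passes shares capped mass among uncapped sessions)
  for (it in 1:3) {
    s <- sum(len)
    if (s <= 0) break
    len <- pmin(len * target_minutes / s, config$session_cap)
  }
  hours <- sample.int(24L, n, replace = TRUE,
                      prob = config$diurnal_profile) - 1L
  starts <- sort(hours * 3600 + runif(n, 0, 3600))
  len_s <- len * 60  # pairing of lengths with starts is arbitrary
  cur <- 0
  out_s <- numeric(n); out_e <- numeric(n)
  for (j in seq_len(n)) {
    st <- max(starts[j], cur)
    en <- min(st + len_s[j], 86400)
    out_s[j] <- st; out_e[j] <- en
    cur <- en
  }
  keep <- out_e > out_s
  data.table(start_s = out_s[keep], end_s = out_e[keep])
}

#' Remove sensor rows falling inside outage intervals
#'
#' Deletes every row (foreground, screen, auxiliary) whose instant lies in
#' any of a participant's outage intervals `[start, end)`: while the
#' sensing app is down nothing is observed, including real usage.
#'
#' @param logs list with `foreground`, `screen`, `aux` tables (each with
#'   `participant_id`, `timestamp`).
#' @param schedule data.frame `participant_id`, `start`, `end` (epoch ms);
#'   intervals of one participant must not overlap.
#' @return the logs list with in-outage rows removed.
#' @export
inject_outages <- function(logs, schedule) {
  sch <- as.data.table(schedule)
  if (!nrow(sch)) return(logs)
  data.table::setorder(sch, participant_id, start)
  overlap <- sch[, any(start[-1L] < end[-.N]), by = participant_id]$V1
  if (any(overlap, na.rm = TRUE)) {
    stop("outage schedule has overlapping intervals", call. = FALSE)
  }
  drop_rows <- function(d) {
    d <- as.data.table(d)
    if (!nrow(d)) return(d)
    keep <- rep(TRUE, nrow(d))
    for (p in unique(sch$participant_id)) {
      iv <- sch[participant_id == p]
      rows <- which(d$participant_id == p)
      if (!length(rows)) next
      ts <- d$timestamp[rows]
      # interval index containing each instant, if any
      idx <- findInterval(ts, iv$start)
      inside <- idx >= 1L & ts < iv$end[pmax(idx, 1L)]
      keep[rows[inside]] <- FALSE
    }
    d[keep]
  }
  out <- lapply(logs, drop_rows)
  class(out) <- class(logs)
  out
}

#' Write a synthetic cohort to delimited sensor log files
#'
#' Serializes the cohort to the long event-log dialect read by
#' [read_sensor_tables()] (`participant_id,timestamp,sensor,payload`, epoch
#' ms), one file per sensor family, plus the ground truth as JSON.
#'
#' @param cohort `sm_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fg <- as.data.table(cohort$foreground)[
    , .(participant_id, timestamp = sprintf("%.0f", timestamp),
        sensor = "applications_foreground", payload = package_name)]
  sc <- as.data.table(cohort$screen)[
    , .(participant_id, timestamp = sprintf("%.0f", timestamp),
        sensor = "screen", payload = state)]
  ax <- as.data.table(cohort$aux)[
    , .(participant_id, timestamp = sprintf("%.0f", timestamp),
        sensor, payload = "")]
  paths <- file.path(dir, c("foreground.csv", "screen.csv", "aux.csv"))
  data.table::fwrite(fg, paths[1L])
  data.table::fwrite(sc, paths[2L])
  data.table::fwrite(ax, paths[3L])
  truth_path <- file.path(dir, "truth.json")
  tr <- cohort$truth
  jsonlite::write_json(list(
    participants = tr$participants, days = tr$days,
    outages = tr$outages, enrollment = tr$enrollment,
    repertoires = tr$repertoires,
    between_fraction_duration = tr$between_fraction_duration,
    between_fraction_checks = tr$between_fraction_checks),
    truth_path, digits = NA, auto_unbox = TRUE)
  invisible(c(paths, truth_path))
}

#' @export
print.sm_cohort <- function(x, ...) {
  cat(sprintf("Synthetic sensing cohort: %d participants x %d days (seed %s)\n",
              x$config$n_participants, x$config$n_days, x$config$seed))
  cat(sprintf("  foreground events: %d | screen events: %d | aux rows: %d | outages: %d\n",
              nrow(x$foreground), nrow(x$screen), nrow(x$aux),
              nrow(x$truth$outages)))
  invisible(x)
}
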