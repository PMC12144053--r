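#' Valid minutes in one participant-hour bin
#'
#' A valid minute is a clock-aligned one-minute window (hh:mm:00–hh:mm:59,
#' local civil time) in which at least one row from *any* phone sensor was
#' logged — evidence the sensing app was alive. This counts them for a
#' single bin; [hour_bins()] is the vectorized version used by the pipeline,
#' and the two agree by construction.
#'
#' @param sensor_rows data.frame pooling rows from all sensors
#'   (`participant_id`, `timestamp` epoch ms; other columns ignored).
#' @param participant participant id of the bin.
#' @param date local calendar date (`Date` or string) of the bin.
#' @param hour hour of day, 0–23.
#' @param tz IANA zone of the local civil time.
#' @return integer count in 0–60.
#' @export
valid_minutes <- function(sensor_rows, participant, date, hour, tz = "UTC") {
  .check_tz(tz)
  rows <- as.data.table(sensor_rows)[participant_id == participant]
  if (!nrow(rows)) return(0L)
  slot <- as.numeric(as.Date(date)) * 24 + as.integer(hour)
  ms <- rows$timestamp
  in_bin <- .local_hour_slot(ms, tz) == slot
  if (!any(in_bin)) return(0L)
  lm <- floor((ms[in_bin] + .offset_ms(ms[in_bin], tz)) / MS_PER_MIN)
  length(unique(lm))
}

#' Participant-hour bins with valid-minute counts and yield ratios
#'
#' Lays out the full grid of enrolled local-civil-time hours per participant
#' and counts valid minutes (minutes with at least one row from any sensor)
#' in each. The yield ratio of a bin is `valid_minutes / 60`.
#'
#' Enrollment defaults to `[first sensor row, last sensor row]` per
#' participant; pass `enrollment` to fix it externally (e.g. from a study
#' roster or generator ground truth), which keeps boundary hours stable when
#' rows near the edges are missing.
#'
#' @param logs an `sm_logs` list (or any list of data.frames each with
#'   `participant_id` and `timestamp`); all tables are pooled.
#' @param tz IANA zone for local binning.
#' @param enrollment optional data.frame `participant_id`, `start`, `end`
#'   (epoch ms); hours whose start lies in `[start, end)` are enrolled.
#' @return data.table `participant_id`, `date`, `hour`, `valid_minutes`,
#'   `yield_ratio`, classed `sm_bins`.
#' @export
hour_bins <- function(logs, tz = "UTC", enrollment = NULL) {
  .check_tz(tz)
  tabs <- if (inherits(logs, "sm_logs") || (is.list(logs) &&
                                            !is.data.frame(logs))) {
    logs
  } else list(logs)
  pooled <- data.table::rbindlist(
    lapply(tabs, function(d) as.data.table(d)[, .(participant_id, timestamp)]),
    use.names = TRUE)
  if (!nrow(pooled) && is.null(enrollment)) {
    stop("no sensor rows and no enrollment window", call. = FALSE)
  }
  if (is.null(enrollment)) {
    enrollment <- pooled[, .(start = min(timestamp), end = max(timestamp)),
                         by = participant_id]
  }
  enr <- as.data.table(enrollment)
  grid <- enr[, {
    s <- .local_hour_slot(start, tz)
    e <- .local_hour_slot(max(start, end - 1), tz)
    .(slot = seq(s, e))
  }, by = participant_id]

  if (nrow(pooled)) {
    mins <- unique(pooled[, .(participant_id,
                              minute = floor((timestamp +
                                .offset_ms(timestamp, tz)) / MS_PER_MIN))])
    counts <- mins[, .(valid_minutes = .N),
                   by = .(participant_id, slot = minute %/% 60)]
    grid <- merge(grid, counts, by = c("participant_id", "slot"),
                  all.x = TRUE)
  } else {
    grid[, valid_minutes := NA_integer_]
  }
  grid[is.na(valid_minutes), valid_minutes := 0L]
  f <- .slot_fields(grid$slot)
  grid[, `:=`(date = f$date, hour = f$hour)]
  grid[, yield_ratio := valid_minutes / 60]
  grid[, slot := NULL]
  data.table::setcolorder(grid, c("participant_id", "date", "hour",
                                  "valid_minutes", "yield_ratio"))
  data.table::setorder(grid, participant_id, date, hour)
  data.table::setattr(grid, "class", c("sm_bins", class(grid)))
  grid[]
}

#' Zero-versus-missing status of an hour's usage
#'
#' Distinguishes a true zero (no app use during a well-sensed hour) from
#' unobserved use (sensing was down). The rule: if any usage was captured in
#' the bin, the value is observed regardless of yield — captured data are
#' real data; otherwise, an hour with at least `min_valid_minutes` of
#' sensing coverage is a valid hour whose zero is taken at face value
#' (`zero_filled`); otherwise the bin is `missing` (NA). The default
#' threshold of 30 minutes is the 50%-of-hour convention; it is a
#' researcher-set dial and any choice introduces some bias, so it is exposed
#' as an argument.
#'
#' @param valid_minutes integer vector, 0–60 per bin.
#' @param usage captured usage per bin (minutes, or any nonnegative
#'   quantity; only zero/positive matters for the status).
#' @param min_valid_minutes validity threshold in minutes (default 30).
#' @return data.table with `status` (factor: observed, zero_filled, missing)
#'   and `value` (usage, 0, or NA respectively).
#' @export
apply_valid_hour_rule <- function(valid_minutes, usage,
                                  min_valid_minutes = 30) {
  if (any(is.na(usage)) || any(usage < 0)) {
    stop("usage must be nonnegative and non-missing", call. = FALSE)
  }
  if (length(valid_minutes) != length(usage)) {
    stop("valid_minutes and usage lengths differ", call. = FALSE)
  }
  status <- ifelse(usage > 0, "observed",
                   ifelse(valid_minutes >= min_valid_minutes,
                          "zero_filled", "missing"))
  value <- ifelse(status == "observed", usage,
                  ifelse(status == "zero_filled", 0, NA_real_))
  data.table(status = factor(status,
                             levels = c("observed", "zero_filled",
                                        "missing")),
             value = value)
}

#' Data-yield summary per participant and study-wide
#'
#' Mean yield ratio over each participant's enrolled hours, plus two study
#' aggregates: `study_pooled` weights every enrolled hour equally
#' (total valid minutes / total enrolled minutes) and
#' `study_participant_mean` averages the per-participant ratios. The two
#' differ under unequal enrollment; both are reported.
#'
#' @param bins an `sm_bins` table from [hour_bins()].
#' @return list of class `sm_yield`: `participants` (data.table
#'   `participant_id`, `enrolled_hours`, `valid_hours`, `yield_ratio`),
#'   `study_pooled`, `study_participant_mean`.
#' @export
yield_summary <- function(bins) {
  b <- as.data.table(bins)
  if (!nrow(b)) stop("no bins to summarize", call. = FALSE)
  per <- b[, .(enrolled_hours = .N,
               valid_hours = sum(valid_minutes >= 30),
               yield_ratio = mean(yield_ratio)), by = participant_id]
  structure(list(participants = per[],
                 study_pooled = sum(b$valid_minutes) / (60 * nrow(b)),
                 study_participant_mean = mean(per$yield_ratio)),
            class = "sm_yield")
}

#' @export
print.sm_yield <- function(x, ...) {
  cat(sprintf("Data yield: %.2f%% pooled over %d participants (range %.1f-%.1f%%; participant-mean %.2f%%)\n",
              100 * x$study_pooled, nrow(x$participants),
              100 * min(x$participants$yield_ratio),
              100 * max(x$participants$yield_ratio),
              100 * x$study_participant_mean))
  invisible(x)
}
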