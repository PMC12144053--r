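#' Read raw sensor event tables
#'
#' Reads one or more delimited sensor log files in the long event-log
#' dialect: UTF-8 CSV with header `participant_id,timestamp,sensor,payload`.
#' `timestamp` may be epoch milliseconds or ISO-8601 text (with or without a
#' zone designator; bare local strings are interpreted in `tz`, ambiguous
#' fall-back instants resolve to the earlier UTC offset). The `sensor` column
#' routes rows: `applications_foreground` rows become foreground launch
#' events (payload = package name), `screen` rows become screen state events
#' (payload in `on`, `off`, `lock`, `unlock`), anything else is kept as
#' auxiliary sensor rows that count toward valid minutes only.
#'
#' Exact duplicate rows (same participant, instant, sensor, payload) are
#' dropped with a message reporting the count. Events are returned sorted by
#' participant and instant.
#'
#' @param paths character vector of file paths.
#' @param tz IANA zone used to interpret bare local timestamps.
#' @return list of data.tables `foreground` (participant_id, timestamp,
#'   package_name), `screen` (participant_id, timestamp, state), `aux`
#'   (participant_id, timestamp, sensor), classed `sm_logs`.
#' @export
read_sensor_tables <- function(paths, tz = "UTC") {
  .check_tz(tz)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("file not found: ", paste(missing, collapse = ", "),
                            call. = FALSE)
  tabs <- lapply(paths, function(p) {
    d <- utils::read.csv(p, stringsAsFactors = FALSE,
                         colClasses = "character")
    expected <- c("participant_id", "timestamp", "sensor", "payload")
    unknown <- setdiff(names(d), expected)
    if (length(unknown)) {
      stop("unknown column(s) in ", p, ": ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (!all(expected %in% names(d))) {
      stop("missing column(s) in ", p, ": ",
           paste(setdiff(expected, names(d)), collapse = ", "),
           call. = FALSE)
    }
    d
  })
  raw <- data.table::rbindlist(tabs)
  if (!nrow(raw)) {
    raw <- data.table(participant_id = character(), timestamp = character(),
                      sensor = character(), payload = character())
  }
  raw[, timestamp := .parse_timestamp_ms(timestamp, tz)]
  n0 <- nrow(raw)
  raw <- unique(raw, by = c("participant_id", "timestamp", "sensor",
                            "payload"))
  dropped <- n0 - nrow(raw)
  if (dropped > 0) message("dropped ", dropped, " duplicate sensor row",
                           if (dropped > 1) "s")
  data.table::setorder(raw, participant_id, timestamp)

  fg <- raw[sensor == "applications_foreground",
            .(participant_id, timestamp, package_name = payload)]
  sc <- raw[sensor == "screen", .(participant_id, timestamp, state = payload)]
  bad <- setdiff(unique(sc$state), c("on", "off", "lock", "unlock"))
  if (length(bad)) stop("unknown screen state(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  aux <- raw[!sensor %in% c("applications_foreground", "screen"),
             .(participant_id, timestamp, sensor)]
  structure(list(foreground = fg, screen = sc, aux = aux),
            class = "sm_logs")
}

#' Reconstruct app usage episodes from foreground launch events
#'
#' The foreground sensor logs an event when an app comes to the foreground;
#' it does not log when use stops. Episode termination is therefore a
#' modelling rule, made explicit here: an episode opened by a launch event
#' ends at the earliest of (a) the participant's next foreground event,
#' (b) the next screen `off` or `lock` event (`unlock` does not reopen the
#' prior app), and (c) launch + `cap_minutes`. The cap keeps a final
#' unterminated event (screen left on, missing screen rows) from turning
#' into multi-hour phantom usage.
#'
#' Consecutive launches of the *same* package with no intervening screen-off
#' merge into a single episode for duration purposes (re-tapping an app you
#' are already in does not restart usage), but every launch event still
#' counts toward checking frequency downstream: duration comes from
#' episodes, checks from events. A screen-off coinciding exactly with the
#' next launch terminates the episode (no merge). All intervals are
#' half-open `[start, end)` in epoch ms, so durations are exactly additive
#' across bin boundaries. Zero-length episodes (two launches at the same
#' instant) are dropped from the episode table; the launches remain events.
#'
#' Episodes of one participant never overlap: only one app is in the
#' foreground at a time, and each episode is closed no later than the next
#' launch.
#'
#' @param foreground data.frame of launch events (`participant_id`,
#'   `timestamp` epoch ms, `package_name`).
#' @param screen optional data.frame of screen events (`participant_id`,
#'   `timestamp`, `state`).
#' @param cap_minutes maximum single-episode duration, minutes (default 120).
#' @return data.table with `participant_id`, `package_name`, `start`, `end`
#'   (epoch ms), `duration` (minutes), `n_events` (launches merged into the
#'   episode), classed `sm_episodes`.
#' @export
build_episodes <- function(foreground, screen = NULL, cap_minutes = 120) {
  if (!is.numeric(cap_minutes) || length(cap_minutes) != 1L ||
      is.na(cap_minutes) || cap_minutes <= 0) {
    stop("cap_minutes must be a positive number", call. = FALSE)
  }
  cap_ms <- cap_minutes * MS_PER_MIN
  fg <- as.data.table(foreground)
  empty <- data.table(participant_id = character(),
                      package_name = character(), start = numeric(),
                      end = numeric(), duration = numeric(),
                      n_events = integer())
  if (!nrow(fg)) {
    data.table::setattr(empty, "class", c("sm_episodes", class(empty)))
    return(empty)
  }
  fg <- fg[order(participant_id, timestamp)]
  offs <- if (!is.null(screen) && nrow(as.data.table(screen))) {
    sc <- as.data.table(screen)
    sc[state %in% c("off", "lock"), .(participant_id, timestamp)]
  } else {
    data.table(participant_id = character(), timestamp = numeric())
  }
  data.table::setorder(offs, participant_id, timestamp)

  out <- fg[, {
    t <- timestamp
    n <- length(t)
    po <- offs[participant_id == .BY$participant_id, timestamp]
    nxt <- c(t[-1L], Inf)
    # first screen-off strictly after each launch
    if (length(po)) {
      idx <- findInterval(t, po) + 1L
      off_t <- c(po, Inf)[pmin(idx, length(po) + 1L)]
    } else {
      off_t <- rep(Inf, n)
    }
    end_t <- pmin(nxt, off_t, t + cap_ms)
    # merge same-package runs bounded by the next launch with no screen-off
    same <- if (n > 1L) {
      c(FALSE, package_name[-n] == package_name[-1L] &
                 end_t[-n] == t[-1L] &
                 off_t[-n] > t[-1L])
    } else FALSE
    grp <- cumsum(!same)
    sizes <- tabulate(grp)
    data.table(package_name = package_name[!same],
               start = t[!same],
               end = end_t[cumsum(sizes)],
               n_events = as.integer(sizes))
  }, by = participant_id]
  # cap also applies to merged episodes
  out[, end := pmin(end, start + cap_ms)]
  out <- out[end > start]
  out[, duration := (end - start) / MS_PER_MIN]
  data.table::setcolorder(out, c("participant_id", "package_name", "start",
                                 "end", "duration", "n_events"))
  data.table::setattr(out, "class", c("sm_episodes", class(out)))
  out[]
}
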