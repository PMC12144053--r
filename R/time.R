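# Civil-time helpers. All event instants are carried internally as numeric
# epoch milliseconds (UTC); local binning converts through an IANA zone.

MS_PER_MIN  <- 60000
MS_PER_HOUR <- 3600000

.check_tz <- function(tz_name) {
  if (!is.character(tz_name) || length(tz_name) != 1L || is.na(tz_name) ||
      !nzchar(tz_name) || !(tz_name %in% OlsonNames()) && tz_name != "UTC") {
    stop("invalid IANA timezone name: ", deparse(tz_name), call. = FALSE)
  }
  invisible(tz_name)
}

# UTC offset (in ms) of `tz` at the start of each containing UTC hour.
# IANA offsets are whole minutes, so minute-aligned windows stay aligned.
.offset_ms <- function(ms, tz) {
  uh <- floor(ms / MS_PER_HOUR)
  u <- unique(uh)
  t <- as.POSIXct(u * 3600, origin = "1970-01-01", tz = "UTC")
  off <- as.POSIXlt(t, tz = tz)$gmtoff
  off[is.na(off)] <- 0
  off[match(uh, u)] * 1000
}

#' Convert event instants to local civil time
#'
#' Adds local calendar fields (`local_date`, `local_hour`, `local_minute`) to
#' an event table whose `timestamp` column holds epoch milliseconds. Epoch
#' instants are unambiguous, so daylight-saving folds and gaps cannot arise
#' here; they only matter when *parsing* wall-clock text (see
#' [read_sensor_tables()], which resolves ambiguous local strings to the
#' earlier UTC offset).
#'
#' @param events data.frame with a numeric `timestamp` column (epoch ms).
#' @param tz_name IANA zone name, e.g. `"America/New_York"`.
#' @return the table with `local_date` (Date), `local_hour` (0-23) and
#'   `local_minute` (0-59) columns appended.
#' @export
localize <- function(events, tz_name = "UTC") {
  .check_tz(tz_name)
  dt <- as.data.table(events)
  if (!nrow(dt)) {
    dt[, `:=`(local_date = as.Date(character()), local_hour = integer(),
              local_minute = integer())]
    return(dt[])
  }
  lm <- floor((dt$timestamp + .offset_ms(dt$timestamp, tz_name)) / MS_PER_MIN)
  dt[, local_date := as.Date(floor(lm / 1440), origin = "1970-01-01")]
  dt[, local_hour := as.integer((lm %/% 60) %% 24)]
  dt[, local_minute := as.integer(lm %% 60)]
  dt[]
}

# Inverse of the epoch->local mapping for a table produced by localize():
# the original `timestamp` column is untouched, so de-localizing is dropping
# the derived columns.
delocalize <- function(events) {
  dt <- as.data.table(events)
  for (col in c("local_date", "local_hour", "local_minute"))
    if (col %in% names(dt)) dt[, (col) := NULL]
  dt[]
}

# Absolute local-hour index (hours since epoch in local civil time).
.local_hour_slot <- function(ms, tz) {
  floor((ms + .offset_ms(ms, tz)) / MS_PER_HOUR)
}

# slot -> (date, hour) in local civil time
.slot_fields <- function(slot) {
  list(date = as.Date(floor(slot / 24), origin = "1970-01-01"),
       hour = as.integer(slot %% 24))
}

# Parse timestamps given either as epoch milliseconds or ISO-8601 text.
# Bare local ISO strings (no zone designator) are interpreted in `tz`;
# strings falling into a DST fold resolve to the earlier UTC offset
# (i.e. the first of the two wall-clock occurrences), strings inside a
# spring-forward gap are mapped to the instant at the gap's start.
.parse_timestamp_ms <- function(x, tz) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) return(num)

  iso_utc <- grepl("Z$|[+-][0-9]{2}:?[0-9]{2}$", x)
  out <- rep(NA_real_, length(x))
  if (any(iso_utc)) {
    t <- as.POSIXct(sub("Z$", "+0000", gsub("([+-][0-9]{2}):([0-9]{2})$",
                                            "\\1\\2", x[iso_utc])),
                    format = "%Y-%m-%dT%H:%M:%OS%z", tz = "UTC")
    out[iso_utc] <- as.numeric(t) * 1000
  }
  if (any(!iso_utc)) {
    s <- gsub("T", " ", x[!iso_utc], fixed = TRUE)
    t <- as.POSIXct(s, tz = tz, format = "%Y-%m-%d %H:%M:%OS")
    # DST fold: as.POSIXct with isdst unset picks one offset; force the
    # earlier offset (DST in the northern-hemisphere fall-back case) by
    # preferring the smaller epoch value of the two candidate parses.
    lt <- as.POSIXlt(s, tz = tz, format = "%Y-%m-%d %H:%M:%OS")
    lt$isdst <- 1L
    t_dst <- suppressWarnings(as.POSIXct(lt))
    pick <- !is.na(t_dst) &
      (is.na(t) | as.numeric(t_dst) < as.numeric(t))
    tt <- as.numeric(t)
    tt[pick] <- as.numeric(t_dst)[pick]
    out[!iso_utc] <- tt * 1000
  }
  bad <- which(is.na(out))
  if (length(bad)) {
    stop("unparseable timestamp at row ", bad[1L], ": ", x[bad[1L]],
         call. = FALSE)
  }
  out
}
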