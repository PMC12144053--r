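#' Summary block at a reporting grain
#'
#' Descriptive mean/SD/min/max/n of a usage feature at one of the three
#' conventional grains: `"hourly"` (all non-missing hourly cells, zeros
#' included — note this takes no account of hours participants were asleep,
#' a caveat of the hourly rows rather than a filter), `"daily"` (all
#' non-excluded person-days), or `"between_person"` (per-participant means
#' of the daily values, then summarized across participants).
#'
#' @param x an `sm_hourly` table (for `grain = "hourly"`) or `sm_daily`
#'   table (for `"daily"` / `"between_person"`).
#' @param grain one of `"between_person"`, `"daily"`, `"hourly"`.
#' @param feature `"duration"` or `"checks"`.
#' @return one-row data.frame: `grain`, `feature`, `scope`, `mean`, `sd`,
#'   `min`, `max`, `n`.
#' @export
summarize_usage <- function(x, grain = c("daily", "between_person",
                                         "hourly"),
                            feature = c("duration", "checks")) {
  grain <- match.arg(grain)
  feature <- match.arg(feature)
  d <- as.data.table(x)
  if (!nrow(d)) stop("empty feature table", call. = FALSE)
  vals <- if (grain == "hourly") {
    if (!"value" %in% names(d)) stop("hourly grain needs an sm_hourly table",
                                     call. = FALSE)
    v <- if (feature == "duration") d$value
         else ifelse(is.na(d$value), NA_real_, d$count_event)
    v[!is.na(v)]
  } else {
    if (!"daily_sum" %in% names(d)) stop("grain '", grain,
                                         "' needs an sm_daily table",
                                         call. = FALSE)
    dd <- d[excluded == FALSE]
    v <- if (feature == "duration") dd$daily_sum else dd$daily_checks
    if (grain == "between_person") {
      as.numeric(tapply(v, dd$participant_id, mean))
    } else v
  }
  if (!length(vals)) stop("no non-missing values at grain ", grain,
                          call. = FALSE)
  scope <- if ("scope" %in% names(d)) as.character(d$scope[1L]) else NA
  data.frame(grain = grain, feature = feature, scope = scope,
             mean = mean(vals), sd = sd(vals), min = min(vals),
             max = max(vals), n = length(vals))
}

#' Between/within-person variance decomposition (one-way random-effects ICC)
#'
#' Decomposes repeated daily measurements into a between-person and a
#' within-person variance component with the one-way random-effects ANOVA
#' estimator: `sigma2_within = MSW`, `sigma2_between = (MSB - MSW) / k_bar`
#' with the unbalanced-design group-size correction
#' `k_bar = (N - sum(n_i^2) / N) / (k - 1)`; a negative between estimate is
#' truncated at 0 (the standard convention). The between fraction
#' `sigma2_b / (sigma2_b + sigma2_w)` is ICC(1): the share of total variance
#' attributable to stable differences between participants.
#'
#' @param values numeric vector of daily measurements.
#' @param group participant identifier per value.
#' @return object of class `sm_icc`: list with `between_variance`,
#'   `within_variance`, `between_fraction`, `n_groups`, `n_obs`, `k_bar`.
#' @export
icc_between_fraction <- function(values, group) {
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]
  group <- as.character(group)[ok]
  k <- length(unique(group))
  N <- length(values)
  if (k < 2L) stop("need at least 2 participants", call. = FALSE)
  if (N <= k) stop("need repeated measurements within participants",
                   call. = FALSE)
  ni <- as.numeric(table(group))
  gm <- mean(values)
  mi <- tapply(values, group, mean)
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum((values - mi[group])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  k_bar <- (N - sum(ni^2) / N) / (k - 1)
  between <- max(0, (msb - msw) / k_bar)
  structure(list(between_variance = between, within_variance = msw,
                 between_fraction = between / (between + msw),
                 n_groups = k, n_obs = N, k_bar = k_bar),
            class = "sm_icc")
}

#' @export
print.sm_icc <- function(x, ...) {
  cat(sprintf("ICC(1) between-person fraction = %.3f (between var %.2f, within var %.2f; %d participants, %d observations)\n",
              x$between_fraction, x$between_variance, x$within_variance,
              x$n_groups, x$n_obs))
  invisible(x)
}

#' Repeated-measures (within-person) correlation
#'
#' The common within-person association between two repeatedly measured
#' variables after removing participant-level means: both variables are
#' centered within participant and the correlation is computed over the
#' centered values, `r = sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))`, with
#' `df = N - k - 1` (N complete pairs, k participants) and the p-value from
#' the usual t transform `t = r * sqrt(df / (1 - r^2))`. This is identical
#' to the ANCOVA common-slope formulation (partial correlation of y with x
#' adjusting for participant), and is invariant to adding arbitrary
#' per-participant constants to either variable.
#'
#' Pairs with a missing member are dropped; a participant with fewer than
#' two complete pairs (or zero within-person variance) contributes nothing
#' to the sums. If no participant carries within-person information the
#' correlation is undefined and an error is thrown.
#'
#' @param x,y numeric vectors of paired repeated measurements.
#' @param group participant identifier per pair.
#' @return object of class `sm_rmcorr`: list with `r`, `df`, `p`,
#'   `n_pairs`, `n_groups`.
#' @export
rm_correlation <- function(x, y, group) {
  ok <- !is.na(x) & !is.na(y) & !is.na(group)
  x <- x[ok]; y <- y[ok]; group <- as.character(group)[ok]
  keep <- names(which(table(group) >= 2L))
  use <- group %in% keep
  x <- x[use]; y <- y[use]; group <- group[use]
  N <- length(x)
  k <- length(unique(group))
  if (k < 2L) stop("need at least 2 participants with >= 2 complete pairs",
                   call. = FALSE)
  xc <- x - tapply(x, group, mean)[group]
  yc <- y - tapply(y, group, mean)[group]
  sxx <- sum(xc^2); syy <- sum(yc^2)
  if (sxx == 0 || syy == 0) {
    stop("no within-person variance; repeated-measures correlation undefined",
         call. = FALSE)
  }
  r <- sum(xc * yc) / sqrt(sxx * syy)
  df <- N - k - 1
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tval), df)
  structure(list(r = r, df = df, p = p, n_pairs = N, n_groups = k),
            class = "sm_rmcorr")
}

#' @export
print.sm_rmcorr <- function(x, ...) {
  cat(sprintf("repeated-measures r = %.3f (df = %d, p = %.3g; %d pairs, %d participants)\n",
              x$r, x$df, x$p, x$n_pairs, x$n_groups))
  invisible(x)
}

#' Within-person correlation of daily duration with daily checking
#'
#' Convenience wrapper applying [rm_correlation()] to a daily feature table:
#' the common within-person association between how long social media was
#' used on a day and how often it was checked.
#'
#' @param daily `sm_daily` table (one scope); excluded days are dropped.
#' @return `sm_rmcorr` object.
#' @export
duration_checks_correlation <- function(daily) {
  d <- as.data.table(daily)[excluded == FALSE]
  rm_correlation(d$daily_sum, d$daily_checks, d$participant_id)
}
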