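#' Diel component by span differencing
#'
#' Separates the daily periodic signal from the longer-term trend by fitting
#' two loess smooths to the same series: a small span that follows the daily
#' oscillation and a large span that only tracks the trend. The residual
#' (small-span fit minus large-span fit) is the diel component; by
#' construction `small-span fit = trend + residual` exactly on the grid.
#'
#' @param ts a [cyto_ts()] covering at least 3 days.
#' @param span_trend large span for the trend (default 0.3).
#' @param span_diel small span for the daily signal (default 0.05); must be
#'   smaller than `span_trend`.
#' @param degree polynomial degree for both fits (default 2).
#' @param step_h grid step (default 1 h).
#' @return data frame of class `cyto_diel`: `time`, `trend`, `fit_diel`,
#'   `residual` (= `fit_diel - trend`).
#' @export
diel_component <- function(ts, span_trend = 0.3, span_diel = 0.05,
                           degree = 2, step_h = 1) {
  if (!(span_diel < span_trend)) {
    stop("span_diel must be smaller than span_trend", call. = FALSE)
  }
  if (nrow(ts) < 4) stop("too few points for a diel decomposition", call. = FALSE)
  if (diff(range(as.numeric(ts$time))) < 3 * 86400) {
    stop("series must cover at least 3 days", call. = FALSE)
  }
  lo_d <- regularize(ts, span_diel, degree, step_h)
  lo_t <- regularize(ts, span_trend, degree, step_h)
  out <- data.frame(time = lo_d$time, trend = lo_t$value,
                    fit_diel = lo_d$value,
                    residual = lo_d$value - lo_t$value)
  out$is_source <- out$time %in% ts$time[!is.na(ts$value)]
  attr(out, "variable") <- ts_variable(ts)
  attr(out, "spans") <- c(diel = span_diel, trend = span_trend)
  class(out) <- c("cyto_diel", "data.frame")
  out
}

#' Hour-of-day profile (boxplot statistics)
#'
#' Groups a series by local hour-of-day over an analysis window and returns
#' the per-bin median, quartiles and count - the numbers behind an hourly
#' boxplot. By default the diel residual is profiled; set `use = "raw"` to
#' profile the values of a plain series instead.
#'
#' @param x a `cyto_diel` (residual profiled) or any data frame with `time`
#'   and `value` columns (`use = "raw"`).
#' @param window POSIXct `c(start, end)`; must span at least 2 full days.
#' @param tz_offset_h local-zone offset for the hour binning (default +1).
#' @param use `"residual"` or `"raw"`.
#' @param source_only for a `cyto_diel`, keep only grid hours backed by an
#'   actual observation (default `TRUE`): with 2-hourly sampling the
#'   in-between hours are loess interpolation, not data, and would distort
#'   the boxplot statistics.
#' @return data frame of class `cyto_dielprofile`, 24 rows: `hour`,
#'   `median`, `q1`, `q3`, `n`, `populated`.
#' @export
hourly_profile <- function(x, window = range(x$time), tz_offset_h = 1,
                           use = c("residual", "raw"), source_only = TRUE) {
  use <- match.arg(use)
  if (use == "residual" && source_only && "is_source" %in% names(x)) {
    x <- x[x$is_source, , drop = FALSE]
  }
  window <- as_utc(window)
  if (diff(as.numeric(window)) < 2 * 86400) {
    stop("profile window must span at least 2 full days", call. = FALSE)
  }
  val <- if (use == "residual") {
    if (!"residual" %in% names(x)) stop("`x` has no residual column; use = 'raw'?", call. = FALSE)
    x$residual
  } else x$value
  sel <- x$time >= window[1] & x$time <= window[2] & !is.na(val)
  hr <- floor(local_hour(x$time[sel], tz_offset_h)) %% 24
  v <- val[sel]
  out <- data.frame(hour = 0:23, median = NA_real_, q1 = NA_real_,
                    q3 = NA_real_, n = 0L, populated = FALSE)
  for (h in 0:23) {
    vi <- v[hr == h]
    if (length(vi) == 0) next
    qs <- stats::quantile(vi, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    out[h + 1, c("median", "q1", "q3")] <- qs[c(2, 1, 3)]
    out$n[h + 1] <- length(vi)
    out$populated[h + 1] <- TRUE
  }
  attr(out, "window") <- window
  attr(out, "tz_offset_h") <- tz_offset_h
  class(out) <- c("cyto_dielprofile", "data.frame")
  out
}

#' Circular increase interval of an hourly profile
#'
#' The longest circular run of populated hours with a positive
#' median-to-next-median difference, returned as `(start_hour, end_hour)`
#' where `end_hour` is the hour after the last positive step (wrap-around
#' allowed). A profile that increases through the whole cycle is degenerate:
#' `(0, 0)` with attribute `degenerate = TRUE`. With 2-hourly sampling only
#' even bins are populated; endpoints snap to populated hours.
#'
#' @param profile a `cyto_dielprofile` with >= 12 populated bins.
#' @return integer vector `c(start_hour, end_hour)`, possibly with
#'   attributes `degenerate` and `total_rise`.
#' @export
increase_interval <- function(profile) {
  pop <- profile[profile$populated, ]
  if (nrow(pop) < 12) stop("need >= 12 populated hour bins", call. = FALSE)
  hrs <- pop$hour
  med <- pop$median
  k <- length(hrs)
  d <- med[c(2:k, 1)] - med  # circular step to the next populated hour
  pos <- d > 0
  if (sum(pos) >= k - 1) {
    # rising through (essentially) the whole cycle: no meaningful interval
    out <- c(start_hour = 0L, end_hour = 0L)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  if (!any(pos)) {
    out <- c(start_hour = NA_integer_, end_hour = NA_integer_)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  # runs of TRUE on a circle: unwrap by doubling
  pos2 <- c(pos, pos)
  best_len <- 0; best_rise <- -Inf; best_start <- NA_integer_
  i <- 1
  while (i <= k) {
    if (pos2[i]) {
      j <- i
      while (j < i + k && pos2[j + 1]) j <- j + 1
      len <- j - i + 1
      rise <- sum(d[((i:j - 1) %% k) + 1])
      if (len > best_len || (len == best_len && rise > best_rise)) {
        best_len <- len; best_rise <- rise; best_start <- i
      }
      i <- j + 1
    } else i <- i + 1
  }
  start_hour <- hrs[best_start]
  end_hour <- hrs[((best_start + best_len - 1) %% k) + 1]
  out <- c(start_hour = as.integer(start_hour), end_hour = as.integer(end_hour))
  attr(out, "total_rise") <- best_rise
  out
}

#' Peak hour of an hourly profile
#'
#' @param profile a `cyto_dielprofile` with >= 12 populated bins.
#' @return hour of the maximum median; ties resolve to the earliest hour and
#'   set attribute `tie = TRUE`.
#' @export
peak_hour <- function(profile) {
  pop <- profile[profile$populated, ]
  if (nrow(pop) < 12) stop("need >= 12 populated hour bins", call. = FALSE)
  mx <- max(pop$median)
  at <- pop$hour[pop$median == mx]
  out <- as.integer(at[1])
  if (length(at) > 1) attr(out, "tie") <- TRUE
  out
}

#' Division-hour estimate from an abundance diel profile
#'
#' With a symmetric division burst the diel abundance component rises from
#' its daily minimum to its daily maximum over an interval centred on the
#' division hour, so the circular midpoint of the rising arc (profile argmin
#' to argmax, going forward around the clock) estimates the division hour
#' regardless of synchrony. More robust than the midpoint of the
#' [increase_interval()] run, which reacts to single noisy bins.
#'
#' @param profile abundance `cyto_dielprofile`.
#' @return fractional hour in `[0, 24)` (`NA` for a flat profile).
#' @export
division_hour_estimate <- function(profile) {
  pop <- profile[profile$populated, ]
  if (nrow(pop) < 12) stop("need >= 12 populated hour bins", call. = FALSE)
  if (diff(range(pop$median)) == 0) return(NA_real_)
  hmin <- pop$hour[which.min(pop$median)]
  hmax <- pop$hour[which.max(pop$median)]
  (hmin + ((hmax - hmin) %% 24) / 2) %% 24
}

#' Circular difference in hours (shortest way around the clock)
#'
#' @param a,b hours (numeric, possibly fractional).
#' @return signed difference in `(-12, 12]`.
#' @export
circular_hour_diff <- function(a, b) {
  d <- (a - b) %% 24
  ifelse(d > 12, d - 24, d)
}
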