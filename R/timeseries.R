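#' Timestamped series container
#'
#' A `cyto_ts` is a plain data frame with columns `time` (POSIXct, UTC) and
#' `value` (numeric, `NA` allowed for missing/below-detection observations),
#' carrying the variable name and units as attributes. Timestamps must be
#' strictly increasing; irregular spacing is allowed.
#'
#' @param time POSIXct vector (coerced to UTC) or something `as.POSIXct()`
#'   understands.
#' @param value numeric vector, same length as `time`.
#' @param variable character scalar, e.g. `"NO3NO2_uM"` or a cluster name.
#' @param units character scalar, e.g. `"uM"`, `"cells_cm3"`, `"mV"`.
#' @return A data frame of class `cyto_ts`.
#' @export
cyto_ts <- function(time, value, variable = "value", units = "dimensionless") {
  time <- as_utc(time)
  value <- as.numeric(value)
  if (length(time) != length(value)) {
    stop("`time` and `value` must have the same length", call. = FALSE)
  }
  if (anyNA(time)) stop("timestamps must not be NA", call. = FALSE)
  if (length(time) > 1 && any(diff(as.numeric(time)) <= 0)) {
    dup <- format(time[c(FALSE, diff(as.numeric(time)) <= 0)], tz = "UTC")
    stop("timestamps must be strictly increasing; offending: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  if (any(is.infinite(value))) {
    stop("values must be finite or NA", call. = FALSE)
  }
  out <- data.frame(time = time, value = value)
  attr(out, "variable") <- as.character(variable)[1]
  attr(out, "units") <- as.character(units)[1]
  class(out) <- c("cyto_ts", "data.frame")
  out
}

#' @export
print.cyto_ts <- function(x, ...) {
  cat(sprintf("<cyto_ts> %s [%s], %d points, %s .. %s\n",
              ts_variable(x), ts_units(x), nrow(x),
              format(min(x$time), tz = "UTC"), format(max(x$time), tz = "UTC")))
  invisible(x)
}

#' @rdname cyto_ts
#' @param x a `cyto_ts`.
#' @export
ts_variable <- function(x) attr(x, "variable")

#' @rdname cyto_ts
#' @export
ts_units <- function(x) attr(x, "units")

as_utc <- function(time) {
  if (inherits(time, "POSIXct")) {
    attr(time, "tzone") <- "UTC"
    return(time)
  }
  as.POSIXct(time, tz = "UTC")
}

#' Hours elapsed since an origin
#'
#' @param time POSIXct vector.
#' @param origin POSIXct scalar.
#' @return numeric hours.
#' @keywords internal
hours_since <- function(time, origin) {
  as.numeric(difftime(as_utc(time), as_utc(origin), units = "hours"))
}

#' Local hour of day for timestamps stored in UTC
#'
#' Internal storage is UTC; diel statistics are computed in a configurable
#' local zone expressed as a fixed offset in hours (default +1, i.e. CET,
#' without daylight-saving transitions).
#'
#' @param time POSIXct vector (UTC).
#' @param tz_offset_h numeric, hours east of UTC.
#' @return numeric hour-of-day in `[0, 24)` (fractional hours preserved).
#' @export
local_hour <- function(time, tz_offset_h = 1) {
  time <- as_utc(time)
  secs <- as.numeric(time) %% 86400
  (secs / 3600 + tz_offset_h) %% 24
}

#' Restrict a series to a time window
#'
#' @param ts a `cyto_ts`.
#' @param start,end POSIXct window bounds (inclusive).
#' @return a `cyto_ts`.
#' @export
ts_window <- function(ts, start, end) {
  start <- as_utc(start); end <- as_utc(end)
  keep <- ts$time >= start & ts$time <= end
  cyto_ts(ts$time[keep], ts$value[keep], ts_variable(ts), ts_units(ts))
}
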