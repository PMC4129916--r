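#' @import data.table
NULL

iso_utc <- function(time) format(as_utc(time), "%Y-%m-%dT%H:%M:%S+0000")

parse_iso <- function(s) {
  out <- as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  if (anyNA(out)) stop("unparseable ISO-8601 timestamp(s): ",
                       paste(utils::head(s[is.na(out)], 3), collapse = ", "),
                       call. = FALSE)
  out
}

#' Write / read a listmode sample
#'
#' A sample is stored as a pair of files in `dir`: a long-format CSV
#' `events_<protocol>_<stamp>.csv` with columns `event_id`, `channel`,
#' `sample_index`, `value_mV` (comma separator, `.` decimal, UTF-8, header
#' row), and a JSON sidecar `meta_<protocol>_<stamp>.json` with the
#' acquisition metadata. Pulse values are digitized to 1 uV (3 decimals) at
#' generation, so the text round-trip is exact.
#'
#' @param sample a `listmode_sample` (see [synthesize_listmode()]).
#' @param dir output directory (created if missing).
#' @return `write_listmode()` returns the events file path invisibly;
#'   `read_listmode()` returns a `listmode_sample`.
#' @export
write_listmode <- function(sample, dir) {
  stopifnot(inherits(sample, "listmode_sample"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- sprintf("%s_%s", sample$meta$protocol_id, stamp_utc(sample$meta$timestamp))
  events_path <- file.path(dir, paste0("events_", stem, ".csv"))
  meta_path <- file.path(dir, paste0("meta_", stem, ".json"))
  meta <- sample$meta
  meta$timestamp <- iso_utc(meta$timestamp)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  data.table::fwrite(sample$events, events_path)
  invisible(events_path)
}

#' @rdname write_listmode
#' @param events_path path to an `events_*.csv` file; the metadata sidecar is
#'   located by name substitution.
#' @export
read_listmode <- function(events_path) {
  if (!file.exists(events_path)) stop("missing events file: ", events_path, call. = FALSE)
  meta_path <- sub("events_([^/]+)\\.csv$", "meta_\\1.json", events_path)
  if (identical(meta_path, events_path) || !file.exists(meta_path)) {
    stop("missing metadata sidecar for ", events_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  meta$timestamp <- parse_iso(meta$timestamp)
  for (f in c("trigger_level_mV", "flow_rate_mm3s", "duration_s",
              "volume_nominal_cm3", "volume_cm3")) {
    if (!is.null(meta[[f]])) meta[[f]] <- as.numeric(meta[[f]])
  }
  if (!is.null(meta$protocol_id)) meta$protocol_id <- as.integer(meta$protocol_id)
  ev <- data.table::fread(events_path, colClasses = list(
    character = "event_id", integer = "sample_index", numeric = "value_mV"))
  required <- c("event_id", "channel", "sample_index", "value_mV")
  if (!identical(names(ev), required)) {
    stop("events file must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  .validate_events(ev)
  structure(list(meta = meta, events = ev, labels = NULL),
            class = "listmode_sample")
}

# Schema checks shared by reader and constructor: five equal-length,
# non-negative, finite pulse sequences per event.
.validate_events <- function(ev) {
  if (nrow(ev) == 0) stop("events table is empty", call. = FALSE)
  bad <- ev[!is.finite(value_mV) | value_mV < 0, unique(event_id)]
  if (length(bad) > 0) {
    stop("negative or non-finite pulse values in event(s): ",
         paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
  }
  lens <- ev[, .N, by = .(event_id, channel)]
  bad_ch <- lens[, .(nch = .N, onelen = data.table::uniqueN(N)), by = event_id]
  wrong <- bad_ch[nch != 5L | onelen != 1L, event_id]
  if (length(wrong) > 0) {
    stop("event(s) with missing channels or mismatched channel lengths: ",
         paste(utils::head(wrong, 3), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read an environmental table into per-variable series
#'
#' Expects a long-format CSV with columns `timestamp` (ISO-8601 with offset),
#' `variable`, `value`, `units`. Within each variable, timestamps must be
#' strictly increasing. Values at or below the variable's detection limit
#' (nutrients: 0.05 uM for NO3+NO2 and silicate, 0.02 uM for phosphate) are
#' flagged missing (`NA`), with the number of censored points recorded in the
#' `n_below_detection` attribute of each series.
#'
#' @param path CSV path.
#' @param detection_limits named numeric vector of lower detection limits in
#'   the variable's units; defaults cover the nutrient variables.
#' @return named list of [cyto_ts()] (empty list, with a warning, for an
#'   empty table).
#' @export
read_env_table <- function(path,
                           detection_limits = c(NO3NO2_uM = 0.05,
                                                PO4_uM = 0.02,
                                                SiOH4_uM = 0.05)) {
  tab <- data.table::fread(path, colClasses = list(character = c("timestamp", "variable", "units")))
  if (nrow(tab) == 0) {
    warning("empty environmental table: ", path)
    return(list())
  }
  required <- c("timestamp", "variable", "value", "units")
  if (!all(required %in% names(tab))) {
    stop("environmental table must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (v in unique(tab$variable)) {
    sub <- tab[variable == v]
    tm <- parse_iso(sub$timestamp)
    if (any(diff(as.numeric(tm)) <= 0)) {
      dups <- format(tm[c(FALSE, diff(as.numeric(tm)) <= 0)], tz = "UTC")
      stop(sprintf("non-increasing timestamps for %s: %s", v,
                   paste(utils::head(dups, 5), collapse = ", ")), call. = FALSE)
    }
    val <- sub$value
    n_bd <- 0L
    lim <- if (length(detection_limits)) detection_limits[v] else NA_real_
    if (length(lim) == 1 && !is.na(lim)) {
      below <- !is.na(val) & val < lim
      n_bd <- sum(below)
      val[below] <- NA_real_
    }
    ts <- cyto_ts(tm, val, variable = v, units = sub$units[1])
    attr(ts, "detection_limit") <- if (!is.na(lim)) unname(lim) else NA_real_
    attr(ts, "n_below_detection") <- n_bd
    out[[v]] <- ts
  }
  out
}

#' Write forcing series as a long environmental table
#'
#' Inverse of [read_env_table()] (without detection-limit censoring).
#'
#' @param series named list of [cyto_ts()].
#' @param path output CSV path.
#' @export
write_env_table <- function(series, path) {
  tabs <- lapply(series, function(ts) {
    data.table::data.table(timestamp = iso_utc(ts$time),
                           variable = ts_variable(ts), value = ts$value,
                           units = ts_units(ts))
  })
  data.table::fwrite(data.table::rbindlist(tabs), path)
  invisible(path)
}

#' Read/write a regularized or cluster series CSV
#' @keywords internal
write_series_csv <- function(df, path) {
  out <- data.table::as.data.table(df)
  if ("time" %in% names(out)) out[, time := iso_utc(time)]
  data.table::fwrite(out, path)
  invisible(path)
}

#' @keywords internal
read_series_csv <- function(path) {
  out <- data.table::fread(path)
  if ("time" %in% names(out)) out[, time := parse_iso(time)]
  as.data.frame(out)
}

# --- instrument-native import hooks ----------------------------------------

.importers <- new.env(parent = emptyenv())

#' Import hooks for instrument-native listmode formats
#'
#' The package's native interchange format is the CSV + JSON pair of
#' [write_listmode()]. For instrument-native files (FCS, vendor listmode) an
#' importer can be registered at run time: a function taking a path and
#' returning a `listmode_sample`. None ships with the package.
#'
#' @param format format label, e.g. `"fcs"`.
#' @param fun importer `function(path) -> listmode_sample`.
#' @export
register_listmode_importer <- function(format, fun) {
  stopifnot(is.character(format), is.function(fun))
  assign(tolower(format), fun, envir = .importers)
  invisible(format)
}

#' @rdname register_listmode_importer
#' @param path file to import.
#' @export
import_listmode <- function(path, format = tools::file_ext(path)) {
  fun <- mget(tolower(format), envir = .importers,
              ifnotfound = list(NULL))[[1]]
  if (is.null(fun)) {
    stop("no importer registered for format '", format,
         "'; see register_listmode_importer()", call. = FALSE)
  }
  fun(path)
}
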