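#' Detect abundance pulses from loess slopes
#'
#' An onset is an hour where the smoothed slope crosses from non-positive to
#' positive (or the series start, if it begins rising), stays positive for at
#' least `persistence_h`, and is followed by a rise whose peak exceeds
#' `min_fold` times the onset value. The peak is the maximum between the
#' onset and the next onset (or series end); the pulse ends at the first
#' return below the onset value, or at the next onset.
#'
#' @param reg regular hourly series ([regularize()] output or any data frame
#'   with `time` and `value`).
#' @param slopes slope vector aligned with `reg` (default: finite differences
#'   of the values).
#' @param persistence_h hours the slope must remain positive (default 12).
#' @param min_fold minimum peak / onset ratio (default 1.5).
#' @return data frame: `onset`, `peak_time`, `end_time`, `peak_value`,
#'   `fold_change`, ordered in time (zero rows if none).
#' @export
detect_pulses <- function(reg, slopes = NULL, persistence_h = 12, min_fold = 1.5) {
  v <- reg$value
  tm <- reg$time
  step_h <- if (length(tm) > 1) as.numeric(difftime(tm[2], tm[1], units = "hours")) else 1
  m <- length(v)
  if (is.null(slopes)) slopes <- loess_slope_values(v, step_h)
  persistence <- max(1L, ceiling(persistence_h / step_h))
  if (m < persistence + 1) {
    warning("series shorter than the persistence window; no pulses detected")
    return(.empty_pulses())
  }
  pos <- slopes > 0
  crossing <- which(pos & c(TRUE, !pos[-m]))  # start counts if it begins rising
  keep <- vapply(crossing, function(i) {
    run <- pos[i:min(m, i + persistence - 1)]
    all(run)
  }, logical(1))
  cands <- crossing[keep]
  if (length(cands) == 0) return(.empty_pulses())
  out <- list()
  bounds <- c(cands[-1] - 1L, m)
  for (k in seq_along(cands)) {
    i0 <- cands[k]; i1 <- bounds[k]
    seg <- v[i0:i1]
    pk <- i0 + which.max(seg) - 1L
    fold <- v[pk] / v[i0]
    if (!is.finite(fold) || fold < min_fold) next
    after <- if (pk < i1) which(v[(pk + 1):i1] < v[i0]) else integer(0)
    iend <- if (length(after) > 0) pk + after[1] else i1
    out[[length(out) + 1]] <- data.frame(
      onset = tm[i0], peak_time = tm[pk], end_time = tm[iend],
      peak_value = v[pk], fold_change = fold)
  }
  if (length(out) == 0) return(.empty_pulses())
  do.call(rbind, out)
}

.empty_pulses <- function() {
  data.frame(onset = as.POSIXct(character(), tz = "UTC"),
             peak_time = as.POSIXct(character(), tz = "UTC"),
             end_time = as.POSIXct(character(), tz = "UTC"),
             peak_value = numeric(), fold_change = numeric())
}

#' Windowed cross-correlation with lag search
#'
#' Pearson correlation between the environmental series shifted back by each
#' candidate lag and the abundance series, over an analysis window that is
#' extended `lead_days` backwards to integrate the preceding environmental
#' conditions. Only non-negative lags are searched (the environment leads the
#' biology) unless `include_negative = TRUE`. The best lag maximizes r (not
#' |r|). Significance uses a one-sided Gaussian bound with a Bonferroni
#' correction for the number of lags searched,
#' `r* = qnorm(1 - 0.025 / n_lags) / sqrt(n)`; under serial correlation of
#' both series this is still anti-conservative and should be read as a
#' screening rule, not a test.
#'
#' @param env,abun regular series on the same hourly grid (data frames with
#'   `time`, `value`).
#' @param window POSIXct `c(start, end)` analysis window (applied to the
#'   abundance series).
#' @param lead_days days the window is extended backwards (default 1).
#' @param max_lag_days maximum lag searched (default 15).
#' @param include_negative also search negative lags.
#' @param min_n lags with fewer overlapping points are dropped (default 10).
#' @return a `cyto_ccf`: list with `lag_days`, `r`, `n`, `best_lag_days`,
#'   `best_r`, `n_best`, `significant`, `threshold`, plus the window and
#'   variable names.
#' @export
windowed_ccf <- function(env, abun, window, lead_days = 1, max_lag_days = 15,
                         include_negative = FALSE, min_n = 10) {
  step_h <- as.numeric(difftime(abun$time[2], abun$time[1], units = "hours"))
  if (!isTRUE(all.equal(step_h,
        as.numeric(difftime(env$time[2], env$time[1], units = "hours"))))) {
    stop("env and abun must share the same regular grid step", call. = FALSE)
  }
  window <- as_utc(window)
  w0 <- window[1] - lead_days * 86400
  w1 <- window[2]
  sel_t <- abun$time >= w0 & abun$time <= w1
  if (sum(sel_t) == 0) stop("empty analysis window", call. = FALSE)
  max_lag_steps <- floor(max_lag_days * 24 / step_h)
  lags <- if (include_negative) seq(-max_lag_steps, max_lag_steps) else 0:max_lag_steps
  env_idx <- match(as.numeric(abun$time), as.numeric(env$time))
  r <- rep(NA_real_, length(lags))
  n <- integer(length(lags))
  t_idx <- which(sel_t)
  for (j in seq_along(lags)) {
    k <- lags[j]
    src <- env_idx[t_idx] - k
    ok <- !is.na(src) & src >= 1 & src <= nrow(env)
    a <- abun$value[t_idx[ok]]
    e <- env$value[src[ok]]
    ok2 <- is.finite(a) & is.finite(e)
    n[j] <- sum(ok2)
    if (n[j] > min_n && stats::sd(a[ok2]) > 0 && stats::sd(e[ok2]) > 0) {
      r[j] <- stats::cor(e[ok2], a[ok2])
    }
  }
  valid <- !is.na(r)
  if (!any(valid)) stop("no lag had enough overlapping points", call. = FALSE)
  stopifnot(all(abs(r[valid]) <= 1 + 1e-12))
  best <- which(r == max(r[valid]))[1]
  n_lags <- sum(valid)
  threshold <- stats::qnorm(1 - 0.025 / n_lags) / sqrt(n[best])
  structure(list(
    env_variable = attr(env, "variable") %||% "env",
    abun_variable = attr(abun, "variable") %||% "abundance",
    window = window, lead_days = lead_days,
    lag_days = lags * step_h / 24, r = r, n = n,
    best_lag_days = lags[best] * step_h / 24, best_r = r[best],
    n_best = n[best], threshold = threshold,
    significant = r[best] > threshold), class = "cyto_ccf")
}

#' @export
print.cyto_ccf <- function(x, ...) {
  cat(sprintf("<cyto_ccf> %s vs %s: best r = %.2f at lag %.1f d (n = %d)%s\n",
              x$env_variable, x$abun_variable, x$best_r, x$best_lag_days,
              x$n_best, if (x$significant) " *" else " (ns)"))
  invisible(x)
}

#' Succession order of one pulse across clusters
#'
#' @param pulse_tables named list of [detect_pulses()] outputs, one per
#'   cluster.
#' @param index which pulse (1 = first) to order on.
#' @return list of character vectors: clusters sorted by onset, clusters
#'   with onsets in the same hour grouped together.
#' @export
succession_order <- function(pulse_tables, index = 1) {
  onsets <- vapply(pulse_tables, function(p) {
    if (nrow(p) >= index) as.numeric(p$onset[index]) else NA_real_
  }, numeric(1))
  onsets <- onsets[!is.na(onsets)]
  if (length(onsets) == 0) return(list())
  hours <- floor(onsets / 3600)
  ord <- order(hours)
  split(names(onsets)[ord], factor(hours[ord], levels = unique(hours[ord]))) |>
    unname()
}

#' Cross-correlation summary table
#'
#' Rows are clusters, columns environmental variables, cells `"r / lag_days"`
#' for significant associations and blank otherwise.
#'
#' @param env_series named list of regular environmental series.
#' @param abun_series named list of regular abundance series.
#' @param window analysis window (POSIXct `c(start, end)`).
#' @param ... passed to [windowed_ccf()].
#' @return data frame with one row per cluster.
#' @export
ccf_table <- function(env_series, abun_series, window, ...) {
  rows <- lapply(names(abun_series), function(cl) {
    cells <- vapply(names(env_series), function(ev) {
      res <- tryCatch(windowed_ccf(env_series[[ev]], abun_series[[cl]],
                                   window, ...),
                      error = function(e) NULL)
      if (is.null(res) || !res$significant) return("")
      sprintf("r = %.2f lag = %.1f", res$best_r, res$best_lag_days)
    }, character(1))
    cbind(data.frame(cluster = cl), as.data.frame(as.list(cells)))
  })
  do.call(rbind, rows)
}
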