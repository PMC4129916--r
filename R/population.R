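#' Diel division kernel
#'
#' Wrapped-Gaussian density in hour-of-day, centred on the division hour,
#' with width `(1 - synchrony) * 12` hours (floored at 0.5 h), evaluated on
#' the 24 integer hours and normalized to unit mean so that a day of growth
#' integrates to the same total regardless of synchrony.
#'
#' @param division_hour centre of the division burst (local hour, 0-23).
#' @param synchrony dividing-fraction concentration, 0-1.
#' @return numeric length-24 vector `K[h+1]` for local hours `h = 0..23`,
#'   mean exactly 1.
#' @export
diel_division_kernel <- function(division_hour, synchrony) {
  if (synchrony <= 0) return(rep(1, 24))  # no synchrony: division is uniform
  sigma <- max((1 - synchrony) * 12, 0.5)
  h <- 0:23
  d <- numeric(24)
  for (k in -3:3) d <- d + stats::dnorm(h - division_hour + 24 * k, 0, sigma)
  d / mean(d)
}

# Cumulative diel excess: running integral of (K - 1)/24 over local hours,
# centred to zero mean. The detrended log-abundance diel component is
# growth-rate * this curve; the log mean-FWS diel component is its negative
# (cells added by division are small).
.diel_cycle_curve <- function(division_hour, synchrony) {
  K <- diel_division_kernel(division_hour, synchrony)
  C <- cumsum(K - 1) / 24
  C - mean(C)
}

#' Simulate cluster population dynamics
#'
#' Integrates hourly abundance and mean per-cell forward-scatter series for
#' each cluster over the forcing period. Per-capita growth is
#' `nutrient_gain * nutrient(t - lag)` (day^-1) times the diel division
#' kernel; loss is constant; days whose mean wind speed exceeds the collapse
#' threshold end with a `(1 - wind_collapse_factor)` abundance collapse.
#' Mean FWS is the cluster's optical baseline times a diel size factor that
#' mirrors the division cycle with log-amplitude `fws_growth_rate` (day^-1
#' scale), so abundance and mean size are exactly anti-phased within the day.
#'
#' @param forcing named list of hourly [cyto_ts()] from [simulate_forcing()].
#' @param clusters list of [cluster_params()].
#' @param limiting_nutrient forcing variable name driving growth.
#' @param wind_threshold daily-mean wind (m/s) defining a collapse day.
#' @param tz_offset_h local-time offset used for the diel kernel.
#' @param seed unused placeholder for future stochastic dynamics; the
#'   integration itself is deterministic.
#' @return named list, one data frame per cluster with columns `time`,
#'   `abundance` (cells/cm3), `mean_fws` (a.u.), `size_factor`, `mu`
#'   (realized per-capita growth, day^-1).
#' @export
simulate_population <- function(forcing, clusters,
                                limiting_nutrient = "NO3NO2_uM",
                                wind_threshold = 5, tz_offset_h = 1,
                                seed = NULL) {
  nut <- forcing[[limiting_nutrient]]
  if (is.null(nut)) stop("forcing lacks the limiting nutrient series ",
                         limiting_nutrient, call. = FALSE)
  time <- nut$time
  nh <- length(time)
  hours <- hours_since(time, time[1])
  hod <- floor(local_hour(time, tz_offset_h)) %% 24
  wind <- forcing$wind_mps
  collapse_at <- integer(0)
  if (!is.null(wind)) {
    day <- as.Date(wind$time, tz = "UTC")
    daily <- tapply(wind$value, day, mean)
    windy <- names(daily)[daily > wind_threshold]
    # collapse applied at the last tick of each windy day
    collapse_at <- vapply(windy, function(d) {
      max(which(as.Date(time, tz = "UTC") == as.Date(d)))
    }, integer(1))
  }
  out <- list()
  for (cp in clusters) {
    K <- diel_division_kernel(cp$division_hour, cp$synchrony)
    C <- .diel_cycle_curve(cp$division_hour, cp$synchrony)
    lag_h <- round(cp$response_lag_days * 24)
    idx_lag <- pmax(seq_len(nh) - lag_h, 1)
    nut_lag <- nut$value[idx_lag]
    mu <- cp$nutrient_gain * nut_lag * K[hod + 1]
    logN <- numeric(nh)
    logN[1] <- log(cp$baseline_abundance)
    step <- (mu - cp$loss_rate) / 24
    for (i in seq_len(nh - 1)) {
      # growth accrued over (i, i+1] is booked at the arriving hour so the
      # abundance and size diel phases stay aligned
      logN[i + 1] <- logN[i] + step[i + 1]
      if (cp$wind_collapse_factor > 0 && (i + 1) %in% collapse_at) {
        logN[i + 1] <- logN[i + 1] + log(1 - cp$wind_collapse_factor)
      }
    }
    if (any(!is.finite(logN)) || any(!is.finite(exp(logN)))) {
      stop("non-finite abundance for cluster ", cp$name, call. = FALSE)
    }
    size_factor <- exp(-cp$fws_growth_rate * C[hod + 1])
    fws_base <- cluster_mean_fws(cp)
    out[[cp$name]] <- data.frame(
      time = time, abundance = exp(logN),
      mean_fws = fws_base * size_factor,
      size_factor = size_factor, mu = mu)
  }
  out
}

#' Expected mean per-cell total FWS of a cluster at its baseline size
#'
#' Lognormal amplitude mean times the expected trapezoid area factor
#' `(L - 1) / 2` of the raised-cosine pulse at the cluster's mean length.
#'
#' @param cp a [cluster_params()].
#' @return expected total-FWS descriptor value, a.u. (mV x samples).
#' @export
cluster_mean_fws <- function(cp) {
  mu_log <- cp$optics$log_mean_FWS * log(10)
  sd_log <- cp$optics$log_sd_FWS * log(10)
  exp(mu_log + sd_log^2 / 2) * (cp$optics$mean_length - 1) / 2
}
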