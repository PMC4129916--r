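#' Simulate environmental forcing series
#'
#' Builds one hourly series per scenario variable: baseline (constant or
#' linear ramp over the campaign) plus the sum of all event kernels plus
#' AR(1) noise. Overlapping events on the same variable are summed.
#' Concentration-like variables (nutrients, wind, precipitation, solar) are
#' clamped at zero after summation.
#'
#' @param config a [scenario_config()].
#' @return named list of hourly [cyto_ts()], one per variable in
#'   [forcing_variables()].
#' @export
simulate_forcing <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  time <- seq(config$start_time, config$end_time, by = 3600)
  nh <- length(time)
  frac <- if (nh > 1) (seq_len(nh) - 1) / (nh - 1) else 0
  out <- list()
  for (v in forcing_variables()) {
    base <- config$baselines[[v]]
    if (is.null(base)) base <- 0
    values <- if (length(base) == 2) base[1] + (base[2] - base[1]) * frac
              else rep(base, nh)
    for (ev in config$forcing_events) {
      if (ev$variable != v) next
      values <- values + .event_kernel(ev, time)
    }
    sd_v <- config$noise_sd[[v]]
    if (!is.null(sd_v) && is.finite(sd_v) && sd_v > 0) {
      noise <- local_seed(derive_seed(config$seed, match(v, forcing_variables())),
                          .ar1_noise(nh, config$noise_ar, sd_v))
      values <- values + noise
    }
    if (v %in% .nonneg_vars) values <- pmax(values, 0)
    out[[v]] <- cyto_ts(time, values, variable = v, units = .forcing_units[[v]])
  }
  out
}

# Kernel of one event evaluated on the hourly grid.
.event_kernel <- function(ev, time) {
  dt_h <- as.numeric(difftime(time, ev$onset, units = "hours"))
  k <- numeric(length(time))
  if (ev$shape == "impulse") {
    hit <- which.min(abs(dt_h))
    k[hit] <- ev$magnitude
  } else if (ev$shape == "decaying_pulse") {
    on <- dt_h >= 0
    k[on] <- ev$magnitude * exp(-dt_h[on] / ev$decay_h)
  } else if (ev$shape == "ramp") {
    on <- dt_h >= 0
    total <- max(dt_h)
    if (total > 0) k[on] <- ev$magnitude * dt_h[on] / total
  }
  k
}

# Stationary AR(1) noise with marginal sd `sd_marg`.
.ar1_noise <- function(n, phi, sd_marg) {
  innov_sd <- sd_marg * sqrt(1 - phi^2)
  x <- numeric(n)
  e <- stats::rnorm(n, 0, innov_sd)
  x[1] <- stats::rnorm(1, 0, sd_marg)
  for (i in seq_len(n)[-1]) x[i] <- phi * x[i - 1] + e[i]
  x
}
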