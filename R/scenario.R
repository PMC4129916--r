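#' Forcing event
#'
#' One environmental perturbation added to a baseline series. Shapes:
#' `"impulse"` (magnitude added at the single onset hour, e.g. daily rainfall),
#' `"decaying_pulse"` (step of `magnitude` at onset followed by exponential
#' decay with e-folding time `decay_h`), and `"ramp"` (linear growth from 0 at
#' onset to `magnitude` at the end of the scenario). Negative magnitudes are
#' allowed (e.g. temperature dips); concentration-like variables are clamped
#' at zero after summing all components.
#'
#' @param variable one of the scenario variable names (see
#'   [forcing_variables()]).
#' @param onset POSIXct (UTC) event onset.
#' @param magnitude event size in the variable's units.
#' @param shape `"impulse"`, `"decaying_pulse"` or `"ramp"`.
#' @param decay_h e-folding time in hours (required for `"decaying_pulse"`).
#' @return a `forcing_event` list.
#' @export
forcing_event <- function(variable, onset, magnitude,
                          shape = c("decaying_pulse", "impulse", "ramp"),
                          decay_h = NULL) {
  shape <- match.arg(shape)
  if (!variable %in% forcing_variables()) {
    stop("unknown forcing variable: ", variable, call. = FALSE)
  }
  if (!is.finite(magnitude)) stop("event magnitude must be finite", call. = FALSE)
  if (shape == "decaying_pulse") {
    if (is.null(decay_h) || !is.finite(decay_h) || decay_h <= 0) {
      stop("decaying_pulse requires decay_h > 0", call. = FALSE)
    }
  }
  structure(list(variable = variable, onset = as_utc(onset),
                 magnitude = magnitude, shape = shape, decay_h = decay_h),
            class = "forcing_event")
}

#' Scenario variable roster
#'
#' @return character vector of the environmental variables a scenario
#'   simulates.
#' @export
forcing_variables <- function() {
  c("NO3NO2_uM", "PO4_uM", "SiOH4_uM", "wind_mps", "precip_mm",
    "solar_Jcm2", "temp_C", "salinity")
}

.forcing_units <- c(
  NO3NO2_uM = "uM", PO4_uM = "uM", SiOH4_uM = "uM", wind_mps = "m_s",
  precip_mm = "mm", solar_Jcm2 = "J_cm2", temp_C = "degC",
  salinity = "dimensionless")

# variables that cannot go negative
.nonneg_vars <- c("NO3NO2_uM", "PO4_uM", "SiOH4_uM", "wind_mps",
                  "precip_mm", "solar_Jcm2")

#' Instrument acquisition protocol
#'
#' @param protocol_id integer protocol identifier (1 or 2 in the default
#'   two-protocol schedule).
#' @param trigger_channel channel the acquisition triggers on (default
#'   `"FLR"`, red fluorescence).
#' @param trigger_level_mV trigger threshold in mV (> 0).
#' @param flow_rate_mm3s sample flow rate in mm3/s (> 0).
#' @param duration_s acquisition duration in seconds (> 0).
#' @param volume_efficiency fraction of the nominal pumped volume actually
#'   analysed, in `(0, 1]`.
#' @param noise_event_rate sub-trigger junk particles per cm3 recorded in the
#'   listmode stream.
#' @return an `instrument_config` list.
#' @export
instrument_config <- function(protocol_id, trigger_channel = "FLR",
                              trigger_level_mV, flow_rate_mm3s, duration_s,
                              volume_efficiency = 1, noise_event_rate = 0) {
  stopifnot(trigger_level_mV > 0, flow_rate_mm3s > 0, duration_s > 0,
            volume_efficiency > 0, volume_efficiency <= 1,
            noise_event_rate >= 0)
  structure(list(protocol_id = as.integer(protocol_id),
                 trigger_channel = trigger_channel,
                 trigger_level_mV = trigger_level_mV,
                 flow_rate_mm3s = flow_rate_mm3s, duration_s = duration_s,
                 volume_efficiency = volume_efficiency,
                 noise_event_rate = noise_event_rate),
            class = "instrument_config")
}

#' Cluster population parameters
#'
#' Dynamics: per-capita growth is `nutrient_gain * nutrient(t - response_lag)`
#' (day^-1 per uM of the limiting nutrient), modulated over the day by a
#' wrapped-Gaussian division kernel centred on `division_hour` (local time)
#' with width `(1 - synchrony) * 12` hours and unit daily mean; losses are a
#' constant `loss_rate`. Days whose mean wind speed exceeds the collapse
#' threshold multiply abundance by `(1 - wind_collapse_factor)`. Mean per-cell
#' forward scatter follows the inverse of the division-accumulation cycle:
#' cells added around the division hour are small, so mean size is minimal at
#' the end of the division burst and maximal just before it.
#'
#' @param name cluster label.
#' @param baseline_abundance starting abundance, cells/cm3 (> 0).
#' @param nutrient_gain growth response, day^-1 per uM.
#' @param response_lag_days delay between nutrient availability and the
#'   growth response, days.
#' @param loss_rate day^-1.
#' @param wind_collapse_factor fractional abundance loss per wind-event day,
#'   in `[0, 1)`.
#' @param division_hour local hour-of-day (0-23) at the centre of the
#'   division burst.
#' @param synchrony dividing fraction per day, in `[0, 1]`; 0 disables the
#'   diel cycle.
#' @param fws_growth_rate day^-1 scale of the diel size cycle (log-size gained
#'   over the inter-division growth phase).
#' @param optics named list: per-channel `log_mean`/`log_sd` (log10 mV pulse
#'   amplitude) and `mean_length` (pulse length in sample points, >= 3).
#' @return a `cluster_params` list.
#' @export
cluster_params <- function(name, baseline_abundance, nutrient_gain,
                           response_lag_days, loss_rate,
                           wind_collapse_factor = 0, division_hour = 22,
                           synchrony = 0.5, fws_growth_rate = 0.5,
                           optics = NULL) {
  stopifnot(baseline_abundance > 0, loss_rate >= 0,
            synchrony >= 0, synchrony <= 1,
            wind_collapse_factor >= 0, wind_collapse_factor < 1,
            division_hour >= 0, division_hour < 24)
  if (is.null(optics)) optics <- .default_optics[[name]]
  if (is.null(optics)) stop("no optics given or known for cluster ", name,
                            call. = FALSE)
  if (any(unlist(optics[paste0("log_sd_", cyto_channels())]) <= 0)) {
    stop("optics log-sd must be positive", call. = FALSE)
  }
  if (optics$mean_length < 3) stop("mean pulse length must be >= 3", call. = FALSE)
  structure(list(name = name, baseline_abundance = baseline_abundance,
                 nutrient_gain = nutrient_gain,
                 response_lag_days = response_lag_days, loss_rate = loss_rate,
                 wind_collapse_factor = wind_collapse_factor,
                 division_hour = division_hour, synchrony = synchrony,
                 fws_growth_rate = fws_growth_rate, optics = optics),
            class = "cluster_params")
}

#' Optical channels recorded per particle
#' @return character vector, in storage order.
#' @export
cyto_channels <- function() c("FWS", "SWS", "FLO", "FLY", "FLR")

# Default optical signatures (log10 mV amplitudes). The small picophytoplankton
# clusters carry dim, narrowly distributed red fluorescence placed between the
# two acquisition trigger levels (7 and 10 mV), so the low-trigger protocol
# records them and the high-trigger protocol does not - the mechanism by which
# the two protocols target different size classes.
.make_optics <- function(fws, sws, flo, fly, flr, len, flr_sd = 0.15) {
  means <- c(FWS = fws, SWS = sws, FLO = flo, FLY = fly, FLR = flr)
  sds <- c(FWS = 0.15, SWS = 0.15, FLO = 0.15, FLY = 0.15, FLR = flr_sd)
  out <- c(as.list(stats::setNames(means, paste0("log_mean_", names(means)))),
           as.list(stats::setNames(sds, paste0("log_sd_", names(sds)))))
  out$mean_length <- len
  out
}

.default_optics <- list(
  PicoFLO            = .make_optics(1.00, 1.00, 2.20, 0.80, log10(8.3), 5, flr_sd = 0.02),
  Picoeukaryotes     = .make_optics(1.60, 1.20, 0.60, 0.60, log10(8.3), 5, flr_sd = 0.02),
  Nanophytoplankton  = .make_optics(2.60, 2.00, 0.90, 1.00, 2.60, 9),
  Microphytoplankton = .make_optics(3.60, 2.40, 1.20, 1.40, 3.40, 21),
  HighSWS            = .make_optics(2.30, 3.40, 0.80, 0.90, 2.10, 9),
  HighFLO            = .make_optics(2.80, 2.20, 3.10, 1.20, 2.70, 11),
  noise              = .make_optics(0.30, 0.30, 0.20, 0.20, 0.48, 3)
)

#' Scenario configuration
#'
#' Bundles the campaign schedule, environmental forcing, cluster dynamics and
#' instrument protocols for the synthetic generator.
#'
#' @param start_time,end_time POSIXct campaign bounds (UTC).
#' @param sample_interval_h hours between acquisition ticks (default 2).
#' @param gap_windows list of length-2 POSIXct vectors; ticks inside any
#'   window are skipped (instrument outage).
#' @param forcing_events list of [forcing_event()]s.
#' @param cluster_params list of [cluster_params()]s.
#' @param instruments list of [instrument_config()]s (one per protocol).
#' @param baselines named list per variable: either a number (constant) or
#'   `c(from, to)` (linear ramp over the campaign).
#' @param noise_sd named numeric, marginal sd of the AR(1) hourly noise added
#'   to each variable (0 disables).
#' @param noise_ar AR(1) coefficient of the forcing noise (default 0.9).
#' @param tz_offset_h local-time offset for diel processes (default +1).
#' @param wind_collapse_threshold daily-mean wind speed (m/s) above which a
#'   wind-collapse day is declared (default 5).
#' @param limiting_nutrient forcing variable driving growth (default
#'   `"NO3NO2_uM"`).
#' @param loss_ref_uM nutrient concentration at which growth balances loss;
#'   used by [default_scenario()] to derive per-cluster loss rates.
#' @param seed integer master seed for all generator randomness.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(start_time, end_time, sample_interval_h = 2,
                            gap_windows = list(), forcing_events = list(),
                            cluster_params = list(), instruments = list(),
                            baselines = default_baselines(),
                            noise_sd = default_noise_sd(), noise_ar = 0.9,
                            tz_offset_h = 1, wind_collapse_threshold = 5,
                            limiting_nutrient = "NO3NO2_uM",
                            loss_ref_uM = 0.25, seed = 1) {
  start_time <- as_utc(start_time); end_time <- as_utc(end_time)
  if (end_time <= start_time) stop("end_time must be after start_time", call. = FALSE)
  if (sample_interval_h <= 0) stop("sample_interval_h must be positive", call. = FALSE)
  for (gw in gap_windows) {
    gw <- as_utc(gw)
    if (length(gw) != 2 || gw[1] >= gw[2]) stop("each gap window must be c(start, end) with start < end", call. = FALSE)
    if (gw[1] < start_time || gw[2] > end_time) {
      stop("gap window outside the scenario range", call. = FALSE)
    }
  }
  for (ev in forcing_events) {
    if (ev$onset < start_time || ev$onset > end_time) {
      stop(sprintf("forcing event on %s (%s) rejected: outside scenario range",
                   ev$variable, format(ev$onset, tz = "UTC")), call. = FALSE)
    }
  }
  seed <- as.integer(seed)
  structure(list(start_time = start_time, end_time = end_time,
                 sample_interval_h = sample_interval_h,
                 gap_windows = lapply(gap_windows, as_utc),
                 forcing_events = forcing_events,
                 cluster_params = cluster_params, instruments = instruments,
                 baselines = baselines, noise_sd = noise_sd,
                 noise_ar = noise_ar, tz_offset_h = tz_offset_h,
                 wind_collapse_threshold = wind_collapse_threshold,
                 limiting_nutrient = limiting_nutrient,
                 loss_ref_uM = loss_ref_uM, seed = seed),
            class = "scenario_config")
}

#' @rdname scenario_config
#' @export
default_baselines <- function() {
  list(NO3NO2_uM = 0.05, PO4_uM = 0.02, SiOH4_uM = 0.4, wind_mps = 2.5,
       precip_mm = 0, solar_Jcm2 = c(600, 2086), temp_C = c(13.5, 15.85),
       salinity = 37.51)
}

#' @rdname scenario_config
#' @export
default_noise_sd <- function() {
  c(NO3NO2_uM = 0.01, PO4_uM = 0.002, SiOH4_uM = 0.02, wind_mps = 0.3,
    precip_mm = 0, solar_Jcm2 = 30, temp_C = 0.05, salinity = 0.05)
}

#' Study-styled default scenario
#'
#' A ~73-day late-winter campaign sampled every 2 h by two acquisition
#' protocols, with a 10-day instrument outage, nitrate pulses in mid-February
#' and early/mid March, phosphate and silicate pulses, wind and precipitation
#' events, and six optically separable phytoplankton clusters whose staggered
#' nutrient-response lags produce three ordered abundance pulses.
#'
#' @param abundance_scale multiplier on all baseline abundances (and on the
#'   instrument noise-event rate); below 1 produces a lighter desk-scale
#'   campaign with identical dynamics but poorer counting statistics. Scaled
#'   baselines are floored at 5 cells/cm3 so the rare clusters keep
#'   analyzable counting statistics; at scales below 1 the abundance ratios
#'   between clusters are therefore not preserved.
#' @param seed master seed.
#' @param noise logical; `FALSE` zeroes all forcing noise.
#' @return a `scenario_config`.
#' @export
default_scenario <- function(abundance_scale = 1, seed = 1, noise = TRUE) {
  d <- function(x) as.POSIXct(x, tz = "UTC")
  ev <- function(var, onset, mag, shape = "decaying_pulse", decay_h = 96) {
    forcing_event(var, d(onset), mag, shape, decay_h = decay_h)
  }
  events <- list(
    # nitrate: two major pulses (mid-February and 9 March) plus a moderate
    # late-February rise driving the middle abundance pulse
    ev("NO3NO2_uM", "2012-02-14 00:00", 2.26, decay_h = 72),
    ev("NO3NO2_uM", "2012-02-29 00:00", 0.90, decay_h = 72),
    ev("NO3NO2_uM", "2012-03-09 00:00", 1.10, decay_h = 72),
    # phosphate pulses trailing the nitrate pulses
    ev("PO4_uM", "2012-02-23 00:00", 0.07, decay_h = 72),
    ev("PO4_uM", "2012-03-27 00:00", 0.06, decay_h = 72),
    # silicate: early maximum and two pulses
    ev("SiOH4_uM", "2012-01-24 06:00", 2.27, decay_h = 120),
    ev("SiOH4_uM", "2012-02-14 00:00", 2.06, decay_h = 120),
    ev("SiOH4_uM", "2012-03-20 00:00", 1.39, decay_h = 120),
    # wind events (> 5 m/s daily mean)
    ev("wind_mps", "2012-01-29 00:00", 3.7, decay_h = 18),
    ev("wind_mps", "2012-02-10 00:00", 4.0, decay_h = 18),
    ev("wind_mps", "2012-03-08 00:00", 2.8, decay_h = 30),
    ev("wind_mps", "2012-03-09 00:00", 2.9, decay_h = 30),
    ev("wind_mps", "2012-03-19 00:00", 4.1, decay_h = 18),
    # precipitation impulses (day 7 and day 41)
    ev("precip_mm", "2012-01-31 00:00", 28.2, shape = "impulse"),
    ev("precip_mm", "2012-03-05 00:00", 16.1, shape = "impulse"),
    # temperature dips coupled to the nitrate pulses
    ev("temp_C", "2012-02-14 00:00", -0.5, decay_h = 72),
    ev("temp_C", "2012-03-08 00:00", -0.3, decay_h = 72)
  )
  gain <- c(PicoFLO = 0.35, Picoeukaryotes = 0.40, Nanophytoplankton = 0.38,
            Microphytoplankton = 0.42, HighSWS = 0.36, HighFLO = 0.38)
  lag <- c(PicoFLO = 2.2, Picoeukaryotes = 2.0, Nanophytoplankton = 2.4,
           Microphytoplankton = 1.0, HighSWS = 2.1, HighFLO = 2.3)
  base <- c(PicoFLO = 9583, Picoeukaryotes = 7875, Nanophytoplankton = 2260,
            Microphytoplankton = 20, HighSWS = 65, HighFLO = 226)
  divh <- c(PicoFLO = 1, Picoeukaryotes = 22, Nanophytoplankton = 12,
            Microphytoplankton = 15, HighSWS = 15, HighFLO = 9)
  loss_ref <- 0.25  # uM at which growth balances loss -> decline between pulses
  clusters <- lapply(names(gain), function(nm) {
    cluster_params(nm, baseline_abundance = max(base[[nm]] * abundance_scale, 5),
                   nutrient_gain = gain[[nm]],
                   response_lag_days = lag[[nm]],
                   loss_rate = gain[[nm]] * loss_ref,
                   wind_collapse_factor = 0.15,
                   division_hour = divh[[nm]], synchrony = 0.5,
                   fws_growth_rate = 0.5)
  })
  instruments <- list(
    instrument_config(1, trigger_level_mV = 7, flow_rate_mm3s = 4.5,
                      duration_s = 240, volume_efficiency = 0.35,
                      noise_event_rate = 100 * abundance_scale),
    instrument_config(2, trigger_level_mV = 10, flow_rate_mm3s = 9,
                      duration_s = 600, volume_efficiency = 0.98,
                      noise_event_rate = 100 * abundance_scale)
  )
  noise_sd <- default_noise_sd()
  if (!noise) noise_sd[] <- 0
  scenario_config(
    start_time = d("2012-01-24 00:00"), end_time = d("2012-04-06 00:00"),
    sample_interval_h = 2,
    gap_windows = list(c(d("2012-03-16 00:00"), d("2012-03-26 00:00"))),
    forcing_events = events, cluster_params = clusters,
    instruments = instruments, noise_sd = noise_sd,
    loss_ref_uM = loss_ref, seed = seed)
}
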