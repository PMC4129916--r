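# Shared fixture builders. Everything is generated in code; no stored data.

utc <- function(x) as.POSIXct(x, tz = "UTC")

zero_noise <- function() stats::setNames(rep(0, 8), forcing_variables())

# Minimal one-cluster scenario with flat nutrients at `nut` uM and no noise.
quiet_scenario <- function(start = "2012-02-01 00:00", days = 16, nut = 1,
                           gain = 0.4, loss = gain * nut, synchrony = 0.5,
                           division_hour = 22, lag_days = 2, baseline = 5000,
                           events = list(), seed = 1,
                           name = "Picoeukaryotes") {
  bl <- default_baselines()
  bl$NO3NO2_uM <- nut
  scenario_config(
    utc(start), utc(start) + days * 86400, baselines = bl,
    forcing_events = events,
    cluster_params = list(cluster_params(
      name, baseline_abundance = baseline, nutrient_gain = gain,
      response_lag_days = lag_days, loss_rate = loss, synchrony = synchrony,
      division_hour = division_hour, fws_growth_rate = 0.5)),
    noise_sd = zero_noise(), seed = seed)
}

# Population truth for a quiet scenario, subsampled at the 2-h schedule.
quiet_population <- function(cfg) {
  f <- simulate_forcing(cfg)
  pop <- simulate_population(f, cfg$cluster_params)
  list(forcing = f, pop = pop[[1]])
}

# Build a listmode sample directly from an events table (no digitization),
# for descriptor oracle tests.
raw_sample <- function(events, trigger_level = 7, protocol = 1,
                       timestamp = utc("2012-02-01 00:00")) {
  structure(list(
    meta = list(timestamp = timestamp, protocol_id = protocol,
                trigger_channel = "FLR", trigger_level_mV = trigger_level,
                flow_rate_mm3s = 9, duration_s = 600,
                volume_nominal_cm3 = 5.4, volume_cm3 = 5.4),
    events = data.table::as.data.table(events), labels = NULL),
    class = "listmode_sample")
}

# Long-format rows for one pulse on one channel.
pulse_rows <- function(id, channel, values) {
  data.table::data.table(event_id = id, channel = channel,
                         sample_index = seq_along(values),
                         value_mV = as.numeric(values))
}

# A full 5-channel event from one numeric vector per channel.
event_rows <- function(id, fws, sws = fws, flo = fws, fly = fws, flr = fws) {
  data.table::rbindlist(list(
    pulse_rows(id, "FWS", fws), pulse_rows(id, "SWS", sws),
    pulse_rows(id, "FLO", flo), pulse_rows(id, "FLY", fly),
    pulse_rows(id, "FLR", flr)))
}

raised_cosine <- function(A, L) A * sin(pi * (seq_len(L) - 1) / (L - 1))^2

default_state <- function(clusters = c("Picoeukaryotes"), abundance = 200,
                          size_factor = 1) {
  data.frame(cluster = clusters,
             abundance = rep_len(abundance, length(clusters)),
             size_factor = rep_len(size_factor, length(clusters)))
}

protocol2 <- function(noise_rate = 0) {
  instrument_config(2, trigger_level_mV = 10, flow_rate_mm3s = 9,
                    duration_s = 600, volume_efficiency = 1,
                    noise_event_rate = noise_rate)
}

protocol1 <- function(noise_rate = 0) {
  instrument_config(1, trigger_level_mV = 7, flow_rate_mm3s = 4.5,
                    duration_s = 240, volume_efficiency = 0.35,
                    noise_event_rate = noise_rate)
}

all_cluster_params <- function(scale = 1) default_scenario(scale)$cluster_params

iso_utc_for_test <- function(t) format(t, "%Y-%m-%dT%H:%M:%S+0000", tz = "UTC")

# Independent definitional loess oracle: weighted least squares solved from
# scratch with lm() at a single query point.
loess_oracle <- function(x, y, x0, span, degree) {
  n <- length(x)
  q <- ceiling(span * n)
  d <- abs(x - x0)
  dmax <- sort(d)[q]
  idx <- which(d <= dmax)
  w <- if (dmax == 0) rep(1, length(idx)) else (1 - (d[idx] / dmax)^3)^3
  keep <- w > 0
  yy <- y[idx][keep]; ww <- w[keep]
  fit <- if (degree == 0) stats::lm(yy ~ 1, weights = ww)
         else stats::lm(yy ~ poly(x[idx][keep] - x0, degree, raw = TRUE),
                        weights = ww)
  unname(stats::coef(fit)[1])
}
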