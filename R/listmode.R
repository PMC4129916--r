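#' Synthesize one listmode sample
#'
#' Draws a Poisson number of particles per cluster (`abundance x analysed
#' volume`), gives each particle a five-channel pulse shape - a raised-cosine
#' (`A * sin^2(pi * i / (L - 1))`, integer length `L >= 3`) whose per-channel
#' amplitude is lognormal around the cluster's optical signature, with the
#' forward-scatter amplitude scaled by the cluster's current diel size
#' factor - and appends sub-trigger instrument noise particles. The
#' acquisition trigger is not applied here: the recorded stream carries every
#' particle, and thresholding is a processing step ([apply_trigger()]).
#' Values are digitized to 1 uV.
#'
#' @param state data frame with columns `cluster`, `abundance` (cells/cm3)
#'   and `size_factor` (diel FWS multiplier, 1 = baseline), one row per
#'   cluster present in the water.
#' @param clusters list of [cluster_params()] supplying the optics.
#' @param instrument an [instrument_config()].
#' @param timestamp acquisition time (POSIXct UTC).
#' @param seed integer seed for this sample's draws.
#' @return a `listmode_sample`: list with `meta` (protocol, trigger, flow
#'   rate, duration, nominal and effective analysed volume, timestamp),
#'   `events` (long data.table: `event_id`, `channel`, `sample_index`,
#'   `value_mV`) and `labels` (data.table `event_id`, `cluster`; noise
#'   particles are labelled `"noise"`).
#' @export
synthesize_listmode <- function(state, clusters, instrument, timestamp, seed) {
  stopifnot(inherits(instrument, "instrument_config"))
  vol_nominal <- instrument$flow_rate_mm3s * instrument$duration_s / 1000
  vol <- vol_nominal * instrument$volume_efficiency
  if (!is.finite(vol) || vol <= 0) stop("zero analysed volume", call. = FALSE)
  optics <- stats::setNames(lapply(clusters, `[[`, "optics"),
                            vapply(clusters, `[[`, "", "name"))
  local_seed(seed, {
    lambda <- state$abundance * vol
    n_per <- stats::rpois(nrow(state), lambda)
    n_noise <- stats::rpois(1, instrument$noise_event_rate * vol)
    label <- c(rep(state$cluster, n_per), rep("noise", n_noise))
    sizef <- c(rep(state$size_factor, n_per), rep(1, n_noise))
    nev <- length(label)
    if (nev == 0) {
      events <- data.table::data.table(event_id = character(),
                                       channel = character(),
                                       sample_index = integer(),
                                       value_mV = numeric())
      labels <- data.table::data.table(event_id = character(),
                                       cluster = character())
    } else {
      opt_for <- function(field) {
        vapply(label, function(l) {
          o <- if (l == "noise") .default_optics$noise else optics[[l]]
          as.numeric(o[[field]])
        }, numeric(1), USE.NAMES = FALSE)
      }
      mean_len <- opt_for("mean_length")
      # odd lengths only: the raised-cosine peak then falls on a sample
      # point, so the maximum descriptor equals the drawn amplitude and the
      # acquisition trigger acts on the amplitude itself
      half <- round(stats::rnorm(nev, (mean_len - 1) / 2, 0.05 * mean_len))
      len <- 2L * pmax(1L, as.integer(half)) + 1L
      amps <- sapply(cyto_channels(), function(ch) {
        10^stats::rnorm(nev, opt_for(paste0("log_mean_", ch)),
                        opt_for(paste0("log_sd_", ch)))
      })
      amps <- matrix(amps, nrow = nev,
                     dimnames = list(NULL, cyto_channels()))
      amps[, "FWS"] <- amps[, "FWS"] * sizef
      ids <- sprintf("e%06d", seq_len(nev))
      ev_idx <- rep(seq_len(nev), times = len)
      sidx <- sequence(len)
      len_rep <- len[ev_idx]
      shape <- sin(pi * (sidx - 1) / (len_rep - 1))^2
      blocks <- lapply(cyto_channels(), function(ch) {
        data.table::data.table(
          event_id = ids[ev_idx], channel = ch, sample_index = sidx,
          value_mV = round(amps[ev_idx, ch] * shape, 3))
      })
      events <- data.table::rbindlist(blocks)
      data.table::setorder(events, event_id)  # stable: channel order kept
      labels <- data.table::data.table(event_id = ids, cluster = label)
    }
    structure(list(
      meta = list(timestamp = as_utc(timestamp),
                  protocol_id = instrument$protocol_id,
                  trigger_channel = instrument$trigger_channel,
                  trigger_level_mV = instrument$trigger_level_mV,
                  flow_rate_mm3s = instrument$flow_rate_mm3s,
                  duration_s = instrument$duration_s,
                  volume_nominal_cm3 = vol_nominal,
                  volume_cm3 = vol),
      events = events, labels = labels), class = "listmode_sample")
  })
}

#' Run a full synthetic campaign
#'
#' Simulates forcing and population dynamics, then writes one listmode sample
#' per acquisition protocol at every schedule tick outside the gap windows,
#' along with the truth tables needed for validation:
#' `samples/events_<protocol>_<stamp>.csv` + sidecars, `forcing.csv` (long
#' environmental table), `truth_abundance.csv` (hourly true abundance and
#' mean FWS per cluster), and `truth_labels.csv` (true cluster of every
#' recorded event). Byte-identical for a fixed scenario seed.
#'
#' @param config a [scenario_config()].
#' @param out_dir output directory; must be creatable/writable (checked
#'   before any simulation).
#' @return invisibly, a list with the tick times, file paths and the forcing
#'   and population objects.
#' @export
run_campaign <- function(config, out_dir) {
  stopifnot(inherits(config, "scenario_config"))
  dir.create(file.path(out_dir, "samples"), recursive = TRUE, showWarnings = FALSE)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ writeLines("x", probe); TRUE }, error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) stop("output path is not writable: ", out_dir, call. = FALSE)
  unlink(probe)

  forcing <- simulate_forcing(config)
  pop <- simulate_population(forcing, config$cluster_params,
                             limiting_nutrient = config$limiting_nutrient,
                             wind_threshold = config$wind_collapse_threshold,
                             tz_offset_h = config$tz_offset_h)
  ticks <- campaign_ticks(config)
  time_grid <- forcing[[1]]$time
  cluster_names <- vapply(config$cluster_params, `[[`, "", "name")

  write_env_table(forcing, file.path(out_dir, "forcing.csv"))
  truth <- data.table::rbindlist(lapply(cluster_names, function(nm) {
    data.table::data.table(timestamp = iso_utc(pop[[nm]]$time), cluster = nm,
                           abundance = pop[[nm]]$abundance,
                           mean_fws = pop[[nm]]$mean_fws)
  }))
  data.table::fwrite(truth, file.path(out_dir, "truth_abundance.csv"))

  label_acc <- vector("list", length(ticks) * length(config$instruments))
  k <- 0
  for (i in seq_along(ticks)) {
    ti <- match(as.numeric(ticks[i]), as.numeric(time_grid))
    if (is.na(ti)) stop("schedule tick off the hourly grid", call. = FALSE)
    state <- data.frame(
      cluster = cluster_names,
      abundance = vapply(cluster_names, function(nm) pop[[nm]]$abundance[ti], numeric(1)),
      size_factor = vapply(cluster_names, function(nm) pop[[nm]]$size_factor[ti], numeric(1)))
    for (instr in config$instruments) {
      smp <- synthesize_listmode(
        state, config$cluster_params, instr, ticks[i],
        seed = derive_seed(config$seed, i, instr$protocol_id))
      path <- write_listmode(smp, file.path(out_dir, "samples"))
      k <- k + 1
      label_acc[[k]] <- data.table::data.table(
        sample = basename(path), smp$labels)
    }
  }
  data.table::fwrite(data.table::rbindlist(label_acc),
                     file.path(out_dir, "truth_labels.csv"))
  manifest <- list(
    seed = config$seed,
    n_ticks = length(ticks),
    n_samples = length(ticks) * length(config$instruments),
    start = iso_utc(config$start_time), end = iso_utc(config$end_time),
    sample_interval_h = config$sample_interval_h,
    clusters = as.list(cluster_names))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(ticks = ticks, out_dir = out_dir, forcing = forcing,
                 population = pop))
}

#' Schedule ticks of a scenario (gap windows removed)
#'
#' @param config a [scenario_config()].
#' @return POSIXct vector of acquisition times.
#' @export
campaign_ticks <- function(config) {
  ticks <- seq(config$start_time, config$end_time,
               by = config$sample_interval_h * 3600)
  for (gw in config$gap_windows) {
    ticks <- ticks[ticks < gw[1] | ticks > gw[2]]
  }
  ticks
}

#' Hash of a campaign/results bundle
#'
#' MD5 over the sorted (relative path, file MD5) pairs of every file under
#' `dir`, excluding `manifest.json`. Two runs with the same scenario seed
#' must produce the same hash.
#'
#' @param dir bundle directory.
#' @return character scalar MD5.
#' @export
bundle_hash <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = FALSE))
  files <- files[!basename(files) %in% "manifest.json"]
  sums <- tools::md5sum(file.path(dir, files))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(files, unname(sums)), tmp)
  unname(tools::md5sum(tmp))
}
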