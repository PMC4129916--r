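#!/usr/bin/env Rscript
# Diel cycles during the abundance pulses: separate the daily periodic
# component from the trend by differencing a small-span and a large-span
# loess fit, build hour-of-day boxplot statistics for abundance and mean
# per-cell forward scatter, and extract the division-timing proxies
# (abundance increase interval, estimated division hour, FWS peak hour).
#
# Reads results/series/ and results/pulses.csv; writes results/diel_summary.csv.

library(cytocampaign)

files <- list.files("results/series", full.names = TRUE)
series <- lapply(files, cytocampaign:::read_series_csv)
names(series) <- sub("\\.csv$", "", basename(files))
pulses <- read.csv("results/pulses.csv")
pulses$onset <- as.POSIXct(pulses$onset, tz = "UTC")
pulses$end_time <- as.POSIXct(pulses$end_time, tz = "UTC")

# configured division hours, for comparison with the recovered estimates
configured <- c(PicoFLO = 1, Picoeukaryotes = 22, Nanophytoplankton = 12,
                Microphytoplankton = 15, HighSWS = 15, HighFLO = 9)

rows <- list()
for (nm in names(series)) {
  s <- series[[nm]]
  ab <- cyto_ts(s$time, s$abundance, nm, "cells_cm3")
  ok <- !is.na(s$mean_fws)
  fw <- cyto_ts(s$time[ok], s$mean_fws[ok], nm, "au")
  p <- pulses[pulses$cluster == nm, ]
  for (k in seq_len(min(nrow(p), 3))) {
    # profile the 8 days following the onset (the pulse and its tail)
    win <- c(p$onset[k], min(p$onset[k] + 8 * 86400, max(s$time)))
    if (diff(as.numeric(win)) < 2 * 86400) next
    res <- tryCatch({
      wa <- ts_window(ab, win[1] - 86400, win[2] + 86400)
      wf <- ts_window(fw, win[1] - 86400, win[2] + 86400)
      da <- diel_component(wa, 0.3, 0.05)
      df <- diel_component(wf, 0.3, 0.05)
      pa <- hourly_profile(da, win)
      pf <- hourly_profile(df, win)
      iv <- increase_interval(pa)
      data.frame(cluster = nm, pulse = k,
                 increase_start = iv[["start_hour"]],
                 increase_end = iv[["end_hour"]],
                 division_hour_est = division_hour_estimate(pa),
                 division_hour_true = configured[[nm]],
                 fws_peak_hour = peak_hour(pf))
    }, error = function(e) NULL)
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
}
out <- do.call(rbind, rows)
print(out, row.names = FALSE)
write.csv(out, "results/diel_summary.csv", row.names = FALSE)
message("Median |division-hour error|: ",
        stats::median(abs(circular_hour_diff(out$division_hour_est,
                                             out$division_hour_true))), " h")
message(paste("Note: at the 1% desk scale the per-sample mean-FWS and",
              "abundance noise of the rare clusters exceeds the diel",
              "amplitude, so these campaign-level estimates are noisy;",
              "recovery at realistic per-bin precision is established by",
              "the dedicated diel study in the test suite."))
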