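#!/usr/bin/env Rscript
# Lagged coupling between the environmental drivers and the cluster
# abundance series: windowed cross-correlation over each detected pulse,
# with the window opened one day early to integrate the preceding
# environmental conditions. Produces the summary matrix (clusters x
# variables, "r / lag" for significant associations).
#
# Reads results/campaign/forcing.csv, results/series/, results/pulses.csv;
# writes results/ccf_table.csv.

library(cytocampaign)

forcing <- read_env_table("results/campaign/forcing.csv",
                          detection_limits = NULL)
env_vars <- c("NO3NO2_uM", "PO4_uM", "SiOH4_uM", "wind_mps", "precip_mm",
              "solar_Jcm2", "temp_C")
env_reg <- lapply(forcing[env_vars], regularize, span = 0.3, degree = 2)

files <- list.files("results/series", full.names = TRUE)
series <- lapply(files, cytocampaign:::read_series_csv)
names(series) <- sub("\\.csv$", "", basename(files))
abun_reg <- lapply(names(series), function(nm) {
  s <- series[[nm]]
  regularize(cyto_ts(s$time, s$abundance, nm, "cells_cm3"), 0.3, 2)
})
names(abun_reg) <- names(series)

pulses <- read.csv("results/pulses.csv")
pulses$onset <- as.POSIXct(pulses$onset, tz = "UTC")
pulses$peak_time <- as.POSIXct(pulses$peak_time, tz = "UTC")

tables <- list()
for (k in sort(unique(ave(seq_len(nrow(pulses)), pulses$cluster,
                          FUN = seq_along)))[1:3]) {
  idx <- as.integer(ave(seq_len(nrow(pulses)), pulses$cluster,
                        FUN = seq_along)) == k
  if (!any(idx)) next
  win <- c(min(pulses$onset[idx]) - 86400, max(pulses$peak_time[idx]) + 2 * 86400)
  message(sprintf("Pulse %d window: %s .. %s", k,
                  format(win[1], "%b %d"), format(win[2], "%b %d")))
  tab <- ccf_table(env_reg, abun_reg, win, lead_days = 1, max_lag_days = 15)
  print(tab)
  tables[[k]] <- cbind(pulse = k, tab)
}
write.csv(do.call(rbind, tables), "results/ccf_table.csv", row.names = FALSE)
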