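#!/usr/bin/env Rscript
# Simulate the study-styled buoy campaign: 73 days (24 Jan - 6 Apr 2012),
# two acquisition protocols every 2 h, a 10-day instrument outage in
# mid-March, nutrient/wind/precipitation forcing and six phytoplankton
# clusters with synchronized division. Run at 1% of field abundances so the
# whole campaign stays desk-sized; the dynamics are unchanged.
#
# Writes results/campaign/ (listmode samples + truth tables + forcing).

library(cytocampaign)

out_dir <- "results/campaign"
scenario <- default_scenario(abundance_scale = 0.01, seed = 11)

message("Simulating campaign into ", out_dir, " ...")
t0 <- Sys.time()
camp <- run_campaign(scenario, out_dir)
message(sprintf("%d ticks x %d protocols in %.1f min",
                length(camp$ticks), length(scenario$instruments),
                as.numeric(Sys.time() - t0, units = "mins")))

# What did the forcing look like?
no3 <- camp$forcing$NO3NO2_uM
peaks <- which(diff(sign(diff(no3$value))) == -2) + 1
peaks <- peaks[no3$value[peaks] > 0.8]
message("Major nitrate maxima (uM): ",
        paste(sprintf("%.2f on %s", no3$value[peaks],
                      as.Date(no3$time[peaks], tz = "UTC")), collapse = "; "))
message("True abundance ranges (cells/cm3):")
for (nm in names(camp$population)) {
  rng <- range(camp$population[[nm]]$abundance)
  message(sprintf("  %-20s %8.1f .. %8.1f", nm, rng[1], rng[2]))
}
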