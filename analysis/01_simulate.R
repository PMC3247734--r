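#!/usr/bin/env Rscript
# Stage 1: simulate the monitoring campaign.
#
# Generates seven years of half-hourly monsoon weather (the span used for the
# climate regime summaries) and one focal year of stem-radius series for five
# trees, corrupts the stem record with realistic sensor artifacts (gaps,
# power-outage windows, spikes), and writes everything in the logger format
# the ingest stage reads, plus the generator's ground-truth increments.

library(dendrosri)

seed <- 1234L
out <- "results/simdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("simulating 7 years of half-hourly weather ...")
wx7 <- generate_weather(climate_config(), years = 7, start_year = 2002,
                        seed = seed)
write_logger(wx7, file.path(out, "weather.csv"))

message("simulating one focal year of stem series for 5 trees ...")
cfg <- stem_config()
wx1 <- wx7[as.Date(wx7$timestamp, tz = "UTC") <= as.Date("2002-12-31"), ]
sim <- generate_stem_series(cfg, wx1, seed = seed + 1L)
art <- inject_artifacts(sim$series, cfg, seed = seed + 2L)
write_logger(art$series, file.path(out, "stem.csv"))
write.csv(sim$truth, file.path(out, "ground_truth.csv"), row.names = FALSE)
write.csv(art$log, file.path(out, "artifact_log.csv"), row.names = FALSE)

message(sprintf("wrote %d weather rows, %d stem rows, %d artifacts -> %s",
                nrow(wx7), nrow(art$series), nrow(art$log), out))
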