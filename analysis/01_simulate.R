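#!/usr/bin/env Rscript
# Generate the synthetic study system: covariate fields, hourly GPS tracks
# for a mixed-age cohort of bulls with known musth bouts, and field
# sightings. Writes everything in the formats the ingestion code reads.

suppressPackageStartupMessages({library(optparse); library(musthmove)})
opt <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1),
  make_option("--outdir", type = "character", default = "results"))))

simdir <- file.path(opt$outdir, "sim")
dir.create(simdir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = opt$seed, n_individuals = 6,
                  ages = c(27, 31, 33, 39, 43, 47), n_days = 240)
stack <- make_environment(cfg)
sim <- simulate_tracks(cfg, stack)
obs <- simulate_observations(sim$truth, rate = cfg$sighting_rate,
                             one_signal_frac = cfg$one_signal_frac,
                             seed = opt$seed + 1)

write_fixes(sim$tracks, file.path(simdir, "fixes.csv"))
write.csv(obs, file.path(simdir, "observations.csv"), row.names = FALSE)
write.csv(sim$truth, file.path(simdir, "ground_truth.csv"), row.names = FALSE)
write_asc(stack$elevation, file.path(simdir, "elevation.asc"))
for (s in stack$ndvi) {
  write_asc(s$grid, file.path(simdir, sprintf("ndvi_%s.asc", s$start)))
}
write_geojson(stack$water, "LineString", file.path(simdir, "water.geojson"))
write_geojson(stack$protected, "Polygon", file.path(simdir, "protected.geojson"))

n_musth <- sum(sim$truth$state == "musth")
cat(sprintf("simulated %d bulls x %d days (%d musth days, %.1f%%), %d sightings\n",
            cfg$n_individuals, cfg$n_days, n_musth,
            100 * n_musth / nrow(sim$truth), nrow(obs)))
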