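#!/usr/bin/env Rscript
# Daily movement statistics (mean speed, 95% MCP, sinuosity) for every
# QC-included day, environmental covariates sampled per fix and averaged
# per day, ages, musth labels from the sightings, and pooled
# standardization of the model covariates.

suppressPackageStartupMessages({library(optparse); library(musthmove)})
opt <- parse_args(OptionParser(option_list = list(
  make_option("--outdir", type = "character", default = "results"))))

simdir <- file.path(opt$outdir, "sim")
tracks <- read_fixes(file.path(opt$outdir, "regular_fixes.csv"))
qc <- read.csv(file.path(opt$outdir, "day_qc.csv"))
qc$date <- as.Date(qc$date)
obs <- read_observations(file.path(simdir, "observations.csv"))
truth <- read.csv(file.path(simdir, "ground_truth.csv"))

# covariate stack back from disk
elev <- read_asc(file.path(simdir, "elevation.asc"))
ndvi_files <- list.files(simdir, "^ndvi_", full.names = TRUE)
ndvi <- lapply(ndvi_files, function(f) {
  list(start = as.Date(sub(".*ndvi_(.*)\\.asc$", "\\1", f)), grid = read_asc(f))
})
stack <- cov_stack(elev, ndvi,
                   water = read_geojson(file.path(simdir, "water.geojson")),
                   protected = read_geojson(file.path(simdir, "protected.geojson")))

met <- do.call(rbind, lapply(names(tracks), function(id) {
  m <- daily_metrics(tracks[[id]], qc[qc$id == id, ])
  cv <- daily_covariate_means(sample_covariates(tracks[[id]], stack))
  merge(m, cv, by = c("id", "date"))
}))

# age from the ground-truth roster; musth label from expanded observations
age0 <- tapply(truth$age_years, truth$id, function(a) a[1])
met$age <- as.numeric(age0[met$id])
labels <- suppressWarnings(expand_labels(obs))
met$label <- labels$label[match(paste(met$id, met$date),
                                paste(labels$id, labels$date))]
names(met)[names(met) == "dist_water_km"] <- "dist_water"

st <- standardize(met, c("ndvi", "slope", "vrm", "dist_water"),
                  age_col = "age")
write.csv(st$data, file.path(opt$outdir, "daily_metrics.csv"), row.names = FALSE)
write.csv(st$params, file.path(opt$outdir, "standardization.csv"),
          row.names = FALSE)

lab_days <- sum(!is.na(met$label))
cat(sprintf("%d analysable days, %d with state labels; speed %.2f-%.2f km/h\n",
            nrow(met), lab_days, min(met$mean_speed_kmh),
            max(met$mean_speed_kmh)))
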