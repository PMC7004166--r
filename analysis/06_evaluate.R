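#!/usr/bin/env Rscript
# Score the decoded musth days against the expanded field observations and
# against the simulator's ground truth.

suppressPackageStartupMessages({library(optparse); library(musthmove)})
opt <- parse_args(OptionParser(option_list = list(
  make_option("--outdir", type = "character", default = "results"))))

dec <- read.csv(file.path(opt$outdir, "musth_decode.csv"))
dec$date <- as.Date(dec$date)
obs <- read_observations(file.path(opt$outdir, "sim", "observations.csv"))
truth <- read.csv(file.path(opt$outdir, "sim", "ground_truth.csv"))
truth$date <- as.Date(truth$date)

labels <- suppressWarnings(expand_labels(obs))
cs <- confusion(dec, labels)

# ground-truth scoring over every decoded day (not only observation days)
gt <- truth[, c("id", "date", "state")]
gt$label <- ifelse(gt$state == "musth", "musth", "non_musth")
cs_truth <- confusion(dec, gt[, c("id", "date", "label")])

write.csv(cs$per_individual, file.path(opt$outdir, "evaluation_by_bull.csv"),
          row.names = FALSE)
jsonlite::write_json(
  list(observation_days = list(pooled = cs$pooled,
                               mean_individual = cs$mean_individual),
       ground_truth_days = list(pooled = cs_truth$pooled,
                                mean_individual = cs_truth$mean_individual)),
  file.path(opt$outdir, "evaluation.json"), auto_unbox = TRUE, digits = 6)

cat(sprintf("observation-day scoring: mean sens %.2f, mean spec %.2f (pooled %.2f/%.2f)\n",
            cs$mean_individual$sensitivity, cs$mean_individual$specificity,
            cs$pooled$sensitivity, cs$pooled$specificity))
cat(sprintf("ground-truth scoring:    mean sens %.2f, mean spec %.2f\n",
            cs_truth$mean_individual$sensitivity,
            cs_truth$mean_individual$specificity))
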