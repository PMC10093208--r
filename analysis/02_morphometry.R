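#!/usr/bin/env Rscript
# Step 2 — segment the first frame of every sequence and measure each
# mitochondrion: area, skeleton length, width, elongation factor, branch
# count and redox-state ratio; then summarize per cell with the
# fifty-mitochondria QC gate. Writes per-object and per-cell CSV tables.

suppressPackageStartupMessages({
  library(mitomorph)
  library(dplyr)
})

seed <- 42L
cfg <- acquisition_config(n_frames = 2)
n_cells <- 6L
effects <- list(
  control = list(),
  tau3R = list(`6h` = c(event_rate = 2.0),
               `24h` = c(redox_ratio = 1.5, length = 0.8)),
  tau4R = list(`6h` = c(event_rate = 1.5),
               `24h` = c(redox_ratio = 0.8))
)

features_all <- list()
records_all <- list()
for (g in names(effects)) {
  for (i in seq_len(n_cells)) {
    cell <- sprintf("%s_%02d", g, i)
    ser <- simulate_timepoint_series(
      cfg, field_params(), effect_spec = effects[[g]],
      seed = seed + 100L * match(g, names(effects)) + i,
      cell_id = cell, condition = g)
    for (tp in names(ser$stacks)) {
      res <- analyze_stack(ser$stacks[[tp]], dynamics = FALSE)
      res$features$condition <- g
      features_all[[length(features_all) + 1L]] <- res$features
      records_all[[length(records_all) + 1L]] <- res$cell_record
    }
  }
}
features <- bind_rows(features_all)
records <- bind_rows(records_all)

dir.create("results", showWarnings = FALSE)
write.csv(features, "results/mito_features.csv", row.names = FALSE)
write.csv(records, "results/cell_records.csv", row.names = FALSE)

message(sprintf(
  "measured %d mitochondria in %d cell-timepoints (%d cells QC-pass)",
  nrow(features), nrow(records), sum(records$qc_pass)))
records |>
  group_by(condition, timepoint) |>
  summarise(redox = mean(redox_ratio_mean),
            elongation = mean(elongation_mean), .groups = "drop") |>
  as.data.frame() |>
  print()
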