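#!/usr/bin/env Rscript
# Step 3 — mitochondrial dynamics: segment every frame of a 60-frame
# sequence per cell, link objects into tracks (Hungarian assignment under a
# 1 um gate), keep tracks spanning the whole sequence, and estimate the
# fusion/fission event rate from successive object counts. Smaller fields
# than step 02 keep the 60-frame runs quick. Writes tracks.csv and
# events.csv.

suppressPackageStartupMessages({
  library(mitomorph)
  library(dplyr)
})

seed <- 42L
cfg <- acquisition_config(n_frames = 60, image_shape = c(256, 256))
n_cells <- 3L
groups <- c(control = 0.001, tau3R = 0.002, tau4R = 0.0015)  # event rates

tracks_all <- list()
events_all <- list()
for (g in names(groups)) {
  for (i in seq_len(n_cells)) {
    cell <- sprintf("%s_%02d", g, i)
    # noise off: the count-difference event estimator stands in for manual
    # counting and is meant for clean counts; camera noise makes borderline
    # segmentations flicker and would inflate it (see methods vignette)
    sim <- simulate_field(
      cfg, field_params(n_mito = 12, event_rate = groups[[g]],
                        poisson_noise = FALSE, read_sd = 0,
                        quantize = FALSE),
      seed = seed + 10L * match(g, names(groups)) + i,
      cell_id = cell, condition = g)
    res <- analyze_stack(sim$stack, qc_min = 1)
    tr <- res$tracks
    tr$cell_id <- cell
    tr$condition <- g
    tracks_all[[cell]] <- tr
    ev <- res$event_estimate
    events_all[[cell]] <- tibble::tibble(
      cell_id = cell, condition = g,
      mean_count = ev$mean_count, n_events = ev$n_events,
      n_fusion_candidates = ev$n_fusion_candidates,
      n_fission_candidates = ev$n_fission_candidates,
      event_rate_per_particle = ev$event_rate_per_particle,
      n_full_tracks = nrow(res$track_summary),
      displacement_mean = mean(res$track_summary$displacement),
      speed_mean = mean(res$track_summary$speed),
      true_n_events = nrow(sim$truth$events))
  }
}

dir.create("results", showWarnings = FALSE)
write.csv(bind_rows(tracks_all), "results/tracks.csv", row.names = FALSE)
write.csv(bind_rows(events_all), "results/events.csv", row.names = FALSE)

ev <- bind_rows(events_all)
message(sprintf("%d sequences; mean event rate per particle %.3f",
                nrow(ev), mean(ev$event_rate_per_particle)))
print(as.data.frame(ev[, c("cell_id", "n_events", "true_n_events",
                           "event_rate_per_particle", "speed_mean")]))
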