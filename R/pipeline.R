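# End-to-end drivers: one sequence -> per-object features, per-cell record,
# tracks and event estimate; a set of sequences -> change-score tables.

#' Analyze one dual-channel sequence
#'
#' Runs the full per-sequence pipeline: segmentation of the first frame (the
#' morphology frame) and per-mitochondrion morphometry/redox measurement;
#' then, if `dynamics = TRUE`, segmentation of every frame, track linking,
#' track metrics, and the event-rate estimate from per-frame object counts.
#'
#' @param stack a `frame_stack` from [simulate_field()] (or an equivalent
#'   list with `green`/`red` H x W x T arrays and an
#'   [acquisition_config()] in `$config`).
#' @param seg_params a [segmentation_params()].
#' @param gating_radius track-linking gate, um per frame interval.
#' @param qc_min minimum mitochondria per cell for the QC gate.
#' @param dynamics analyze all frames (tracking + events); when FALSE only
#'   the first frame is measured.
#' @return list: `features` (per-object tibble), `cell_record` (one-row
#'   tibble incl. `displacement_mean`, `speed_mean`, `event_rate` when
#'   dynamics ran), `tracks`, `track_summary`, `event_estimate`, `counts`.
#' @export
analyze_stack <- function(stack, seg_params = segmentation_params(),
                          gating_radius = 1, qc_min = 50L,
                          dynamics = TRUE) {
  cfg <- stack$config
  tt <- dim(stack$green)[3]
  g1 <- stack$green[, , 1]
  r1 <- stack$red[, , 1]
  seg1 <- segment_frame(g1, r1, seg_params)
  features <- measure_frame(seg1, g1, r1, cfg$pixel_size,
                            cell_id = stack$cell_id,
                            timepoint = stack$timepoint)
  cell_record <- if (nrow(features) > 0L) {
    summarize_cell(features, qc_min = qc_min, condition = stack$condition)
  } else {
    NULL
  }
  tracks <- NULL
  track_summary <- NULL
  event_estimate <- NULL
  counts <- NULL
  if (dynamics) {
    frames <- vector("list", tt)
    frames[[1]] <- seg1
    for (t in seq_len(tt)[-1]) {
      frames[[t]] <- segment_frame(stack$green[, , t], stack$red[, , t],
                                   seg_params)
    }
    counts <- vapply(frames, function(f) f$n_objects, integer(1))
    event_estimate <- estimate_event_rate(counts)
    tracks <- link_tracks(frames, gating_radius = gating_radius,
                          pixel_size = cfg$pixel_size)
    track_summary <- summarize_tracks(tracks, cfg$frame_interval)
    if (!is.null(cell_record)) {
      cell_record$displacement_mean <-
        if (nrow(track_summary)) mean(track_summary$displacement) else
          NA_real_
      cell_record$speed_mean <-
        if (nrow(track_summary)) mean(track_summary$speed) else NA_real_
      cell_record$event_rate <- event_estimate$event_rate_per_particle
      cell_record$n_full_tracks <- nrow(track_summary)
    }
  }
  list(features = features, cell_record = cell_record, tracks = tracks,
       track_summary = track_summary, event_estimate = event_estimate,
       counts = counts)
}

# Map a cell record to the long (parameter, value) layout used by the
# change-score tables.
cell_record_to_long <- function(rec, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  pick <- function(nm) rec[[paste0(nm, "_", statistic)]]
  pars <- c(
    redox_ratio = pick("redox_ratio"),
    area = pick("area"),
    length = pick("length"),
    n_branches = pick("n_branches"),
    elongation = pick("elongation")
  )
  col <- function(nm) if (nm %in% names(rec)) rec[[nm]] else NA_real_
  dyn <- c(displacement = col("displacement_mean"),
           speed = col("speed_mean"),
           event_rate = col("event_rate"))
  vals <- c(pars, dyn)
  vals <- vals[!is.na(vals)]
  tibble::tibble(
    cell_id = rec$cell_id, condition = rec$condition,
    timepoint = rec$timepoint,
    parameter = names(vals), value = unname(vals),
    qc_pass = rec$qc_pass, n_mitochondria = rec$n_mitochondria
  )
}

#' Analyze a whole experiment and build its change-score tables
#'
#' Runs [analyze_stack()] on every sequence (cells x timepoints), collects
#' the per-cell parameter values in long format, and computes the
#' baseline-relative, control-centered change scores and the per-condition
#' summary.
#'
#' @param stacks list of `frame_stack`s covering every cell at `BL` plus at
#'   least one post timepoint. Cell identity is taken from `cell_id`,
#'   condition and timepoint from the stack labels.
#' @param seg_params,gating_radius,qc_min,dynamics passed to
#'   [analyze_stack()].
#' @param control_label condition the scores are centered on.
#' @param statistic cell-level statistic entering the score (mean over the
#'   cell's QC-passing mitochondria, or median).
#' @param qc_filter drop cells failing the QC gate before scoring.
#' @return list: `cell_values` (long per-cell table), `cell_records`,
#'   `change_scores`, `summary`, `excluded`.
#' @export
analyze_experiment <- function(stacks, seg_params = segmentation_params(),
                               gating_radius = 1, qc_min = 50L,
                               dynamics = TRUE,
                               control_label = "control",
                               statistic = "mean", qc_filter = TRUE) {
  recs <- list()
  vals <- list()
  for (s in stacks) {
    res <- analyze_stack(s, seg_params, gating_radius, qc_min, dynamics)
    if (is.null(res$cell_record)) next
    recs[[length(recs) + 1L]] <- res$cell_record
    vals[[length(vals) + 1L]] <- cell_record_to_long(res$cell_record,
                                                     statistic)
  }
  cell_records <- dplyr::bind_rows(recs)
  cell_values <- dplyr::bind_rows(vals)
  if (qc_filter && nrow(cell_values)) {
    cell_values <- cell_values[cell_values$qc_pass, , drop = FALSE]
  }
  st <- build_summary_table(cell_values, control_label)
  list(cell_values = cell_values, cell_records = cell_records,
       change_scores = st$change_scores, summary = st$summary,
       excluded = st$excluded)
}
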