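# Frame-to-frame linking of mitochondria, per-track displacement and speed,
# and the fusion/fission event-rate estimate from successive object counts.

#' Link objects across frames into tracks
#'
#' Frame-to-frame assignment minimizing total linking cost under a hard
#' distance gate: candidate links farther than `gating_radius` are forbidden,
#' and every unmatched object pays the gate cost to start or terminate a
#' track (the standard square linear-assignment formulation, solved exactly
#' with the Hungarian algorithm). Unmatched objects start new tracks;
#' matched chains extend existing ones. There is no gap closing: an object
#' missing in one frame terminates its track.
#'
#' @param frames list of per-frame `labeled_objects` (from
#'   [segment_frame()]), one per frame, in order.
#' @param gating_radius maximum link distance, um.
#' @param pixel_size um per px (converts centroids to physical units).
#' @return tibble of track points: `track_id`, `frame`, `label` (per-frame
#'   object label), `x`, `y` (um), plus attribute `n_frames`.
#' @export
link_tracks <- function(frames, gating_radius = 1, pixel_size) {
  stopifnot(length(frames) >= 2L, gating_radius > 0, pixel_size > 0)
  coords <- lapply(frames, function(fr) {
    cbind(x = fr$objects$col * pixel_size, y = fr$objects$row * pixel_size)
  })
  n_frames <- length(frames)
  big <- 1e8
  # track bookkeeping: current track id per object of the previous frame
  next_track <- 1L
  prev_tracks <- integer(nrow(coords[[1]]))
  pts <- list()
  if (nrow(coords[[1]]) > 0L) {
    prev_tracks <- seq_len(nrow(coords[[1]]))
    next_track <- nrow(coords[[1]]) + 1L
    pts[[1]] <- tibble::tibble(track_id = prev_tracks, frame = 1L,
                               label = frames[[1]]$objects$label,
                               x = coords[[1]][, 1], y = coords[[1]][, 2])
  }
  for (t in seq_len(n_frames - 1L)) {
    a <- coords[[t]]
    b <- coords[[t + 1L]]
    n1 <- nrow(a)
    n2 <- nrow(b)
    cur_tracks <- integer(n2)
    if (n2 > 0L) {
      if (n1 > 0L) {
        d <- sqrt(outer(a[, 1], b[, 1], "-")^2 +
                    outer(a[, 2], b[, 2], "-")^2)
        cost <- matrix(big, n1 + n2, n1 + n2)
        link <- d
        link[link > gating_radius] <- big
        cost[seq_len(n1), seq_len(n2)] <- link
        for (i in seq_len(n1)) cost[i, n2 + i] <- gating_radius
        for (j in seq_len(n2)) cost[n1 + j, j] <- gating_radius
        cost[(n1 + 1):(n1 + n2), (n2 + 1):(n2 + n1)] <- 0
        m <- solve_assignment(cost)
        for (i in seq_len(n1)) {
          j <- m[i]
          if (j <= n2 && d[i, j] <= gating_radius) {
            cur_tracks[j] <- prev_tracks[i]
          }
        }
      }
      born <- which(cur_tracks == 0L)
      if (length(born)) {
        cur_tracks[born] <- seq.int(next_track, length.out = length(born))
        next_track <- next_track + length(born)
      }
      pts[[t + 1L]] <- tibble::tibble(
        track_id = cur_tracks, frame = t + 1L,
        label = frames[[t + 1L]]$objects$label,
        x = b[, 1], y = b[, 2])
    }
    prev_tracks <- cur_tracks
  }
  out <- if (length(pts)) dplyr::bind_rows(pts) else
    tibble::tibble(track_id = integer(), frame = integer(),
                   label = integer(), x = numeric(), y = numeric())
  out <- dplyr::arrange(out, .data$track_id, .data$frame)
  attr(out, "n_frames") <- n_frames
  out
}

#' Displacement and speed of one track
#'
#' Displacement is the Euclidean distance between the first and last
#' centroid; speed is the traversed path length divided by the track
#' duration.
#'
#' @param track tibble with columns `frame`, `x`, `y` (um), one row per
#'   observation, frames strictly increasing.
#' @param frame_interval s per frame.
#' @return one-row tibble: `displacement` (um), `speed` (um/s), `duration`
#'   (s), `path_length` (um), `n_obs`.
#' @export
track_metrics <- function(track, frame_interval) {
  stopifnot(frame_interval > 0)
  if (nrow(track) < 2L) stop("track metrics need >= 2 observations")
  stopifnot(all(diff(track$frame) > 0))
  dx <- diff(track$x)
  dy <- diff(track$y)
  path <- unname(sum(sqrt(dx^2 + dy^2)))
  disp <- unname(sqrt((track$x[nrow(track)] - track$x[1])^2 +
                        (track$y[nrow(track)] - track$y[1])^2))
  duration <- (nrow(track) - 1L) * frame_interval
  tibble::tibble(displacement = disp, speed = path / duration,
                 duration = duration, path_length = path,
                 n_obs = nrow(track))
}

#' Per-track dynamics summary for a sequence
#'
#' Applies [track_metrics()] to each track; only tracks spanning the full
#' sequence (observed in every frame) enter the cell-level dynamics
#' summaries, mirroring the restriction to mitochondria trackable along the
#' entire sequence.
#'
#' @param tracks output of [link_tracks()].
#' @param frame_interval s per frame.
#' @param full_length_only keep only tracks spanning all frames.
#' @return tibble: `track_id`, [track_metrics()] columns, `full_length`.
#' @export
summarize_tracks <- function(tracks, frame_interval, full_length_only = TRUE) {
  n_frames <- attr(tracks, "n_frames")
  if (is.null(n_frames)) n_frames <- max(tracks$frame)
  ids <- unique(tracks$track_id)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    tr <- tracks[tracks$track_id == ids[i], , drop = FALSE]
    if (nrow(tr) < 2L) next
    met <- track_metrics(tr, frame_interval)
    met$track_id <- ids[i]
    met$full_length <- nrow(tr) == n_frames
    out[[i]] <- met
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) return(res)
  res <- res[, c("track_id", "displacement", "speed", "duration",
                 "path_length", "n_obs", "full_length")]
  if (full_length_only) res <- res[res$full_length, , drop = FALSE]
  res
}

#' Estimate the fusion/fission event rate from object counts
#'
#' The number of events is the sum of absolute successive object-count
#' changes across the sequence, and the rate per particle is that sum
#' normalized to the average number of mitochondria per frame. Count drops
#' are reported as fusion candidates and rises as fission candidates; the
#' headline rate is unsigned.
#'
#' @param counts non-negative per-frame object counts.
#' @return an `event_estimate` list: `counts`, `mean_count`, `n_events`,
#'   `n_fusion_candidates`, `n_fission_candidates`,
#'   `event_rate_per_particle`, `degenerate` (TRUE when the mean count is 0
#'   and the rate is defined as 0).
#' @export
estimate_event_rate <- function(counts) {
  stopifnot(length(counts) >= 1L, all(counts >= 0),
            all(counts == floor(counts)))
  counts <- as.integer(counts)
  dc <- diff(counts)
  n_events <- sum(abs(dc))
  mean_count <- mean(counts)
  degenerate <- mean_count == 0
  rate <- if (degenerate) 0 else n_events / mean_count
  structure(list(
    counts = counts, mean_count = mean_count,
    n_events = n_events,
    n_fusion_candidates = sum(-dc[dc < 0]),
    n_fission_candidates = sum(dc[dc > 0]),
    event_rate_per_particle = rate,
    degenerate = degenerate
  ), class = "event_estimate")
}
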