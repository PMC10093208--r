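# Track linking (Hungarian assignment vs brute force), track metrics, and
# the event-rate estimate.

test_that("the assignment solver matches exhaustive enumeration", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(2:5, 1)
    m <- n + sample.int(6 - n, 1) - 1L
    cost <- matrix(runif(n * m, 0, 10), n, m)
    got <- mitomorph:::solve_assignment(cost)
    want <- brute_force_assignment(cost)
    expect_equal(sum(cost[cbind(seq_len(n), got)]), want$cost,
                 tolerance = 1e-12)
  }
})

test_that("a constant-velocity object yields the closed-form track", {
  # 1 px/frame for 60 frames at 0.1 um/px and 1 s/frame:
  # displacement = 59 steps x 0.1 um = 5.9 um, speed = 0.1 um/s
  frames <- lapply(1:60, function(t) fake_frame(row = 20, col = 4 + t))
  tracks <- link_tracks(frames, gating_radius = 0.5, pixel_size = 0.1)
  expect_identical(max(tracks$track_id), 1L)
  expect_identical(nrow(tracks), 60L)
  ts <- summarize_tracks(tracks, frame_interval = 1)
  expect_equal(ts$displacement, 5.9, tolerance = 1e-12)
  expect_equal(ts$speed, 0.1, tolerance = 1e-12)
})

test_that("static objects give zero displacement and speed", {
  frames <- lapply(1:10, function(t)
    fake_frame(row = c(5, 20, 33), col = c(8, 25, 12)))
  tracks <- link_tracks(frames, gating_radius = 1, pixel_size = 0.1)
  ts <- summarize_tracks(tracks, frame_interval = 1)
  expect_identical(nrow(ts), 3L)
  expect_true(all(ts$displacement == 0))
  expect_true(all(ts$speed == 0))
})

test_that("frame-to-frame links match the exhaustive matching oracle", {
  gate <- 2
  for (s in 1:12) {
    set.seed(300 + s)
    coords <- lapply(1:3, function(t) {
      n <- sample(1:5, 1)
      cbind(row = runif(n, 1, 10), col = runif(n, 1, 10))
    })
    frames <- lapply(coords, function(cc)
      fake_frame(row = cc[, 1], col = cc[, 2]))
    tracks <- link_tracks(frames, gating_radius = gate, pixel_size = 1)
    for (t in 1:2) {
      a <- cbind(coords[[t]][, 2], coords[[t]][, 1])
      b <- cbind(coords[[t + 1]][, 2], coords[[t + 1]][, 1])
      oracle <- brute_force_link(a, b, gate)
      got <- links_between(tracks, t)
      cost_got <- sum(sqrt(rowSums(
        (a[got[, 1], , drop = FALSE] - b[got[, 2], , drop = FALSE])^2))) +
        gate * (nrow(a) - nrow(got)) + gate * (nrow(b) - nrow(got))
      expect_equal(cost_got, oracle$cost, tolerance = 1e-9)
    }
  }
})

test_that("track metrics follow their geometric definitions", {
  # closed loop: displacement 0, speed > 0
  sq <- tibble::tibble(frame = 1:5,
                       x = c(0, 1, 1, 0, 0), y = c(0, 0, 1, 1, 0))
  m <- track_metrics(sq, frame_interval = 1)
  expect_equal(m$displacement, 0)
  expect_equal(m$speed, 1)
  expect_equal(m$path_length, 4)
  # straight path of k steps of length d
  st <- tibble::tibble(frame = 1:7, x = 0.25 * (0:6), y = 0)
  m2 <- track_metrics(st, frame_interval = 0.5)
  expect_equal(m2$displacement, 6 * 0.25)
  expect_equal(m2$speed, 0.25 / 0.5)
  expect_error(track_metrics(st[1, ], 1), ">= 2")
})

test_that("relabeling objects does not change track geometry", {
  set.seed(7)
  coords <- lapply(1:6, function(t)
    cbind(row = c(5, 15, 25) + 0.2 * t, col = c(5, 18, 30) - 0.1 * t))
  frames <- lapply(coords, function(cc) fake_frame(cc[, 1], cc[, 2]))
  frames_shuffled <- lapply(coords, function(cc) {
    o <- sample(nrow(cc))
    fake_frame(cc[o, 1], cc[o, 2])
  })
  t1 <- summarize_tracks(link_tracks(frames, 1, 0.1), 1)
  t2 <- summarize_tracks(link_tracks(frames_shuffled, 1, 0.1), 1)
  expect_equal(sort(t1$displacement), sort(t2$displacement))
  expect_equal(sort(t1$speed), sort(t2$speed))
})

test_that("event rate follows the stated count formula", {
  e0 <- estimate_event_rate(c(10, 10, 10, 10))
  expect_identical(e0$n_events, 0L)
  expect_equal(e0$event_rate_per_particle, 0)
  e1 <- estimate_event_rate(c(10, 9))
  expect_identical(e1$n_events, 1L)
  expect_equal(e1$event_rate_per_particle, 1 / 9.5)
  e2 <- estimate_event_rate(c(5, 7, 6, 6))
  expect_identical(e2$n_events, 3L)
  expect_identical(e2$n_fission_candidates, 2L)
  expect_identical(e2$n_fusion_candidates, 1L)
  expect_equal(e2$event_rate_per_particle, 3 / 6)
  # lower bound: n_events >= |count(T) - count(1)|
  for (s in 1:10) {
    set.seed(s)
    cts <- pmax(0, round(cumsum(rnorm(20, 0, 2))) + 10)
    ee <- estimate_event_rate(cts)
    expect_gte(ee$n_events, abs(cts[20] - cts[1]))
  }
  ez <- estimate_event_rate(c(0, 0))
  expect_true(ez$degenerate)
  expect_equal(ez$event_rate_per_particle, 0)
})

test_that("Brownian steps reproduce the 4Dt law through the pipeline", {
  # 4 sparse noise-free fields, tracked end to end
  d_coef <- 0.005
  n_frames <- 15L
  disp2 <- numeric(0)
  for (s in 1:4) {
    cfg <- acquisition_config(n_frames = n_frames,
                              image_shape = c(192, 192))
    p <- field_params(n_mito = 7, p_branched = 0, diffusion = d_coef,
                      event_rate = 0, poisson_noise = FALSE, read_sd = 0,
                      quantize = FALSE)
    sim <- simulate_field(cfg, p, seed = 400 + s)
    res <- analyze_stack(sim$stack, qc_min = 1)
    ts <- res$track_summary
    disp2 <- c(disp2, ts$displacement[ts$full_length]^2)
  }
  t_lag <- (n_frames - 1) * 1
  expected <- 4 * d_coef * t_lag
  se <- expected / sqrt(length(disp2)) * 1  # sd of dx^2+dy^2 is 4Dt
  expect_gt(length(disp2), 20)
  expect_lt(abs(mean(disp2) - expected), 3 * se)
})
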