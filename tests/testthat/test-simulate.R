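# Synthetic generator: determinism, photometric construction, event
# bookkeeping, intensity conservation, and the particle-size sampler.

small_cfg <- function(n_frames = 2L, shape = c(96L, 96L)) {
  acquisition_config(n_frames = n_frames, image_shape = shape)
}

noise_free <- function(...) {
  field_params(..., poisson_noise = FALSE, read_sd = 0, quantize = FALSE)
}

test_that("identical seeds give bit-identical stacks and ground truth", {
  cfg <- small_cfg(n_frames = 4L)
  p <- field_params(n_mito = 8, event_rate = 0.02)
  s1 <- simulate_field(cfg, p, seed = 11)
  s2 <- simulate_field(cfg, p, seed = 11)
  s3 <- simulate_field(cfg, p, seed = 12)
  expect_identical(s1$stack$green, s2$stack$green)
  expect_identical(s1$stack$red, s2$stack$red)
  expect_identical(s1$truth$objects, s2$truth$objects)
  expect_identical(s1$truth$counts, s2$truth$counts)
  expect_false(identical(s1$stack$green, s3$stack$green))
})

test_that("a static noise-free object renders identically in both frames", {
  ob <- data.frame(x = 3.2, y = 3.4, theta = 0.4, length = 2, width = 0.5,
                   green = 500, ratio = 1.3)
  p <- noise_free(objects = ob, diffusion = 0, event_rate = 0)
  sim <- simulate_field(small_cfg(), p, seed = 1)
  expect_equal(sim$stack$green[, , 1], sim$stack$green[, , 2])
  expect_equal(sim$stack$red[, , 1], sim$stack$red[, , 2])
  for (ch in c("green", "red")) {
    mask <- sim$stack[[ch]][, , 1] > 0.05 * max(sim$stack[[ch]][, , 1])
    lab <- flood_fill_label(mask)
    expect_identical(max(lab), 1L)
  }
})

test_that("per-object red/green ratio equals the generating ratio, noise off", {
  # degenerate ratio distribution at 2.0
  p <- noise_free(n_mito = 12, ratio_meanlog = log(2), ratio_sdlog = 0,
                  diffusion = 0, event_rate = 0)
  cfg <- small_cfg(shape = c(256L, 256L))
  sim <- simulate_field(cfg, p, seed = 3)
  seg <- segment_frame(sim$stack$green[, , 1], sim$stack$red[, , 1])
  expect_gt(seg$n_objects, 5)
  f <- measure_frame(seg, sim$stack$green[, , 1], sim$stack$red[, , 1],
                     cfg$pixel_size)
  expect_true(all(abs(f$redox_ratio - 2) < 1e-6))
})

test_that("live-object count follows the scheduled events", {
  ob <- data.frame(x = c(3, 6, 9, 12, 9), y = c(3, 6, 9, 3, 12),
                   theta = 0.5, length = 1.6, width = 0.45,
                   green = 400, ratio = 1)
  sched <- tibble::tibble(frame = c(2L, 5L, 7L),
                          type = c("fission", "fusion", "fission"),
                          ids = list(3L, c(1L, 2L), 4L))
  p <- noise_free(objects = ob, diffusion = 0, event_schedule = sched)
  cfg <- acquisition_config(n_frames = 10L, image_shape = c(224L, 224L))
  sim <- simulate_field(cfg, p, seed = 5)
  # events take effect on the following frame
  expected <- integer(10)
  for (t in 1:10) {
    k <- sum(sim$truth$events$frame < t)
    expected[t] <- 5L + sum(ifelse(
      sim$truth$events$type[seq_len(k)] == "fission", 1L, -1L))
  }
  expect_identical(sim$truth$counts, expected)
  expect_identical(sim$truth$counts[10], 5L + 2L - 1L)
})

test_that("fusion conserves integrated intensity in both channels", {
  ob <- data.frame(x = c(4, 6), y = c(4, 6), theta = c(0.2, 1.1),
                   length = c(2, 1.4), width = c(0.5, 0.4),
                   green = c(300, 600), ratio = c(1.0, 2.0))
  sched <- tibble::tibble(frame = 2L, type = "fusion", ids = list(c(1L, 2L)))
  p <- noise_free(objects = ob, diffusion = 0, event_schedule = sched)
  cfg <- acquisition_config(n_frames = 4L, image_shape = c(160L, 160L))
  sim <- simulate_field(cfg, p, seed = 7)
  expect_identical(sim$truth$counts, c(2L, 2L, 1L, 1L))
  # model-level conservation is exact: amplitude x analytic capsule area
  state <- mitomorph:::sample_initial_state(
    cfg, mitomorph:::field_params(objects = ob))
  merged <- mitomorph:::apply_fusion(state, c(1L, 2L))
  area_of <- function(st, i) mitomorph:::capsule_area(
    sum(st$arm_len[[i]]), st$width[i])
  g_parents <- sum(state$green * vapply(1:2, function(i)
    area_of(state, i), numeric(1)))
  r_parents <- sum(state$green * state$ratio * vapply(1:2, function(i)
    area_of(state, i), numeric(1)))
  expect_equal(merged$green[1] * area_of(merged, 1), g_parents,
               tolerance = 1e-9)
  expect_equal(merged$green[1] * merged$ratio[1] * area_of(merged, 1),
               r_parents, tolerance = 1e-9)
  # the rendered integral agrees up to rasterization (edge antialiasing)
  for (ch in c("green", "red")) {
    before <- sum(sim$stack[[ch]][, , 2])
    after <- sum(sim$stack[[ch]][, , 3])
    expect_lt(abs(after - before) / before, 0.1)
  }
})

test_that("random event counts match the per-particle rate", {
  # closed form: each live particle triggers independently with prob
  # lambda per transition, so E[events] = lambda * sum_t N_t
  lambda <- 0.01
  total <- 0
  expected <- 0
  for (s in 1:30) {
    p <- noise_free(n_mito = 10, p_branched = 0, diffusion = 0,
                    event_rate = lambda)
    cfg <- acquisition_config(n_frames = 20L, image_shape = c(256L, 256L))
    sim <- simulate_field(cfg, p, seed = 100 + s)
    total <- total + nrow(sim$truth$events)
    expected <- expected + lambda * sum(sim$truth$counts[-20])
  }
  se <- sqrt(expected)
  expect_lt(abs(total - expected), 3 * se)
})

test_that("timepoint series applies multiplicative shifts by construction", {
  cfg <- small_cfg()
  p <- field_params(n_mito = 6)
  ser0 <- simulate_timepoint_series(cfg, p, effect_spec = list(
    `6h` = c(redox_ratio = 1), `24h` = c(redox_ratio = 1)), seed = 2)
  expect_identical(
    ser0$truths$BL$params$ratio_meanlog,
    ser0$truths$`24h`$params$ratio_meanlog)
  ser <- simulate_timepoint_series(cfg, p, effect_spec = list(
    `24h` = c(redox_ratio = 1.5, length = 0.8)), seed = 2)
  expect_equal(ser$truths$`24h`$params$ratio_meanlog -
                 ser$truths$BL$params$ratio_meanlog, log(1.5))
  expect_equal(ser$truths$`24h`$params$length_meanlog -
                 ser$truths$BL$params$length_meanlog, log(0.8))
  expect_setequal(names(ser$stacks), c("BL", "6h", "24h"))
  expect_identical(ser$stacks$`24h`$timepoint, "24h")
})

test_that("particle sampler honors the mixture and its degenerate limits", {
  s <- simulate_particle_sample(
    50, data.frame(mode = 100, sdlog = 0, weight = 1), seed = 1)
  expect_equal(s$diameters, rep(100, 50))
  s2 <- simulate_particle_sample(
    4000, data.frame(mode = c(80, 300), sdlog = c(0.1, 0.1),
                     weight = c(0.5, 0.5)), seed = 2)
  frac_large <- mean(s2$diameters > 150)
  # 99% binomial CI around 0.5 at n = 4000
  expect_lt(abs(frac_large - 0.5), 2.58 * sqrt(0.25 / 4000))
  expect_identical(simulate_particle_sample(10, seed = 3)$diameters,
                   simulate_particle_sample(10, seed = 3)$diameters)
})

test_that("generator rejects bad inputs", {
  expect_error(simulate_particle_sample(0, seed = 1), "positive")
  # overcrowded field: forced > 30% overlap
  ob <- data.frame(x = 3 + 0.02 * (1:40), y = 3, theta = 0.1,
                   length = 2, width = 0.5, green = 400, ratio = 1)
  p <- noise_free(objects = ob)
  expect_error(simulate_field(small_cfg(), p, seed = 1), "overlap")
  # schedule referencing an unknown id
  sched <- tibble::tibble(frame = 1L, type = "fission", ids = list(99L))
  ob2 <- data.frame(x = 3, y = 3, theta = 0, length = 2, width = 0.5,
                    green = 400, ratio = 1)
  expect_error(
    simulate_field(small_cfg(3L), noise_free(objects = ob2,
                                             event_schedule = sched),
                   seed = 1),
    "unknown id")
  expect_error(acquisition_config(n_frames = 1), "n_frames")
})
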