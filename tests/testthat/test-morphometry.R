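# Per-object morphometry: arithmetic identities, branch counting against
# hand-built skeleton shapes, shape recovery on generated capsules, and the
# per-cell summary with its QC gate.

test_that("elongation factor and redox ratio are the stated quotients", {
  expect_equal(elongation_factor(4, 2), 2)
  expect_equal(elongation_factor(3.7, 3.7), 1)
  expect_error(elongation_factor(4, 0), "width")
  expect_equal(redox_ratio(100, 50), 2)
  expect_equal(redox_ratio(7.3, 7.3), 1)
  expect_error(redox_ratio(10, 0), "mean_green")
})

test_that("measure_object computes area and ratio from first principles", {
  g <- matrix(50, 30, 30)
  r <- matrix(100, 30, 30)
  px <- cbind(10:14, rep(10, 5))
  px <- rbind(px, cbind(10:14, rep(11, 5)))   # 10 pixels
  f <- measure_object(px, g, r, pixel_size = 0.1)
  expect_equal(f$area, 10 * 0.1^2)
  expect_equal(f$redox_ratio, 2)
  expect_equal(f$elongation, f$length / f$width, tolerance = 1e-9)
})

test_that("branch counting matches hand-built skeleton shapes", {
  # straight bar: one branch
  bar <- matrix(FALSE, 30, 30)
  bar[15, 5:24] <- TRUE
  expect_identical(count_branches(bar), 1L)
  # Y: three bars meeting at one pixel
  y <- matrix(FALSE, 41, 41)
  y[21, 5:21] <- TRUE                      # west arm
  for (k in 0:12) {
    y[21 - k, 21 + k] <- TRUE              # north-east arm
    y[21 + k, 21 + k] <- TRUE              # south-east arm
  }
  expect_identical(count_branches(y), 3L)
  # plus sign: four arms
  pl <- matrix(FALSE, 41, 41)
  pl[21, 5:37] <- TRUE
  pl[5:37, 21] <- TRUE
  expect_identical(count_branches(pl), 4L)
  # single pixel
  expect_identical(count_branches(cbind(3L, 3L)), 1L)
})

test_that("noise-free capsules are recovered within 10%", {
  ob <- data.frame(x = c(4, 10, 16, 10), y = c(4, 4, 10, 16),
                   theta = c(0, 0.7, 1.3, 2.2),
                   length = 3, width = 0.5, green = 400, ratio = 1)
  p <- field_params(objects = ob, poisson_noise = FALSE, read_sd = 0,
                    quantize = FALSE, diffusion = 0, event_rate = 0)
  cfg <- acquisition_config(n_frames = 2, image_shape = c(300, 300))
  sim <- simulate_field(cfg, p, seed = 31)
  # half-plateau threshold: recovers the true boundary under symmetric blur
  seg <- segment_frame(sim$stack$green[, , 1], sim$stack$red[, , 1],
                       segmentation_params("fixed", fixed_threshold = 200))
  f <- measure_frame(seg, sim$stack$green[, , 1], sim$stack$red[, , 1],
                     cfg$pixel_size)
  expect_identical(nrow(f), 4L)
  expect_true(all(abs(f$length - 3) / 3 < 0.1))
  expect_true(all(abs(f$elongation - 6) / 6 < 0.1))
})

test_that("3-capsule stars recover their branch count", {
  ob <- data.frame(x = rep(c(5, 11, 17), 3), y = rep(c(5, 11, 17), each = 3),
                   theta = seq(0.1, 2.5, length.out = 9),
                   length = 2.4, width = 0.45, green = 400, ratio = 1,
                   n_branches = 3)
  p <- field_params(objects = ob, poisson_noise = FALSE, read_sd = 0,
                    quantize = FALSE, diffusion = 0, event_rate = 0)
  cfg <- acquisition_config(n_frames = 2, image_shape = c(320, 320))
  sim <- simulate_field(cfg, p, seed = 32)
  seg <- segment_frame(sim$stack$green[, , 1], sim$stack$red[, , 1])
  f <- measure_frame(seg, sim$stack$green[, , 1], sim$stack$red[, , 1],
                     cfg$pixel_size)
  expect_identical(nrow(f), 9L)
  expect_gte(mean(f$n_branches == 3L), 0.9)
})

test_that("morphometry is scale-equivariant and gain-invariant", {
  set.seed(5)
  g <- matrix(runif(900, 100, 200), 30, 30)
  r <- 1.7 * g
  px <- which(matrix(FALSE, 30, 30) | row(g) %in% 12:18 & col(g) %in% 10:22,
              arr.ind = TRUE)
  f1 <- measure_object(px, g, r, pixel_size = 0.1)
  f2 <- measure_object(px, g, r, pixel_size = 0.2)
  expect_equal(f2$length, 2 * f1$length)
  expect_equal(f2$width, 2 * f1$width)
  expect_equal(f2$area, 4 * f1$area)
  expect_equal(f2$elongation, f1$elongation)
  expect_identical(f2$n_branches, f1$n_branches)
  expect_equal(f2$redox_ratio, f1$redox_ratio)
  # gain invariance
  f3 <- measure_object(px, 3 * g, 3 * r, pixel_size = 0.1)
  expect_equal(f3$redox_ratio, f1$redox_ratio)
  f4 <- measure_object(px, g, 5 * r, pixel_size = 0.1)
  expect_equal(f4$redox_ratio, 5 * f1$redox_ratio)
})

test_that("cell summary applies the fifty-mitochondria QC gate", {
  mk <- function(n) {
    tibble::tibble(
      cell_id = "c1", timepoint = "BL", object_id = seq_len(n),
      area = 0.5, length = 2, width = 0.5, elongation = 4,
      n_branches = 1L, mean_green = 100, mean_red = 150,
      redox_ratio = 1.5, centroid_x = 1, centroid_y = 1,
      ratio_defined = TRUE)
  }
  rec49 <- summarize_cell(mk(49))
  rec50 <- summarize_cell(mk(50))
  expect_false(rec49$qc_pass)
  expect_true(rec50$qc_pass)
  expect_equal(rec50$redox_ratio_mean, 1.5)
  expect_equal(rec50$redox_ratio_median, 1.5)
  expect_error(summarize_cell(mk(0)), "empty")
  # mixed values: mean equals direct recomputation; NA ratios excluded
  f <- mk(60)
  f$length <- seq_len(60)
  f$redox_ratio[1:10] <- NA_real_
  rec <- summarize_cell(f)
  expect_equal(rec$length_mean, mean(seq_len(60)))
  expect_equal(rec$length_median, stats::median(seq_len(60)))
  expect_equal(rec$redox_ratio_mean, 1.5)
})
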