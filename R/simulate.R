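# Synthetic dual-channel time-lapse generator with full ground truth.
#
# The generator emulates the imaging regime used for astrocytic MitoTimer
# sequences: a field of elongated mitochondria imaged in two channels
# (green = newly synthesized protein, red = oxidized protein) at 1 frame/s for
# 60 s, 16-bit, with the red channel proportional to the green channel per
# object (the redox-state ratio). Mitochondria are rendered as capsules
# (segments with rounded caps) convolved with a Gaussian PSF; branched
# mitochondria are unions of >= 3 capsule arms sharing a hub. Motion is
# per-object Brownian plus an optional shared drift; fusion/fission events
# either follow an explicit schedule or occur at a per-particle rate.

#' Acquisition configuration
#'
#' Describes the imaging regime: pixel pitch, frame interval, sequence length,
#' frame geometry and bit depth. Defaults follow a 1 frame/s, 60 s, 16-bit
#' regime; the pixel pitch (not reported by typical high-magnification setups)
#' defaults to 0.07 um/px.
#'
#' @param pixel_size physical size of one pixel, um/px. Must be > 0.
#' @param frame_interval time between frames, s. Must be > 0.
#' @param n_frames number of frames per sequence (>= 2).
#' @param image_shape integer vector `c(height, width)` in px, both >= 64.
#' @param bit_depth camera bit depth; intensities are clipped to
#'   `[0, 2^bit_depth - 1]` when quantization is on.
#' @return an `acquisition_config` object (a validated list).
#' @export
acquisition_config <- function(pixel_size = 0.07, frame_interval = 1,
                               n_frames = 60L, image_shape = c(576L, 576L),
                               bit_depth = 16L) {
  stopifnot(
    is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0,
    is.numeric(frame_interval), length(frame_interval) == 1L, frame_interval > 0,
    length(n_frames) == 1L, n_frames >= 2,
    length(image_shape) == 2L, all(image_shape >= 64),
    length(bit_depth) == 1L, bit_depth >= 1
  )
  structure(
    list(
      pixel_size = pixel_size,
      frame_interval = frame_interval,
      n_frames = as.integer(n_frames),
      image_shape = as.integer(image_shape),
      bit_depth = as.integer(bit_depth)
    ),
    class = "acquisition_config"
  )
}

#' Field parameters for the synthetic generator
#'
#' Distributions and dynamics controlling one simulated field (one cell).
#' Lengths/widths are lognormal in um; the per-object red/green ratio and the
#' green amplitude are lognormal. A fraction of objects is branched (>= 3
#' capsule arms sharing a hub); the true branch count of such an object is its
#' number of arms, and unbranched objects count as one branch.
#'
#' @param n_mito number of mitochondria at frame 1.
#' @param length_meanlog,length_sdlog lognormal parameters of the end-to-end
#'   length (um).
#' @param width_meanlog,width_sdlog lognormal parameters of the width (um);
#'   widths are truncated below the sampled length.
#' @param ratio_meanlog,ratio_sdlog lognormal parameters of the per-object
#'   red/green intensity ratio (redox-state ratio).
#' @param green_meanlog,green_sdlog lognormal parameters of the green plateau
#'   amplitude (detector counts).
#' @param p_branched probability an object is branched.
#' @param branch_counts,branch_count_probs possible arm counts for branched
#'   objects and their probabilities.
#' @param diffusion Brownian diffusion coefficient, um^2/s.
#' @param drift shared drift velocity `c(vx, vy)`, um/s.
#' @param event_rate per-particle, per-transition probability of a
#'   fusion/fission event (ignored when `event_schedule` is given).
#' @param event_schedule optional explicit schedule: a data frame with columns
#'   `frame` (the transition index, in `[1, n_frames - 1]`), `type`
#'   (`"fusion"` or `"fission"`) and `ids` (list column of participant ids:
#'   two ids for a fusion, one for a fission).
#' @param psf_sigma Gaussian PSF standard deviation, px.
#' @param gain camera gain for the Poisson shot-noise stage.
#' @param read_sd additive Gaussian read noise, detector counts.
#' @param poisson_noise logical; apply shot noise.
#' @param quantize logical; round to integers and clip to the bit-depth range.
#'   Set `poisson_noise = FALSE`, `read_sd = 0`, `quantize = FALSE` for an
#'   exactly photometric (noise-free) rendering.
#' @param fission_gap gap between the two fission products, px.
#' @param max_overlap maximum tolerated initial overlap fraction
#'   (1 - union area / summed area); denser fields are rejected.
#' @param objects optional explicit object table overriding random sampling:
#'   columns `x`, `y` (um), `theta` (rad), `length`, `width` (um), `green`,
#'   `ratio`; optional `n_branches`.
#' @return a `field_params` object.
#' @export
field_params <- function(n_mito = 70L,
                         length_meanlog = log(1.6), length_sdlog = 0.35,
                         width_meanlog = log(0.45), width_sdlog = 0.12,
                         ratio_meanlog = 0, ratio_sdlog = 0.25,
                         green_meanlog = log(400), green_sdlog = 0.3,
                         p_branched = 0.12,
                         branch_counts = c(3L, 4L),
                         branch_count_probs = c(0.75, 0.25),
                         diffusion = 0.005, drift = c(0, 0),
                         event_rate = 0.001, event_schedule = NULL,
                         psf_sigma = 1.5, gain = 1.0, read_sd = 2.0,
                         poisson_noise = TRUE, quantize = TRUE,
                         fission_gap = 5, max_overlap = 0.3,
                         objects = NULL) {
  stopifnot(
    n_mito >= 1 || !is.null(objects),
    length_sdlog >= 0, width_sdlog >= 0, ratio_sdlog >= 0, green_sdlog >= 0,
    p_branched >= 0, p_branched <= 1,
    length(branch_counts) == length(branch_count_probs),
    all(branch_counts >= 3),
    diffusion >= 0, length(drift) == 2L,
    event_rate >= 0, psf_sigma >= 0, gain > 0, read_sd >= 0,
    fission_gap > 0, max_overlap > 0
  )
  if (!is.null(event_schedule)) {
    stopifnot(all(c("frame", "type", "ids") %in% names(event_schedule)),
              all(event_schedule$type %in% c("fusion", "fission")))
  }
  structure(as.list(environment()), class = "field_params")
}

# --- object state -----------------------------------------------------------

# The live state is a tibble with one row per object:
#   id, x, y (hub position, um), theta, width (um), green, ratio, n_branches,
#   arm_theta, arm_len (list columns: one arm angle/hub-to-tip length per arm).
# Unbranched objects are stored as two collinear arms of length/2 so that a
# single renderer covers both cases.

sample_initial_state <- function(config, params) {
  h_um <- config$image_shape[1] * config$pixel_size
  w_um <- config$image_shape[2] * config$pixel_size
  if (!is.null(params$objects)) {
    ob <- tibble::as_tibble(params$objects)
    stopifnot(all(c("x", "y", "theta", "length", "width", "green", "ratio")
                  %in% names(ob)))
    if (!"n_branches" %in% names(ob)) ob$n_branches <- 1L
    n <- nrow(ob)
    len <- ob$length
    wid <- ob$width
    theta <- ob$theta
    nb <- as.integer(ob$n_branches)
    x <- ob$x
    y <- ob$y
    green <- ob$green
    ratio <- ob$ratio
  } else {
    n <- as.integer(params$n_mito)
    len <- stats::rlnorm(n, params$length_meanlog, params$length_sdlog)
    wid <- pmin(stats::rlnorm(n, params$width_meanlog, params$width_sdlog),
                len * 0.95)
    theta <- stats::runif(n, 0, pi)
    nb <- rep(1L, n)
    branched <- stats::runif(n) < params$p_branched
    if (any(branched)) {
      nb[branched] <- sample(as.integer(params$branch_counts),
                             sum(branched), replace = TRUE,
                             prob = params$branch_count_probs)
    }
    margin <- pmax(len / 2, 0.5)
    x <- stats::runif(n, margin + 0.2, w_um - margin - 0.2)
    y <- stats::runif(n, margin + 0.2, h_um - margin - 0.2)
    green <- stats::rlnorm(n, params$green_meanlog, params$green_sdlog)
    ratio <- stats::rlnorm(n, params$ratio_meanlog, params$ratio_sdlog)
  }
  stopifnot(all(len >= wid), all(wid > 0), all(green > 0), all(ratio > 0))
  arm_theta <- vector("list", n)
  arm_len <- vector("list", n)
  for (i in seq_len(n)) {
    if (nb[i] == 1L) {
      arm_theta[[i]] <- c(theta[i], theta[i] + pi)
      arm_len[[i]] <- rep(len[i] / 2, 2L)
    } else {
      k <- nb[i]
      # arms fan out from the hub; jitter is kept small so that arms stay
      # angularly resolvable after PSF blur
      base <- theta[i] + seq(0, 2 * pi, length.out = k + 1L)[seq_len(k)]
      arm_theta[[i]] <- base + stats::runif(k, -pi / (8 * k), pi / (8 * k))
      # arms must stay resolvable after thinning: at least 1.5 widths
      arm_len[[i]] <- pmax(len[i] / 2 * stats::runif(k, 0.75, 1.25),
                           1.5 * wid[i])
    }
  }
  tibble::tibble(
    id = seq_len(n), x = x, y = y, theta = theta,
    width = wid, green = green, ratio = ratio, n_branches = nb,
    arm_theta = arm_theta, arm_len = arm_len
  )
}

# End-to-end "true length" of an object: unbranched, the capsule length;
# branched, the longest tip-to-tip path through the hub.
state_true_length <- function(state) {
  vapply(seq_len(nrow(state)), function(i) {
    al <- sort(state$arm_len[[i]], decreasing = TRUE)
    al[1] + al[2]
  }, numeric(1))
}

# Analytic capsule area (end-to-end length L, width w): shaft + two caps.
capsule_area <- function(length, width) {
  (length - width) * width + pi * width^2 / 4
}

state_true_area <- function(state) {
  vapply(seq_len(nrow(state)), function(i) {
    w <- state$width[i]
    arms <- state$arm_len[[i]]
    if (state$n_branches[i] == 1L) {
      capsule_area(sum(arms), w)
    } else {
      # hub-to-tip shafts plus one shared hub cap (approximate)
      sum((arms - w / 2) * w) + pi * w^2 / 4
    }
  }, numeric(1))
}

render_state <- function(state, config, channel = c("green", "red")) {
  channel <- match.arg(channel)
  h <- config$image_shape[1]
  w <- config$image_shape[2]
  ps <- config$pixel_size
  img <- matrix(0, h, w)
  for (i in seq_len(nrow(state))) {
    amp <- if (channel == "green") state$green[i] else
      state$green[i] * state$ratio[i]
    hx <- state$x[i] / ps
    hy <- state$y[i] / ps
    wd <- state$width[i] / ps
    for (k in seq_along(state$arm_theta[[i]])) {
      th <- state$arm_theta[[i]][k]
      core <- max(state$arm_len[[i]][k] / ps - wd / 2, 0)
      p <- capsule_patch(h, w, hx, hy,
                         hx + core * cos(th), hy + core * sin(th), wd)
      if (!is.null(p)) {
        img[p$rows, p$cols] <- img[p$rows, p$cols] + amp * p$patch
      }
    }
  }
  img
}

initial_overlap_fraction <- function(state, config) {
  h <- config$image_shape[1]
  w <- config$image_shape[2]
  ps <- config$pixel_size
  cover <- integer(h * w)
  total <- 0L
  for (i in seq_len(nrow(state))) {
    hx <- state$x[i] / ps
    hy <- state$y[i] / ps
    wd <- state$width[i] / ps
    obj_idx <- integer(0)
    for (k in seq_along(state$arm_theta[[i]])) {
      th <- state$arm_theta[[i]][k]
      core <- max(state$arm_len[[i]][k] / ps - wd / 2, 0)
      p <- capsule_patch(h, w, hx, hy,
                         hx + core * cos(th), hy + core * sin(th), wd)
      if (is.null(p)) next
      on <- which(p$patch > 0.5)
      rr <- p$rows[((on - 1L) %% length(p$rows)) + 1L]
      cc <- p$cols[((on - 1L) %/% length(p$rows)) + 1L]
      obj_idx <- c(obj_idx, (cc - 1L) * h + rr)
    }
    obj_idx <- unique(obj_idx)
    cover[obj_idx] <- cover[obj_idx] + 1L
    total <- total + length(obj_idx)
  }
  if (total == 0L) return(0)
  1 - sum(cover > 0L) / total
}

# --- events -----------------------------------------------------------------

apply_fusion <- function(state, ids) {
  i1 <- which(state$id == ids[1])
  i2 <- which(state$id == ids[2])
  stopifnot(length(i1) == 1L, length(i2) == 1L)
  # integrated green of a capsule = plateau amplitude x area; use analytic
  # areas so that fusion conserves both channels' integrated intensity
  l1 <- sum(state$arm_len[[i1]])
  l2 <- sum(state$arm_len[[i2]])
  a1 <- capsule_area(l1, state$width[i1])
  a2 <- capsule_area(l2, state$width[i2])
  g1 <- state$green[i1] * a1
  g2 <- state$green[i2] * a2
  r1 <- g1 * state$ratio[i1]
  r2 <- g2 * state$ratio[i2]
  wm <- (state$width[i1] * a1 + state$width[i2] * a2) / (a1 + a2)
  am <- a1 + a2
  lm <- max((am - pi * wm^2 / 4) / wm + wm, wm)
  xm <- (state$x[i1] * g1 + state$x[i2] * g2) / (g1 + g2)
  ym <- (state$y[i1] * g1 + state$y[i2] * g2) / (g1 + g2)
  thm <- if (a1 >= a2) state$theta[i1] else state$theta[i2]
  gm <- (g1 + g2) / am
  rm <- (r1 + r2) / (g1 + g2)
  new_id <- max(state$id) + 1L
  merged <- tibble::tibble(
    id = new_id, x = xm, y = ym, theta = thm, width = wm,
    green = gm, ratio = rm, n_branches = 1L,
    arm_theta = list(c(thm, thm + pi)), arm_len = list(rep(lm / 2, 2))
  )
  dplyr::bind_rows(state[-c(i1, i2), ], merged)
}

apply_fission <- function(state, id, gap_um) {
  i <- which(state$id == id)
  stopifnot(length(i) == 1L)
  w <- state$width[i]
  l <- sum(state$arm_len[[i]])
  a <- capsule_area(l, w)
  lc <- max((a / 2 - pi * w^2 / 4) / w + w, w)
  th <- state$theta[i]
  off <- lc / 2 + gap_um / 2
  base <- state[i, ]
  mk_child <- function(new_id, sgn) {
    ch <- base
    ch$id <- new_id
    ch$x <- base$x + sgn * off * cos(th)
    ch$y <- base$y + sgn * off * sin(th)
    ch$n_branches <- 1L
    ch$arm_theta <- list(c(th, th + pi))
    ch$arm_len <- list(rep(lc / 2, 2))
    ch
  }
  new_id <- max(state$id)
  dplyr::bind_rows(state[-i, ],
                   mk_child(new_id + 1L, -1), mk_child(new_id + 2L, 1))
}

# --- noise ------------------------------------------------------------------

apply_noise <- function(img, params, config) {
  out <- img
  if (isTRUE(params$poisson_noise)) {
    out <- stats::rpois(length(out), lambda = pmax(out * params$gain, 0)) /
      params$gain
    out <- matrix(out, nrow(img), ncol(img))
  }
  if (params$read_sd > 0) {
    out <- out + matrix(stats::rnorm(length(out), 0, params$read_sd),
                        nrow(img), ncol(img))
  }
  if (isTRUE(params$quantize)) {
    out <- round(pmin(pmax(out, 0), 2^config$bit_depth - 1))
  }
  out
}

# --- main entry points ------------------------------------------------------

#' Simulate one dual-channel time-lapse field
#'
#' Renders a field of capsule-shaped mitochondria in two channels with
#' `red = ratio x green` per object (before noise), Brownian + drift motion,
#' and fusion/fission events, and returns both the image stack and the full
#' ground truth. Identical `(config, params, seed)` give bit-identical output.
#'
#' A scheduled event at frame `f` is the transition between frames `f` and
#' `f + 1`: the new configuration is first visible at frame `f + 1`.
#'
#' @param config an [acquisition_config()].
#' @param params a [field_params()].
#' @param seed integer seed (required; all randomness is derived from it).
#' @param cell_id,condition,timepoint labels carried on the stack.
#' @return a list with elements `stack` (class `frame_stack`: `green` and
#'   `red` H x W x T arrays, `config`, labels) and `truth` (class
#'   `mito_ground_truth`: `objects` (initial per-object table incl. true
#'   length, width, elongation, ratio), `events`, per-frame `counts`,
#'   per-frame true `positions`, and `motion`).
#' @export
simulate_field <- function(config, params = field_params(), seed,
                           cell_id = "cell_1", condition = "control",
                           timepoint = "BL") {
  stopifnot(inherits(config, "acquisition_config"),
            inherits(params, "field_params"),
            !missing(seed), is.numeric(seed))
  timepoint <- match.arg(timepoint, c("BL", "6h", "24h"))
  tt <- config$n_frames
  if (!is.null(params$event_schedule)) {
    es <- params$event_schedule
    if (nrow(es) > 0 && (any(es$frame < 1) || any(es$frame > tt - 1))) {
      stop("event schedule frames must lie in [1, n_frames - 1]")
    }
  }
  withr::with_seed(as.integer(seed), {
    state <- sample_initial_state(config, params)
    ov <- initial_overlap_fraction(state, config)
    if (ov > params$max_overlap) {
      stop(sprintf(
        "initial object overlap %.1f%% exceeds %.0f%%; reduce density",
        100 * ov, 100 * params$max_overlap))
    }
    # ids created by earlier events are legal participants; validated lazily
    sched <- if (!is.null(params$event_schedule))
      tibble::as_tibble(params$event_schedule) else NULL
    h <- config$image_shape[1]
    w <- config$image_shape[2]
    green <- array(0, dim = c(h, w, tt))
    red <- array(0, dim = c(h, w, tt))
    counts <- integer(tt)
    positions <- vector("list", tt)
    events_log <- list()
    initial_objects <- tibble::tibble(
      id = state$id, x = state$x, y = state$y, theta = state$theta,
      length = state_true_length(state), width = state$width,
      elongation = state_true_length(state) / state$width,
      n_branches = state$n_branches,
      green = state$green, red = state$green * state$ratio,
      ratio = state$ratio, area = state_true_area(state)
    )
    dt <- config$frame_interval
    step_sd <- sqrt(2 * params$diffusion * dt)
    for (t in seq_len(tt)) {
      counts[t] <- nrow(state)
      positions[[t]] <- tibble::tibble(frame = t, id = state$id,
                                       x = state$x, y = state$y)
      g_exp <- blur_gaussian(render_state(state, config, "green"),
                             params$psf_sigma)
      r_exp <- blur_gaussian(render_state(state, config, "red"),
                             params$psf_sigma)
      green[, , t] <- apply_noise(g_exp, params, config)
      red[, , t] <- apply_noise(r_exp, params, config)
      if (t == tt) break
      # motion step t -> t + 1
      n <- nrow(state)
      state$x <- state$x + params$drift[1] * dt + stats::rnorm(n, 0, step_sd)
      state$y <- state$y + params$drift[2] * dt + stats::rnorm(n, 0, step_sd)
      # events on the transition t -> t + 1
      if (!is.null(sched)) {
        todo <- sched[sched$frame == t, , drop = FALSE]
        for (e in seq_len(nrow(todo))) {
          ids <- unlist(todo$ids[e])
          if (!all(ids %in% state$id)) {
            stop(sprintf("event at frame %d references unknown id(s): %s",
                         t, paste(setdiff(ids, state$id), collapse = ", ")))
          }
          if (todo$type[e] == "fusion") {
            stopifnot(length(ids) == 2L)
            state <- apply_fusion(state, ids)
          } else {
            stopifnot(length(ids) == 1L)
            state <- apply_fission(state, ids,
                                   params$fission_gap * config$pixel_size)
          }
          events_log[[length(events_log) + 1L]] <-
            tibble::tibble(frame = t, type = todo$type[e], ids = list(ids))
        }
      } else if (params$event_rate > 0) {
        # simple unbranched candidates; one pass per transition
        cand <- state$id[state$n_branches == 1L]
        hits <- cand[stats::runif(length(cand)) < params$event_rate]
        for (id in hits) {
          if (!id %in% state$id) next  # consumed by an earlier event this step
          if (stats::runif(1) < 0.5 && nrow(state) >= 2L) {
            # fuse with the nearest other object
            i <- which(state$id == id)
            d <- sqrt((state$x - state$x[i])^2 + (state$y - state$y[i])^2)
            d[i] <- Inf
            j <- which.min(d)
            ids <- c(id, state$id[j])
            state <- apply_fusion(state, ids)
            events_log[[length(events_log) + 1L]] <-
              tibble::tibble(frame = t, type = "fusion", ids = list(ids))
          } else {
            state <- apply_fission(state, id,
                                   params$fission_gap * config$pixel_size)
            events_log[[length(events_log) + 1L]] <-
              tibble::tibble(frame = t, type = "fission", ids = list(id))
          }
        }
      }
    }
    events <- if (length(events_log)) dplyr::bind_rows(events_log) else
      tibble::tibble(frame = integer(), type = character(), ids = list())
    stack <- structure(
      list(green = green, red = red, config = config, cell_id = cell_id,
           condition = condition, timepoint = timepoint),
      class = "frame_stack"
    )
    truth <- structure(
      list(objects = initial_objects, events = events, counts = counts,
           positions = dplyr::bind_rows(positions),
           motion = list(diffusion = params$diffusion, drift = params$drift),
           params = params, seed = as.integer(seed)),
      class = "mito_ground_truth"
    )
    list(stack = stack, truth = truth)
  })
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf(
    "<frame_stack> cell %s | %s | %s | %d frames %dx%d px | %.3f um/px\n",
    x$cell_id, x$condition, x$timepoint, dim(x$green)[3],
    dim(x$green)[1], dim(x$green)[2], x$config$pixel_size))
  invisible(x)
}

#' Simulate one cell across baseline and post-treatment timepoints
#'
#' Generates independent fields at BL, 6 h and 24 h from a baseline parameter
#' set with per-timepoint multiplicative shifts, mirroring a
#' treatment-response design: the ground-truth log change of a shifted
#' parameter at a timepoint equals the log of its shift.
#'
#' @param config an [acquisition_config()].
#' @param params baseline [field_params()].
#' @param effect_spec named list with elements `"6h"` and/or `"24h"`, each a
#'   named numeric vector of multiplicative shifts (> 0). Supported names:
#'   `redox_ratio`, `length`, `width`, `intensity`, `event_rate`, `diffusion`,
#'   `drift`. Missing entries shift by 1 (no effect).
#' @param seed integer seed; per-timepoint sub-seeds are derived from it.
#' @param cell_id,condition labels carried on all three stacks.
#' @param timepoints timepoints to simulate; must include `"BL"`. Defaults to
#'   the full baseline / 6 h / 24 h design.
#' @return a list with `stacks` and `truths` (named lists over `timepoints`)
#'   and `effects` (the shift table actually applied).
#' @export
simulate_timepoint_series <- function(config, params = field_params(),
                                      effect_spec = list(), seed,
                                      cell_id = "cell_1",
                                      condition = "control",
                                      timepoints = c("BL", "6h", "24h")) {
  stopifnot(!missing(seed), "BL" %in% timepoints,
            all(timepoints %in% c("BL", "6h", "24h")))
  tps <- timepoints
  bad <- setdiff(names(effect_spec), c("6h", "24h"))
  if (length(bad)) stop("effect_spec names must be '6h'/'24h'")
  for (tp in names(effect_spec)) {
    stopifnot(all(effect_spec[[tp]] > 0))
  }
  shift_params <- function(p, shifts) {
    get <- function(nm) if (nm %in% names(shifts)) shifts[[nm]] else 1
    p$ratio_meanlog <- p$ratio_meanlog + log(get("redox_ratio"))
    p$length_meanlog <- p$length_meanlog + log(get("length"))
    p$width_meanlog <- p$width_meanlog + log(get("width"))
    p$green_meanlog <- p$green_meanlog + log(get("intensity"))
    p$event_rate <- p$event_rate * get("event_rate")
    p$diffusion <- p$diffusion * get("diffusion")
    p$drift <- p$drift * get("drift")
    p
  }
  stacks <- list()
  truths <- list()
  for (k in seq_along(tps)) {
    tp <- tps[k]
    p <- if (tp %in% names(effect_spec))
      shift_params(params, as.list(effect_spec[[tp]])) else params
    sim <- simulate_field(config, p, seed = as.integer(seed) + (k - 1L),
                          cell_id = cell_id, condition = condition,
                          timepoint = tp)
    stacks[[tp]] <- sim$stack
    truths[[tp]] <- sim$truth
  }
  list(stacks = stacks, truths = truths, effects = effect_spec)
}

#' Simulate a nanoparticle-tracking size sample
#'
#' Draws particle diameters (nm) from a lognormal mixture, emulating an NTA
#' export for an extracellular-vesicle preparation. Components are
#' parameterized by their modal diameter and log-sd
#' (`meanlog = log(mode) + sdlog^2`).
#'
#' @param n number of particles (>= 1).
#' @param mixture data frame with columns `mode` (nm), `sdlog`, `weight`
#'   (weights must sum to 1). The default is a two-component small/large EV
#'   mixture (modes 90 and 220 nm).
#' @param seed integer seed.
#' @param label,condition sample annotations.
#' @return a `particle_sample`: list with `diameters` (nm), `label`,
#'   `condition`.
#' @export
simulate_particle_sample <- function(n,
                                     mixture = data.frame(
                                       mode = c(90, 220),
                                       sdlog = c(0.35, 0.30),
                                       weight = c(0.7, 0.3)),
                                     seed, label = "sample",
                                     condition = "control") {
  if (length(n) != 1L || n < 1) stop("n must be a positive count")
  stopifnot(all(c("mode", "sdlog", "weight") %in% names(mixture)),
            all(mixture$mode > 0), all(mixture$sdlog >= 0),
            abs(sum(mixture$weight) - 1) < 1e-8, !missing(seed))
  withr::with_seed(as.integer(seed), {
    comp <- sample.int(nrow(mixture), n, replace = TRUE,
                       prob = mixture$weight)
    meanlog <- log(mixture$mode) + mixture$sdlog^2
    d <- stats::rlnorm(n, meanlog[comp], mixture$sdlog[comp])
    structure(list(diameters = d, label = label, condition = condition),
              class = "particle_sample")
  })
}

#' Export ground truth as text files
#'
#' Writes the simulator's ground truth as `ground_truth.json` (objects, motion,
#' per-frame counts) and `events.csv` (frame, type, ids) under `dir`.
#'
#' @param truth a `mito_ground_truth`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
export_ground_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "mito_ground_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt_path <- file.path(dir, "ground_truth.json")
  ev_path <- file.path(dir, "events.csv")
  jsonlite::write_json(
    list(objects = truth$objects, counts = truth$counts,
         motion = truth$motion, seed = truth$seed),
    gt_path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  ev <- truth$events
  ev_flat <- data.frame(
    frame = ev$frame, type = ev$type,
    ids = vapply(ev$ids, function(x) paste(x, collapse = ";"), character(1)))
  utils::write.csv(ev_flat, ev_path, row.names = FALSE)
  invisible(c(gt_path, ev_path))
}
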