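# Independent oracles used to check the package's primitives: a brute-force
# flood fill for connected components, an exhaustive between-class-variance
# search for the Otsu threshold, and exhaustive matching enumeration for the
# track-linking assignment.

# 8-connected flood fill, labels assigned in column-major first-pixel order
# (the same canonical order the package uses).
flood_fill_label <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      lab[i, j] <- cur
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          ni <- p[1] + di
          nj <- p[2] + dj
          if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
              mask[ni, nj] && lab[ni, nj] == 0L) {
            lab[ni, nj] <- cur
            stack[[length(stack) + 1L]] <- c(ni, nj)
          }
        }
      }
    }
  }
  lab
}

# Exhaustive Otsu: try every histogram cut, computing the between-class
# variance directly from the two pixel groups.
otsu_exhaustive <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  lo <- min(x)
  hi <- max(x)
  if (hi <= lo) return(NA_real_)
  bins <- pmin(floor((x - lo) / (hi - lo) * n_bins), n_bins - 1L)
  best <- -Inf
  best_thr <- NA_real_
  for (k in seq_len(n_bins - 1L)) {
    bg <- bins <= (k - 1L)
    w0 <- mean(bg)
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    sb <- w0 * w1 * (mean(bins[bg]) - mean(bins[!bg]))^2
    if (sb > best) {
      best <- sb
      best_thr <- lo + k * (hi - lo) / n_bins
    }
  }
  best_thr
}

# All injective partial matchings of rows 1..n1 to columns 1..n2 (0 = no
# match), as a list of integer vectors.
enumerate_matchings <- function(n1, n2) {
  out <- list()
  rec <- function(i, m, used) {
    if (i > n1) {
      out[[length(out) + 1L]] <<- m
      return(invisible())
    }
    rec(i + 1L, c(m, 0L), used)
    for (j in seq_len(n2)) {
      if (!used[j]) {
        u <- used
        u[j] <- TRUE
        rec(i + 1L, c(m, j), u)
      }
    }
  }
  rec(1L, integer(0), rep(FALSE, n2))
  out
}

# Minimum-cost frame-to-frame matching by exhaustive enumeration, under the
# same objective the tracker uses: distance per link (forbidden above the
# gate), gate cost per unmatched object on either side.
brute_force_link <- function(a, b, gate) {
  n1 <- nrow(a)
  n2 <- nrow(b)
  d <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  best_cost <- Inf
  best <- NULL
  for (m in enumerate_matchings(n1, n2)) {
    cost <- 0
    ok <- TRUE
    for (i in seq_len(n1)) {
      if (m[i] == 0L) {
        cost <- cost + gate
      } else if (d[i, m[i]] > gate) {
        ok <- FALSE
        break
      } else {
        cost <- cost + d[i, m[i]]
      }
    }
    if (!ok) next
    cost <- as.numeric(cost) + gate * (n2 - sum(m > 0L))
    if (cost < best_cost) {
      best_cost <- cost
      best <- m
    }
  }
  list(cost = best_cost, match = best)
}

# Exhaustive linear assignment (square/rectangular, n <= m) over all
# permutations, for checking the Hungarian solver.
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  cols <- utils::combn(m, n, simplify = FALSE)
  best <- Inf
  best_m <- NULL
  for (cs in cols) {
    perms <- all_perms(cs)
    for (p in perms) {
      v <- sum(cost[cbind(seq_len(n), p)])
      if (v < best) {
        best <- v
        best_m <- p
      }
    }
  }
  list(cost = best, match = best_m)
}

all_perms <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

# Minimal per-frame object container accepted by link_tracks().
fake_frame <- function(row, col) {
  list(objects = tibble::tibble(label = seq_along(row), row = row, col = col),
       n_objects = length(row))
}

# Random blob mask on a small grid: thresholded smoothed noise.
random_blob_mask <- function(h, w, density = 0.35) {
  img <- matrix(stats::runif(h * w), h, w)
  img <- mitomorph:::blur_gaussian(img, 1.2)
  img > stats::quantile(img, 1 - density)
}

# Extract the (frame t label -> frame t+1 label) link set from link_tracks
# output, for comparison with the brute-force matcher.
links_between <- function(tracks, t) {
  a <- tracks[tracks$frame == t, c("track_id", "label")]
  b <- tracks[tracks$frame == t + 1L, c("track_id", "label")]
  m <- merge(a, b, by = "track_id", suffixes = c("_a", "_b"))
  m <- m[order(m$label_a), , drop = FALSE]
  cbind(m$label_a, m$label_b)
}
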