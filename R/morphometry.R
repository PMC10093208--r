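# Per-mitochondrion morphometry and redox-state ratio, measured on the first
# frame of each sequence, plus the per-cell summary with its quality gate
# (a minimum number of mitochondria per cell).

#' Elongation factor
#'
#' Length-to-width ratio of a mitochondrion; 1 for a round object, large for
#' a filamentous one.
#'
#' @param length,width in the same units; `width` must be > 0.
#' @return `length / width`.
#' @export
elongation_factor <- function(length, width) {
  if (any(width <= 0)) stop("width must be > 0")
  length / width
}

#' Redox-state ratio
#'
#' Mean red (oxidized reporter) over mean green (newly synthesized reporter)
#' intensity within one object's mask.
#'
#' @param mean_red,mean_green channel means over the object pixels;
#'   `mean_green` must be > 0.
#' @return `mean_red / mean_green`.
#' @export
redox_ratio <- function(mean_red, mean_green) {
  if (any(mean_green <= 0)) stop("mean_green must be > 0")
  mean_red / mean_green
}

# --- skeletonization --------------------------------------------------------

# Zhang-Suen thinning. Operates on a logical matrix; vectorized over pixels
# via shifted copies of the padded image.
#' Skeletonize a binary mask
#'
#' Morphological thinning (Zhang-Suen) down to a 1-px-wide, 8-connected
#' skeleton.
#'
#' @param mask logical matrix.
#' @return logical matrix of the same size.
#' @export
skeletonize <- function(mask) {
  m <- mask != 0
  h <- nrow(m)
  w <- ncol(m)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  shift <- function(p, dr, dc) p[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc]
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      inner <- pad[2:(h + 1L), 2:(w + 1L)]
      p2 <- shift(pad, -1L, 0L); p3 <- shift(pad, -1L, 1L)
      p4 <- shift(pad, 0L, 1L);  p5 <- shift(pad, 1L, 1L)
      p6 <- shift(pad, 1L, 0L);  p7 <- shift(pad, 1L, -1L)
      p8 <- shift(pad, 0L, -1L); p9 <- shift(pad, -1L, -1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      # number of 0 -> 1 transitions in the ordered neighbor ring
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (step == 1L) {
        cond <- inner & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- inner & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        inner[cond] <- FALSE
        pad[2:(h + 1L), 2:(w + 1L)] <- inner
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pad[2:(h + 1L), 2:(w + 1L)]
}

# Build the skeleton pixel graph: vertices = skeleton pixels, edges between
# 8-neighbors weighted by step length (1 or sqrt(2)).
skeleton_graph <- function(skel, reduce = TRUE) {
  h <- nrow(skel)
  idx <- which(skel)
  n <- length(idx)
  if (n == 0L) return(NULL)
  node <- integer(length(skel))
  node[idx] <- seq_len(n)
  r <- ((idx - 1L) %% h) + 1L
  c <- ((idx - 1L) %/% h) + 1L
  w <- ncol(skel)
  at <- function(rr, cc) {
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    out <- logical(length(rr))
    out[ok] <- skel[(cc[ok] - 1L) * h + rr[ok]]
    out
  }
  edges <- NULL
  wts <- NULL
  for (o in list(c(0L, 1L, 1), c(1L, 0L, 1), c(1L, 1L, sqrt(2)),
                 c(-1L, 1L, sqrt(2)))) {
    rn <- r + o[1]
    cn <- c + o[2]
    ok <- rn >= 1L & rn <= h & cn >= 1L & cn <= w
    nidx <- (cn[ok] - 1L) * h + rn[ok]
    both <- skel[nidx]
    a <- idx[ok][both]
    b <- nidx[both]
    if (reduce && o[1] != 0L && o[2] != 0L && length(a)) {
      # diagonal edge: skip when an orthogonal skeleton pixel already joins
      # the pair, so thinning staircases cannot create spurious junctions
      ra <- ((a - 1L) %% h) + 1L
      ca <- ((a - 1L) %/% h) + 1L
      redundant <- at(ra, ca + o[2]) | at(ra + o[1], ca)
      a <- a[!redundant]
      b <- b[!redundant]
    }
    edges <- rbind(edges, cbind(node[a], node[b]))
    wts <- c(wts, rep(o[3], length(a)))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L) {
    g <- igraph::add_edges(g, t(edges), weight = wts)
  }
  igraph::V(g)$row <- r
  igraph::V(g)$col <- c
  g
}

# Geodesic length (px) of the skeleton's longest path. For path-like
# skeletons this is the endpoint-to-endpoint geodesic; cycles fall back to
# the graph diameter. Returns the length and the path's pixel coordinates
# (rows of (row, col)), ordered end to end.
skeleton_longest_path_info <- function(skel) {
  # full 8-connected graph: diagonal steps keep their Euclidean length
  g <- skeleton_graph(skel, reduce = FALSE)
  if (is.null(g) || igraph::vcount(g) == 1L) {
    return(list(length = 0, path = NULL))
  }
  deg <- igraph::degree(g)
  ends <- which(deg <= 1L)
  from <- if (length(ends) >= 2L) ends else seq_len(igraph::vcount(g))
  d <- igraph::distances(g, v = from, to = from)
  d[!is.finite(d)] <- 0
  best <- which(d == max(d), arr.ind = TRUE)[1, ]
  v1 <- from[best[1]]
  v2 <- from[best[2]]
  if (v1 == v2) return(list(length = 0, path = NULL))
  sp <- igraph::shortest_paths(g, from = v1, to = v2)$vpath[[1]]
  list(length = max(d),
       path = cbind(igraph::V(g)$row[as.integer(sp)],
                    igraph::V(g)$col[as.integer(sp)]))
}

skeleton_longest_path <- function(skel) {
  skeleton_longest_path_info(skel)$length
}

#' Count skeleton branches of an object
#'
#' Skeletonizes the object's mask and counts the skeleton segments between
#' endpoints and junctions: a junction-free skeleton (straight or curved
#' path, isolated pixel) counts 1; a star of k arms counts k. Short spurs
#' (thinning artifacts) below `prune_px` are discarded before counting.
#'
#' @param pixels two-column matrix of (row, col) object pixel coordinates, or
#'   a logical mask matrix.
#' @param prune_px minimum arm length (px) for a terminal segment to count.
#' @return integer branch count (>= 1).
#' @export
count_branches <- function(pixels, prune_px = 3) {
  mask <- pixels_to_mask(pixels)
  skel <- skeletonize(mask$mask)
  g <- skeleton_graph(skel)
  if (is.null(g) || igraph::vcount(g) <= 1L) return(1L)
  deg <- igraph::degree(g)
  junctions <- which(deg >= 3L)
  if (length(junctions) == 0L) return(1L)
  # the medial axis of a star with uneven arm angles contains short trunk
  # segments between split junctions (length about w / (2 tan(a/2)) for arm
  # separation a); segments shorter than the object's own width are absorbed
  # into the junction instead of counted
  s_len <- skeleton_longest_path(skel)
  area_px <- sum(mask$mask)
  w_est <- if (s_len > 0)
    (-s_len + sqrt(s_len^2 + pi * area_px)) / (pi / 2) else sqrt(area_px)
  g2 <- igraph::delete_vertices(g, junctions)
  comp <- igraph::components(g2)
  if (comp$no == 0L) return(1L)
  memb <- comp$membership
  # map back to original vertex ids through the stored pixel coordinates
  key <- paste(igraph::V(g)$row, igraph::V(g)$col)
  orig <- match(paste(igraph::V(g2)$row, igraph::V(g2)$col), key)
  n_seg <- 0L
  for (ci in seq_len(comp$no)) {
    vs <- which(memb == ci)
    if (length(vs) == 1L) {
      seg_len <- 0
    } else {
      sub <- igraph::induced_subgraph(g2, vs)
      dd <- igraph::distances(sub)
      dd[!is.finite(dd)] <- 0
      seg_len <- max(dd)
    }
    is_leaf <- any(deg[orig[vs]] <= 1L)
    if (is_leaf) {
      if (seg_len + 1 < prune_px) next          # thinning spur
    } else {
      if (seg_len + 1 < w_est) next             # split-junction trunk
    }
    n_seg <- n_seg + 1L
  }
  max(n_seg, 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Accept either a (row, col) coordinate matrix or a logical mask; return a
# cropped mask plus the crop offset.
pixels_to_mask <- function(pixels) {
  if (is.logical(pixels) || (is.matrix(pixels) && ncol(pixels) != 2L)) {
    idx <- which(pixels != 0, arr.ind = TRUE)
    if (nrow(idx) == 0L) stop("empty object")
    pixels <- idx
  }
  stopifnot(is.matrix(pixels), ncol(pixels) == 2L, nrow(pixels) >= 1L)
  r0 <- min(pixels[, 1]) - 2L
  c0 <- min(pixels[, 2]) - 2L
  mask <- matrix(FALSE,
                 max(pixels[, 1]) - r0 + 2L,
                 max(pixels[, 2]) - c0 + 2L)
  mask[cbind(pixels[, 1] - r0, pixels[, 2] - c0)] <- TRUE
  list(mask = mask, offset = c(r0, c0))
}

# Sum of the two end extensions from the skeleton path tips to the farthest
# mask pixel along the outward local path direction (projection, px).
path_end_extensions <- function(path, pixels) {
  n <- nrow(path)
  ext <- 0
  for (end in c(1L, 2L)) {
    if (end == 1L) {
      e <- path[1, ]
      ref <- path[min(4L, n), ]
    } else {
      e <- path[n, ]
      ref <- path[max(1L, n - 3L), ]
    }
    d <- e - ref
    nrm <- sqrt(sum(d^2))
    if (nrm == 0) next
    d <- d / nrm
    proj <- (pixels[, 1] - e[1]) * d[1] + (pixels[, 2] - e[2]) * d[2]
    ext <- ext + max(0, max(proj))
  }
  ext
}

# Ellipse-style major axis length from the pixel second moments: for a solid
# segment of length L the coordinate variance along the axis is L^2 / 12.
moment_major_axis <- function(pixels) {
  if (nrow(pixels) == 1L) return(1)
  v <- stats::cov(pixels + 0)
  # add the finite pixel footprint
  v <- v + diag(1 / 12, 2)
  sqrt(12 * max(eigen(v, symmetric = TRUE)$values))
}

#' Measure one mitochondrion
#'
#' Computes area, skeleton-based length and width, elongation factor, branch
#' count, channel means and redox-state ratio for one labeled object.
#'
#' Length is the geodesic length of the skeleton's longest path corrected for
#' the thinning erosion at the object's ends: with skeleton length `s` (px)
#' and pixel area `A`, the width `w` solves the capsule identity
#' `A = s * w + (pi/4) w^2` and the reported length is `s + w`. Objects too
#' small to skeletonize (< 9 px) fall back to the second-moment major axis.
#'
#' @param pixels two-column (row, col) matrix of the object's pixels.
#' @param green,red full-frame intensity matrices.
#' @param pixel_size um per px.
#' @param object_id,cell_id,timepoint annotations copied into the output row.
#' @return one-row tibble with fields `object_id`, `area` (um^2), `length`,
#'   `width` (um), `elongation`, `n_branches`, `mean_green`, `mean_red`,
#'   `redox_ratio`, `centroid_x`, `centroid_y` (um), `ratio_defined`.
#' @export
measure_object <- function(pixels, green, red, pixel_size,
                           object_id = 1L, cell_id = "cell_1",
                           timepoint = "BL") {
  stopifnot(is.matrix(pixels), ncol(pixels) == 2L, nrow(pixels) >= 1L,
            pixel_size > 0)
  n_px <- nrow(pixels)
  idx <- cbind(pixels[, 1], pixels[, 2])
  mean_green <- mean(green[idx])
  mean_red <- mean(red[idx])
  area_px <- n_px
  info <- list(length = 0, path = NULL)
  if (n_px >= 9L) {
    pm <- pixels_to_mask(pixels)
    skel <- skeletonize(pm$mask)
    info <- skeleton_longest_path_info(skel)
    if (!is.null(info$path)) {
      # back to frame coordinates
      info$path <- cbind(info$path[, 1] + pm$offset[1],
                         info$path[, 2] + pm$offset[2])
    }
  }
  s <- info$length
  if (s > 0 && nrow(info$path) >= 2L) {
    # extend the skeleton to the mask boundary at both ends along the local
    # path direction: robust to the orientation-dependent erosion of
    # thinning (diagonal ends lose more than one half-width). Extensions are
    # measured to pixel centers; half a pixel accounts for the footprint.
    len_px <- s + path_end_extensions(info$path, pixels) + 0.5
    # capsule identity A = (L - w) w + (pi/4) w^2, solved for w given L
    a <- pi / 4 - 1
    disc <- len_px^2 + 4 * a * area_px
    w_px <- if (disc > 0) (-len_px + sqrt(disc)) / (2 * a) else
      area_px / len_px
    if (w_px <= 0 || w_px > len_px) w_px <- area_px / len_px
  } else {
    len_px <- moment_major_axis(pixels)
    w_px <- area_px / len_px
    if (w_px > len_px) {
      len_px <- sqrt(area_px)
      w_px <- len_px
    }
  }
  if (len_px < w_px) {
    len_px <- w_px <- sqrt(area_px)
  }
  nb <- if (n_px >= 9L) count_branches(pixels) else 1L
  length_um <- len_px * pixel_size
  width_um <- w_px * pixel_size
  ratio_defined <- mean_green > 0
  tibble::tibble(
    cell_id = cell_id, timepoint = timepoint, object_id = object_id,
    area = area_px * pixel_size^2,
    length = length_um, width = width_um,
    elongation = length_um / width_um,
    n_branches = nb,
    mean_green = mean_green, mean_red = mean_red,
    redox_ratio = ifelse(ratio_defined, mean_red / mean_green, NA_real_),
    centroid_x = mean(pixels[, 2]) * pixel_size,
    centroid_y = mean(pixels[, 1]) * pixel_size,
    ratio_defined = ratio_defined
  )
}

#' Measure every object of a labeled frame
#'
#' @param labeled a `labeled_objects` from [label_and_filter()] or
#'   [segment_frame()].
#' @param green,red intensity matrices of the measured frame.
#' @param pixel_size um per px.
#' @param cell_id,timepoint annotations.
#' @return tibble with one [measure_object()] row per surviving object.
#' @export
measure_frame <- function(labeled, green, red, pixel_size,
                          cell_id = "cell_1", timepoint = "BL") {
  stopifnot(inherits(labeled, "labeled_objects"))
  k <- labeled$n_objects
  if (k == 0L) {
    return(measure_object(matrix(c(1L, 1L), 1), green, red, pixel_size)[0, ])
  }
  idx <- which(labeled$labels > 0L)
  lab <- labeled$labels[idx]
  h <- nrow(labeled$labels)
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  out <- vector("list", k)
  for (i in seq_len(k)) {
    sel <- lab == i
    out[[i]] <- measure_object(cbind(rows[sel], cols[sel]), green, red,
                               pixel_size, object_id = i,
                               cell_id = cell_id, timepoint = timepoint)
  }
  dplyr::bind_rows(out)
}

#' Summarize a cell's mitochondria
#'
#' Per-parameter mean and median over a cell's measured mitochondria, with
#' the quality gate `qc_pass = n_mitochondria >= qc_min` (by default fifty
#' mitochondria per cell). Objects with undefined redox ratio are excluded
#' from the ratio summaries only.
#'
#' @param features tibble of [measure_object()] rows sharing one cell and
#'   timepoint.
#' @param qc_min minimum mitochondria per cell for `qc_pass`.
#' @param condition condition label copied into the record.
#' @return one-row tibble (`cell_record`): `cell_id`, `condition`,
#'   `timepoint`, `n_mitochondria`, `qc_pass`, and `<param>_mean` /
#'   `<param>_median` for area, length, width, elongation, n_branches,
#'   redox_ratio.
#' @export
summarize_cell <- function(features, qc_min = 50L, condition = "control") {
  if (nrow(features) == 0L) stop("empty feature list")
  stopifnot(length(unique(features$cell_id)) == 1L,
            length(unique(features$timepoint)) == 1L)
  pars <- c("area", "length", "width", "elongation", "n_branches",
            "redox_ratio")
  rec <- tibble::tibble(
    cell_id = features$cell_id[1],
    condition = condition,
    timepoint = features$timepoint[1],
    n_mitochondria = nrow(features),
    qc_pass = nrow(features) >= qc_min
  )
  for (p in pars) {
    v <- features[[p]]
    if (p == "redox_ratio") v <- v[is.finite(v)]
    rec[[paste0(p, "_mean")]] <- mean(v)
    rec[[paste0(p, "_median")]] <- stats::median(v)
  }
  rec
}
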