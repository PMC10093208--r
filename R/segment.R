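# Per-frame segmentation: thresholding (Otsu or fixed), 8-connected
# component labeling, and the three object filters used on biosensor
# sequences: size, mean intensity, and removal of objects truncated by the
# region-of-interest boundary.

#' Segmentation parameters
#'
#' @param threshold_method `"otsu"` (between-class-variance maximization on a
#'   256-bin histogram) or `"fixed"`.
#' @param fixed_threshold intensity threshold, required when
#'   `threshold_method = "fixed"`; pixels `>= fixed_threshold` are foreground.
#' @param min_area,max_area object size filter, px. Components outside
#'   `[min_area, max_area]` are removed.
#' @param min_mean_intensity objects with mean intensity below this are
#'   removed. The default 0 applies no extra intensity filter beyond the
#'   threshold itself.
#' @param border_margin px inset defining the default rectangular ROI; any
#'   object touching or crossing the ROI boundary is removed as truncated.
#' @param roi optional explicit ROI `c(row_min, row_max, col_min, col_max)`
#'   (inclusive, px); overrides `border_margin`.
#' @return a `segmentation_params` object.
#' @export
segmentation_params <- function(threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_area = 4L, max_area = Inf,
                                min_mean_intensity = 0,
                                border_margin = 1L, roi = NULL) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" && is.null(fixed_threshold)) {
    stop("fixed_threshold must be given when threshold_method = 'fixed'")
  }
  stopifnot(min_area >= 1, max_area > min_area, min_mean_intensity >= 0,
            border_margin >= 0)
  if (!is.null(roi)) stopifnot(length(roi) == 4L, roi[1] <= roi[2],
                               roi[3] <= roi[4])
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_area = min_area, max_area = max_area,
                 min_mean_intensity = min_mean_intensity,
                 border_margin = as.integer(border_margin), roi = roi),
            class = "segmentation_params")
}

#' Otsu threshold of an intensity image
#'
#' Maximizes the between-class variance over a 256-bin histogram of the
#' intensity range and returns the lower edge of the chosen bin, so that
#' `pixel >= threshold` defines foreground.
#'
#' @param x numeric vector or matrix of intensities.
#' @param n_bins histogram resolution.
#' @return the threshold, or `NA_real_` when the image is constant
#'   (degenerate histogram).
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  lo <- min(x)
  hi <- max(x)
  if (hi <= lo) return(NA_real_)
  bins <- pmin(floor((x - lo) / (hi - lo) * n_bins), n_bins - 1L)
  h <- tabulate(bins + 1L, nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(n_bins) - 1L))
  mu_t <- mu[n_bins]
  # between-class variance for a cut after bin k (classes [0..k], [k+1..])
  k <- seq_len(n_bins - 1L)
  denom <- omega[k] * (1 - omega[k])
  sigma_b <- ifelse(denom > 0, (mu_t * omega[k] - mu[k])^2 / denom, -Inf)
  if (all(!is.finite(sigma_b))) return(NA_real_)
  k_star <- which.max(sigma_b)
  # threshold = lower edge of the first foreground bin
  lo + (k_star) * (hi - lo) / n_bins
}

#' Binarize one frame
#'
#' @param frame H x W intensity matrix.
#' @param params a [segmentation_params()].
#' @return logical H x W mask with attribute `threshold` (the value used) and
#'   `degenerate` (TRUE when Otsu found no contrast; the mask is then empty
#'   and a warning is raised).
#' @export
binarize_channel <- function(frame, params = segmentation_params()) {
  stopifnot(is.matrix(frame), length(frame) > 0)
  if (params$threshold_method == "fixed") {
    thr <- params$fixed_threshold
    degenerate <- FALSE
  } else {
    thr <- otsu_threshold(frame)
    degenerate <- is.na(thr)
  }
  if (degenerate) {
    warning("degenerate threshold: constant frame; returning empty mask")
    mask <- matrix(FALSE, nrow(frame), ncol(frame))
    thr <- NA_real_
  } else {
    mask <- frame >= thr
  }
  attr(mask, "threshold") <- thr
  attr(mask, "degenerate") <- degenerate
  mask
}

# 8-connected component labeling via a pixel-adjacency graph. Returns an
# integer matrix; labels are ordered by first (column-major) pixel.
label_components <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  labels <- matrix(0L, h, w)
  fg <- which(mask)
  if (length(fg) == 0L) return(labels)
  node <- integer(h * w)
  node[fg] <- seq_along(fg)
  r <- ((fg - 1L) %% h) + 1L
  c <- ((fg - 1L) %/% h) + 1L
  edge_list <- list()
  # neighbor offsets covering each unordered pair once: E, S, SE, SW
  for (o in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))) {
    rn <- r + o[1]
    cn <- c + o[2]
    ok <- rn >= 1L & rn <= h & cn >= 1L & cn <= w
    idx <- fg[ok]
    nidx <- (cn[ok] - 1L) * h + rn[ok]
    both <- mask[nidx]
    edge_list[[length(edge_list) + 1L]] <-
      cbind(node[idx[both]], node[nidx[both]])
  }
  edges <- do.call(rbind, edge_list)
  if (is.null(edges) || nrow(edges) == 0L) {
    labels[fg] <- seq_along(fg)
    return(labels)
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # renumber by first occurrence in column-major order
  relabel <- integer(max(memb))
  relabel[unique(memb)] <- seq_along(unique(memb))
  labels[fg] <- relabel[memb]
  labels
}

#' Label a binary mask and apply the object filters
#'
#' Labels 8-connected components, then removes components whose area lies
#' outside `[min_area, max_area]`, whose mean intensity (over `frame`) is
#' below `min_mean_intensity`, or which are truncated by the ROI boundary
#' (any object pixel outside the ROI, or 4-adjacent to a pixel outside it).
#' Survivors are renumbered 1..K.
#'
#' @param mask logical H x W matrix.
#' @param frame H x W intensity matrix used for the mean-intensity filter and
#'   the reported per-object mean.
#' @param params a [segmentation_params()].
#' @return a `labeled_objects` list: `labels` (H x W integer matrix),
#'   `objects` (tibble: label, area px, centroid row/col px, mean_intensity),
#'   `n_objects`, and the `roi` used.
#' @export
label_and_filter <- function(mask, frame, params = segmentation_params()) {
  stopifnot(is.matrix(mask), all(dim(mask) == dim(frame)))
  h <- nrow(mask)
  w <- ncol(mask)
  roi <- if (!is.null(params$roi)) as.integer(params$roi) else
    c(1L + params$border_margin, h - params$border_margin,
      1L + params$border_margin, w - params$border_margin)
  stopifnot(roi[1] >= 1, roi[2] <= h, roi[3] >= 1, roi[4] <= w)
  labels <- label_components(mask)
  k <- max(labels)
  if (k == 0L) {
    return(structure(list(labels = labels,
                          objects = tibble::tibble(
                            label = integer(), area = integer(),
                            row = numeric(), col = numeric(),
                            mean_intensity = numeric()),
                          n_objects = 0L, roi = roi),
                     class = "labeled_objects"))
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rr <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  area <- tabulate(lab, k)
  mean_int <- as.numeric(tapply(frame[idx], lab, mean))
  crow <- as.numeric(tapply(rr, lab, mean))
  ccol <- as.numeric(tapply(cc, lab, mean))
  # ROI-truncation: a pixel outside the ROI, or 4-adjacent to outside
  # (i.e. within 1 px of the boundary), marks its object as truncated
  outside <- rr < roi[1] | rr > roi[2] | cc < roi[3] | cc > roi[4]
  # abutting only counts where outside pixels exist beyond the ROI edge
  abutting <- (rr == roi[1] & roi[1] > 1L) | (rr == roi[2] & roi[2] < h) |
    (cc == roi[3] & roi[3] > 1L) | (cc == roi[4] & roi[4] < w)
  truncated <- unique(lab[outside | abutting])
  keep <- which(area >= params$min_area & area <= params$max_area &
                  mean_int >= params$min_mean_intensity)
  keep <- setdiff(keep, truncated)
  keep <- sort(keep)
  relabel <- integer(k)
  relabel[keep] <- seq_along(keep)
  new_labels <- matrix(0L, h, w)
  sel <- lab %in% keep
  new_labels[idx[sel]] <- relabel[lab[sel]]
  structure(list(
    labels = new_labels,
    objects = tibble::tibble(
      label = seq_along(keep), area = area[keep],
      row = crow[keep], col = ccol[keep],
      mean_intensity = mean_int[keep]),
    n_objects = length(keep), roi = roi),
    class = "labeled_objects")
}

#' Segment one dual-channel frame
#'
#' Binarizes the green and red channels independently, takes the union of the
#' two masks as the object definition (one object identity for the
#' ratio computation), and applies the object filters using the summed
#' intensity image.
#'
#' @param green,red H x W intensity matrices.
#' @param params a [segmentation_params()].
#' @return a `labeled_objects` (see [label_and_filter()]).
#' @export
segment_frame <- function(green, red, params = segmentation_params()) {
  mg <- suppressWarnings(binarize_channel(green, params))
  mr <- suppressWarnings(binarize_channel(red, params))
  label_and_filter(mg | mr, green + red, params)
}
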