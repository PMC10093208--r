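# Low-level raster helpers shared by the simulator and the segmentation code.
# Images are H x W numeric matrices; stacks are H x W x T arrays. Pixel (r, c)
# has its centre at coordinates (x = c, y = r) in pixel units, 1-based.

#' One-dimensional Gaussian kernel
#'
#' @param sigma standard deviation in pixels.
#' @param radius half-width of the kernel; defaults to `ceiling(3 * sigma)`.
#' @return numeric vector of length `2 * radius + 1` summing to 1.
#' @keywords internal
gaussian_kernel_1d <- function(sigma, radius = ceiling(3 * sigma)) {
  stopifnot(sigma > 0)
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Banded Toeplitz convolution matrix with renormalized edge rows, so that
# interior intensity is conserved exactly and edges do not darken. Cached per
# (n, sigma) since the simulator blurs many identically sized frames.
conv_cache <- new.env(parent = emptyenv())

conv_band_matrix <- function(n, kernel, sigma) {
  key <- sprintf("%d_%g", n, sigma)
  hit <- conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  radius <- (length(kernel) - 1L) / 2L
  m <- matrix(0, n, n)
  for (d in seq(-radius, radius)) {
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1L & j <= n
    m[cbind(i[ok], j[ok])] <- kernel[d + radius + 1L]
  }
  m <- m / rowSums(m)
  conv_cache[[key]] <- m
  m
}

#' Separable Gaussian blur of an image
#'
#' Used as the point-spread-function model of the simulator. Convolution is
#' linear, so blurring the per-channel expected images preserves the red/green
#' proportionality the generator imposes per object.
#'
#' @param img H x W numeric matrix.
#' @param sigma PSF standard deviation in pixels; `sigma <= 0` returns `img`.
#' @keywords internal
blur_gaussian <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel_1d(sigma)
  kr <- conv_band_matrix(nrow(img), k, sigma)
  kc <- conv_band_matrix(ncol(img), k, sigma)
  kr %*% img %*% kc
}

# Coverage patch of one capsule (segment of half-width w/2 with rounded caps).
# (x1, y1)-(x2, y2) is the core segment in pixel coordinates. Returns NULL
# when the bounding box misses the image, else list(rows, cols, patch) with
# patch in [0, 1] (half-pixel linear edge ramp as antialiasing).
capsule_patch <- function(h, w, x1, y1, x2, y2, width) {
  half <- width / 2
  r0 <- max(1L, floor(min(y1, y2) - half - 1))
  r1 <- min(h, ceiling(max(y1, y2) + half + 1))
  c0 <- max(1L, floor(min(x1, x2) - half - 1))
  c1 <- min(w, ceiling(max(x1, x2) + half + 1))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1
  cols <- c0:c1
  xx <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  yy <- matrix(rows, length(rows), length(cols))
  dx <- x2 - x1
  dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) {
    d <- sqrt((xx - x1)^2 + (yy - y1)^2)
  } else {
    t <- pmin(1, pmax(0, ((xx - x1) * dx + (yy - y1) * dy) / len2))
    d <- sqrt((xx - (x1 + t * dx))^2 + (yy - (y1 + t * dy))^2)
  }
  list(rows = rows, cols = cols, patch = pmin(1, pmax(0, half + 0.5 - d)))
}

# Add one capsule to an image (in-place accumulation of the coverage patch).
add_capsule <- function(img, x1, y1, x2, y2, width, amp) {
  p <- capsule_patch(nrow(img), ncol(img), x1, y1, x2, y2, width)
  if (is.null(p)) return(img)
  img[p$rows, p$cols] <- img[p$rows, p$cols] + amp * p$patch
  img
}
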