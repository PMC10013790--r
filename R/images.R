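# Shared raster helpers. Images are H x W x 3 double arrays in [0,1], masks
# are H x W matrices in {0,1}. On disk both are 8-bit PNG; masks use {0,255}
# but loaders accept {0,1} files too and normalize.

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

as_image3 <- function(x) {
  if (is.matrix(x)) x <- array(rep(x, 3L), c(dim(x), 3L))
  x
}

#' Read an RGB image from a PNG file
#'
#' Returns an H x W x 3 array with values in \[0,1\]. Grayscale images are
#' replicated across channels; an alpha channel is dropped.
#'
#' @param path path to a PNG file
#' @return numeric array, H x W x 3
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  a <- png::readPNG(path)
  if (is.matrix(a)) return(as_image3(a))
  if (dim(a)[3] == 2L) return(as_image3(a[, , 1L]))
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  a
}

#' Write an RGB image to a PNG file
#' @param img H x W x 3 array in \[0,1\] (values are clamped)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_image <- function(img, path) {
  png::writePNG(clamp01(as_image3(img)), path)
  invisible(path)
}

#' Read a binary mask from a PNG file
#'
#' Accepts masks stored as \{0,1\} or \{0,255\}; any nonzero pixel is
#' foreground.
#'
#' @param path path to a PNG file
#' @return H x W matrix in \{0,1\}
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  m <- png::readPNG(path)
  if (!is.matrix(m)) m <- m[, , 1L]
  (m > 0) * 1
}

#' Write a binary mask to an 8-bit PNG file (\{0,255\})
#' @param mask H x W matrix; nonzero means foreground
#' @param path output path
#' @return `path`, invisibly
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

# Zero-pad an image/mask on the bottom/right so both spatial dims are
# multiples of d. Returns list(x, h, w) with the original size for cropping.
pad_to_multiple <- function(x, d) {
  dm <- dim(x)
  h <- dm[1]; w <- dm[2]
  H <- as.integer(ceiling(h / d) * d)
  W <- as.integer(ceiling(w / d) * d)
  if (H == h && W == w) return(list(x = x, h = h, w = w))
  if (length(dm) == 2L) {
    out <- matrix(0, H, W)
    out[seq_len(h), seq_len(w)] <- x
  } else {
    out <- array(0, c(H, W, dm[3]))
    out[seq_len(h), seq_len(w), ] <- x
  }
  list(x = out, h = h, w = w)
}

crop_hw <- function(x, h, w) {
  if (is.matrix(x)) x[seq_len(h), seq_len(w), drop = FALSE]
  else x[seq_len(h), seq_len(w), , drop = FALSE]
}

# One exact quarter-turn (row/col transposition; the convention all
# rotation code in the package follows).
rot90_once <- function(m) t(m)[ncol(m):1, , drop = FALSE]

rotate_exact <- function(x, k) {
  k <- ((k %% 4) + 4) %% 4
  if (k == 0) return(x)
  f <- function(m) { for (i in seq_len(k)) m <- rot90_once(m); m }
  if (is.matrix(x)) return(f(x))
  chans <- lapply(seq_len(dim(x)[3]), function(c) f(x[, , c]))
  array(unlist(chans, use.names = FALSE), c(dim(chans[[1]]), dim(x)[3]))
}

# Sample x at fractional (row, col) grids via the compiled bilinear kernel;
# "none" snaps coordinates to the nearest pixel first.
warp_grid <- function(x, grid_r, grid_c, filter = "bilinear", fill = 0) {
  if (filter == "none") {
    grid_r <- round(grid_r)
    grid_c <- round(grid_c)
  }
  cpp_bilinear_warp(x, grid_r, grid_c, fill)
}

#' Rotate an image or mask, expanding the canvas to fit
#'
#' Multiples of 90 degrees are computed exactly by array transposition (the
#' resampling path is lossy at those angles); other angles use bilinear or
#' nearest-neighbour interpolation with zero fill.
#'
#' @param x H x W matrix or H x W x C array
#' @param angle rotation in degrees
#' @param filter "bilinear" (images) or "none" (nearest neighbour, masks)
#' @return the rotated array; its size grows to contain the rotated frame
#' @export
rotate_expand <- function(x, angle, filter = c("bilinear", "none")) {
  filter <- match.arg(filter)
  angle <- angle %% 360
  if (angle %% 90 == 0) return(rotate_exact(x, angle %/% 90))
  th <- angle * pi / 180
  h <- dim(x)[1]; w <- dim(x)[2]
  H <- ceiling(h * abs(cos(th)) + w * abs(sin(th)))
  W <- ceiling(h * abs(sin(th)) + w * abs(cos(th)))
  # inverse map: source = R(-theta) . (dest - dest_center) + src_center
  yc <- (H + 1) / 2; xc <- (W + 1) / 2
  sy <- (h + 1) / 2; sx <- (w + 1) / 2
  dy <- matrix(seq_len(H) - yc, H, W)
  dx <- matrix(seq_len(W) - xc, H, W, byrow = TRUE)
  grid_r <- cos(th) * dy + sin(th) * dx + sy - 1
  grid_c <- -sin(th) * dy + cos(th) * dx + sx - 1
  warp_grid(x, grid_r, grid_c, filter)
}

rotate_mask_expand <- function(mask, angle) {
  (rotate_expand(mask, angle, filter = "none") > 0.5) * 1
}

# Resize to nr x nc with center-aligned sampling and edge clamping.
resize_arr <- function(x, nr, nc, filter = "bilinear") {
  h <- dim(x)[1]; w <- dim(x)[2]
  rr <- (seq_len(nr) - 0.5) * h / nr - 0.5
  cc <- (seq_len(nc) - 0.5) * w / nc - 0.5
  rr <- pmin(h - 1, pmax(0, rr))
  cc <- pmin(w - 1, pmax(0, cc))
  warp_grid(x, matrix(rr, nr, nc), matrix(cc, nr, nc, byrow = TRUE), filter)
}

# Separable Gaussian smoothing with replicated edges; works at any size
# (displacement fields on small patches, image blur in color augmentation).
smooth_gauss <- function(m, sigma) {
  p <- max(1L, ceiling(2 * sigma))
  k <- stats::dnorm(-p:p, sd = sigma)
  cpp_smooth_sep(m, k / sum(k))
}

gblur_arr <- function(x, sigma) {
  if (is.matrix(x)) return(smooth_gauss(x, sigma))
  for (c in seq_len(dim(x)[3])) x[, , c] <- smooth_gauss(x[, , c], sigma)
  x
}

# Gaussian-smoothed random displacement warp (elastic deformation).
elastic_warp <- function(x, alpha, sigma, binary = FALSE) {
  dm <- dim(x)[1:2]
  dr <- smooth_gauss(matrix(stats::rnorm(prod(dm)), dm[1], dm[2]), sigma)
  dc <- smooth_gauss(matrix(stats::rnorm(prod(dm)), dm[1], dm[2]), sigma)
  nrm <- max(abs(c(dr, dc)), 1e-12)
  dr <- dr / nrm * alpha
  dc <- dc / nrm * alpha
  grid_r <- matrix(seq_len(dm[1]) - 1, dm[1], dm[2]) + dr
  grid_c <- matrix(seq_len(dm[2]) - 1, dm[1], dm[2], byrow = TRUE) + dc
  y <- cpp_bilinear_warp(x, grid_r, grid_c, 0)
  if (binary) (y > 0.5) * 1 else y
}

#' Apply the fixed sepia color transform
#' @param img H x W x 3 array in \[0,1\]
#' @return transformed image, clamped to \[0,1\]
#' @export
sepia <- function(img) {
  M <- matrix(c(0.393, 0.769, 0.189,
                0.349, 0.686, 0.168,
                0.272, 0.534, 0.131), 3, 3, byrow = TRUE)
  dm <- dim(img)
  flat <- matrix(img, ncol = 3L)
  clamp01(array(flat %*% t(M), dm))
}

#' Add i.i.d. Gaussian pixel noise
#' @param img H x W x 3 array in \[0,1\]
#' @param sd noise standard deviation on the \[0,1\] intensity scale
#' @return noisy image, clamped to \[0,1\]
#' @export
add_gaussian_noise <- function(img, sd = 0.05) {
  clamp01(img + array(stats::rnorm(length(img), 0, sd), dim(img)))
}

# Photometric jitter applied to composite images (never to masks):
# brightness/contrast, per-channel gain, optional blur and noise. Uses the
# ambient RNG stream.
color_augment <- function(img) {
  b <- stats::runif(1, 0.85, 1.15)
  ct <- stats::runif(1, 0.85, 1.15)
  gains <- stats::runif(3, 0.92, 1.08)
  mu <- mean(img)
  img <- (img - mu) * ct + mu * b
  for (c in 1:3) img[, , c] <- img[, , c] * gains[c]
  if (stats::runif(1) < 0.3) img <- gblur_arr(clamp01(img), stats::runif(1, 0.3, 0.8))
  if (stats::runif(1) < 0.5) img <- img + array(stats::rnorm(length(img), 0, stats::runif(1, 0.005, 0.02)), dim(img))
  clamp01(img)
}

# Draw a 1-px-thick polyline segment onto channels of an image, in place.
draw_segment <- function(img, r0, c0, r1, c1, col) {
  n <- max(2L, ceiling(max(abs(r1 - r0), abs(c1 - c0)) * 2))
  rr <- round(seq(r0, r1, length.out = n))
  cc <- round(seq(c0, c1, length.out = n))
  keep <- rr >= 1 & rr <= dim(img)[1] & cc >= 1 & cc <= dim(img)[2]
  rr <- rr[keep]; cc <- cc[keep]
  for (ch in 1:3) img[cbind(rr, cc, ch)] <- col[ch]
  img
}
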