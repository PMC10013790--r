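# Procedural field-image simulator. Emulates the study's raw inputs --
# background frames with no wheat, wheat-field frames with known per-head
# instance masks, and temporally coherent clips -- so the whole pipeline can
# be exercised with exact, noise-free ground truth and no external data.

#' Specification for simulated field imagery
#'
#' Describes the canvas, head geometry/texture and background texture used by
#' [make_background()], [make_field_frame()] and [make_clip()]. Heads are
#' textured ellipses with awn-like strokes; awns are drawn on the image but
#' excluded from the instance masks, mirroring the common annotation
#' convention for wheat heads.
#'
#' @param canvas integer c(H, W) canvas size in pixels
#' @param n_heads number of heads per frame
#' @param head_major range (px) of the ellipse semi-major axis
#' @param head_minor range (px) of the ellipse semi-minor axis
#' @param stripe_freq spikelet stripe frequency along the head axis
#' @param awn_strokes number of awn strokes per head (drawn, never masked)
#' @param bg_base background base color (RGB in \[0,1\]), a soil/vegetation green
#' @param bg_noise_sd per-pixel background noise sd
#' @param bg_patch_px coarse blotch scale of the background texture, in px
#' @param stems draw stem strokes on field frames (absent from backgrounds)
#' @param allow_overlap allow head ellipses to overlap each other
#' @return an object of class `field_spec`
#' @export
field_spec <- function(canvas = c(96L, 96L), n_heads = 6L,
                       head_major = c(8, 14), head_minor = c(4, 7),
                       stripe_freq = 2.2, awn_strokes = 3L,
                       bg_base = c(0.33, 0.40, 0.18), bg_noise_sd = 0.04,
                       bg_patch_px = 12, stems = TRUE, allow_overlap = FALSE) {
  stopifnot(length(canvas) == 2L, all(canvas >= 1), n_heads >= 0,
            head_major[2] * 2 < min(canvas))
  structure(list(canvas = as.integer(canvas), n_heads = as.integer(n_heads),
                 head_major = head_major, head_minor = head_minor,
                 stripe_freq = stripe_freq, awn_strokes = as.integer(awn_strokes),
                 bg_base = bg_base, bg_noise_sd = bg_noise_sd,
                 bg_patch_px = bg_patch_px, stems = isTRUE(stems),
                 allow_overlap = isTRUE(allow_overlap)),
            class = "field_spec")
}

new_frame <- function(image, index, clip_id) {
  list(index = as.integer(index), image = image, clip_id = as.character(clip_id))
}

render_background <- function(spec, h, w) {
  ch <- max(2L, ceiling(h / spec$bg_patch_px))
  cw <- max(2L, ceiling(w / spec$bg_patch_px))
  img <- array(0, c(h, w, 3L))
  for (c in 1:3) {
    coarse <- matrix(stats::runif(ch * cw, -1, 1), ch, cw)
    field <- resize_arr(coarse, h, w)
    img[, , c] <- spec$bg_base[c] * (1 + 0.3 * field) +
      stats::rnorm(h * w, 0, spec$bg_noise_sd)
  }
  clamp01(img)
}

#' Generate a textured background frame with no heads
#' @param spec a [field_spec()]
#' @param seed integer seed; the frame is a pure function of (spec, seed)
#' @param index frame index recorded on the returned frame
#' @return a frame: list(index, image, clip_id)
#' @export
make_background <- function(spec = field_spec(), seed = 0L, index = 0L) {
  set.seed(seed)
  new_frame(render_background(spec, spec$canvas[1], spec$canvas[2]),
            index, sprintf("bg-%d", seed))
}

# Rasterize one head ellipse; returns list(mask, tip) where tip is the
# canvas coordinate of the major-axis end (awns radiate from there).
head_ellipse_mask <- function(h, w, center, a, b, theta) {
  rr <- matrix(seq_len(h), h, w) - center[1]
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - center[2]
  u <- rr * cos(theta) + cc * sin(theta)
  v <- -rr * sin(theta) + cc * cos(theta)
  mask <- ((u / a)^2 + (v / b)^2 <= 1) * 1
  tip <- c(center[1] - a * cos(theta), center[2] - a * sin(theta))
  list(mask = mask, u = u, tip = tip)
}

draw_head <- function(img, center, a, b, theta, stripe_freq, awn_strokes) {
  h <- dim(img)[1]; w <- dim(img)[2]
  he <- head_ellipse_mask(h, w, center, a, b, theta)
  mask <- he$mask
  base <- c(0.78, 0.66, 0.32) * stats::runif(1, 0.85, 1.1)
  stripes <- 0.5 + 0.5 * sin(he$u * stripe_freq)
  idx <- which(mask == 1)
  for (c in 1:3) {
    plane <- img[, , c]
    tex <- base[c] * (0.75 + 0.45 * stripes[idx]) + stats::rnorm(length(idx), 0, 0.02)
    plane[idx] <- clamp01(tex)
    img[, , c] <- plane
  }
  # awns: thin strokes from the head tip, image-only (excluded from mask)
  for (k in seq_len(awn_strokes)) {
    ang <- theta + stats::runif(1, -0.5, 0.5)
    len <- stats::runif(1, 0.4, 0.9) * a
    img <- draw_segment(img, he$tip[1], he$tip[2],
                        he$tip[1] - len * cos(ang), he$tip[2] - len * sin(ang),
                        clamp01(base * 1.1))
  }
  list(image = img, mask = mask)
}

draw_stems <- function(img, n) {
  h <- dim(img)[1]; w <- dim(img)[2]
  col <- c(0.25, 0.42, 0.14)
  for (k in seq_len(n)) {
    c0 <- stats::runif(1, 1, w)
    r0 <- stats::runif(1, 1, h)
    len <- stats::runif(1, h / 4, h / 1.5)
    tilt <- stats::runif(1, -0.25, 0.25)
    img <- draw_segment(img, r0, c0, min(h, r0 + len), c0 + tilt * len,
                        clamp01(col * stats::runif(1, 0.8, 1.2)))
  }
  img
}

place_heads <- function(spec, h, w) {
  # sample non-overlapping (unless allowed) head parameters by rejection
  placed <- list()
  occupied <- matrix(0, h, w)
  for (k in seq_len(spec$n_heads)) {
    ok <- FALSE
    for (attempt in seq_len(300L)) {
      a <- stats::runif(1, spec$head_major[1], spec$head_major[2])
      b <- stats::runif(1, spec$head_minor[1], spec$head_minor[2])
      theta <- stats::runif(1, -pi / 5, pi / 5)
      center <- c(stats::runif(1, a + 1, h - a - 1), stats::runif(1, a + 1, w - a - 1))
      m <- head_ellipse_mask(h, w, center, a, b, theta)$mask
      if (sum(m) == 0) next
      if (!spec$allow_overlap && sum(m * occupied) > 0) next
      occupied <- pmax(occupied, m)
      placed[[k]] <- list(center = center, a = a, b = b, theta = theta)
      ok <- TRUE
      break
    }
    if (!ok) stop("packing failure: could not place head ", k, " of ",
                  spec$n_heads, " without overlap")
  }
  placed
}

#' Generate an annotated wheat-field frame
#'
#' Draws `spec$n_heads` textured ellipse heads (plus stems and awns, which
#' belong to the background class) over a procedural background and returns
#' the exact per-head instance masks.
#'
#' @inheritParams make_background
#' @return list(frame, masks) where masks is a list of H x W \{0,1\} matrices,
#'   one per head, exactly matching the drawn head pixels
#' @export
make_field_frame <- function(spec = field_spec(), seed = 0L, index = 0L) {
  set.seed(seed)
  h <- spec$canvas[1]; w <- spec$canvas[2]
  img <- render_background(spec, h, w)
  if (spec$stems) img <- draw_stems(img, n = max(4L, spec$n_heads * 3L))
  params <- place_heads(spec, h, w)
  masks <- vector("list", length(params))
  for (k in seq_along(params)) {
    p <- params[[k]]
    dh <- draw_head(img, p$center, p$a, p$b, p$theta, spec$stripe_freq,
                    spec$awn_strokes)
    img <- dh$image
    masks[[k]] <- dh$mask
  }
  list(frame = new_frame(img, index, sprintf("field-%d", seed)), masks = masks)
}

#' Generate a temporally coherent clip of field frames
#'
#' A larger latent scene is rendered once and each frame is a crop shifted by
#' `t * drift_px_per_frame`, so frame `t`'s masks are exactly frame 0's masks
#' translated (and clipped at the canvas edge).
#'
#' @param spec a [field_spec()]; `spec$canvas` is the per-frame size
#' @param n_frames number of frames (indices 0..n_frames-1)
#' @param drift_px_per_frame scene translation per frame, scalar or c(dr, dc)
#' @param seed integer seed
#' @return list(frames, masks): frames is a list of frames; masks\[\[t\]\] is the
#'   list of nonempty instance masks for frame t
#' @export
make_clip <- function(spec = field_spec(), n_frames = 30L,
                      drift_px_per_frame = 1, seed = 0L) {
  stopifnot(n_frames >= 1)
  drift <- rep(drift_px_per_frame, length.out = 2L)
  pad <- ceiling(abs(drift) * (n_frames - 1))
  big_spec <- spec
  big_spec$canvas <- as.integer(spec$canvas + pad)
  area_ratio <- prod(big_spec$canvas) / prod(spec$canvas)
  big_spec$n_heads <- max(spec$n_heads, as.integer(round(spec$n_heads * area_ratio)))
  scene <- make_field_frame(big_spec, seed = seed)
  h <- spec$canvas[1]; w <- spec$canvas[2]
  frames <- vector("list", n_frames)
  masks <- vector("list", n_frames)
  clip_id <- sprintf("clip-%d", seed)
  for (t in seq_len(n_frames) - 1L) {
    off <- round(t * drift)
    r0 <- 1L + max(0L, off[1]); c0 <- 1L + max(0L, off[2])
    rows <- r0:(r0 + h - 1L); cols <- c0:(c0 + w - 1L)
    frames[[t + 1L]] <- new_frame(scene$frame$image[rows, cols, , drop = FALSE],
                                  t, clip_id)
    ms <- lapply(scene$masks, function(m) m[rows, cols, drop = FALSE])
    masks[[t + 1L]] <- ms[vapply(ms, sum, 0) > 0]
  }
  list(frames = frames, masks = masks)
}

#' Write frames (and optional masks) to the standard on-disk layout
#'
#' Creates `dir/frames/frame_%05d.png`, optionally `dir/masks/frame_%05d.png`
#' (the union mask) plus per-instance masks, and an index CSV.
#'
#' @param frames list of frames
#' @param dir output directory
#' @param masks optional list (per frame) of instance-mask lists
#' @return path to the index CSV, invisibly
#' @export
write_frames <- function(frames, dir, masks = NULL) {
  dir.create(file.path(dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  if (!is.null(masks)) dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  rows <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    p <- file.path(dir, "frames", sprintf("frame_%05d.png", f$index))
    write_image(f$image, p)
    mp <- NA_character_
    if (!is.null(masks)) {
      mp <- file.path(dir, "masks", sprintf("frame_%05d.png", f$index))
      u <- Reduce(pmax, masks[[i]], matrix(0, dim(f$image)[1], dim(f$image)[2]))
      write_mask(u, mp)
    }
    data.frame(clip_id = f$clip_id, index = f$index, path = p,
               mask_path = mp, stringsAsFactors = FALSE)
  })
  idx <- do.call(rbind, rows)
  csv <- file.path(dir, "index.csv")
  utils::write.csv(idx, csv, row.names = FALSE)
  invisible(csv)
}
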