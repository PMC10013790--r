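# Synthesis Step II: geometric augmentation of cutouts, composition of
# computationally annotated images (fakes first, then reals; the recorded
# real footprints define the mask), and whole-dataset emission.

#' Geometric augmentation ranges for cutouts
#'
#' Transform order is horizontal flip, vertical flip, rotation, resize,
#' elastic deformation. The same sampled map is applied to the patch
#' (bilinear) and the footprint (re-binarized at 0.5 after interpolation).
#'
#' @param p_flip_h,p_flip_v flip probabilities
#' @param rotation rotation range in degrees
#' @param scale isotropic resize factor range
#' @param elastic list(p, alpha, sigma): application probability, peak
#'   displacement in px, and smoothing sigma of the displacement field
#' @param max_retries resample budget if a transform empties the footprint
#' @return list of class `aug_params`
#' @export
aug_params <- function(p_flip_h = 0.5, p_flip_v = 0.5,
                       rotation = c(-180, 180), scale = c(0.5, 1.5),
                       elastic = list(p = 0.3, alpha = 2, sigma = 4),
                       max_retries = 10L) {
  structure(list(p_flip_h = p_flip_h, p_flip_v = p_flip_v,
                 rotation = rotation, scale = scale, elastic = elastic,
                 max_retries = max_retries), class = "aug_params")
}

#' Identity augmentation (all transforms off)
#' @return an `aug_params` object that leaves cutouts unchanged
#' @export
identity_aug_params <- function() {
  aug_params(p_flip_h = 0, p_flip_v = 0, rotation = c(0, 0), scale = c(1, 1),
             elastic = list(p = 0, alpha = 0, sigma = 1))
}

sample_transform <- function(params) {
  list(flip_h = stats::runif(1) < params$p_flip_h,
       flip_v = stats::runif(1) < params$p_flip_v,
       angle = stats::runif(1, params$rotation[1], params$rotation[2]),
       scale = stats::runif(1, params$scale[1], params$scale[2]),
       elastic = if (stats::runif(1) < params$elastic$p)
         list(alpha = params$elastic$alpha, sigma = params$elastic$sigma,
              seed = sample.int(.Machine$integer.max, 1L)))
}

is_identity_transform <- function(tr) {
  !tr$flip_h && !tr$flip_v && tr$angle == 0 && tr$scale == 1 &&
    is.null(tr$elastic)
}

apply_transform <- function(patch, footprint, tr) {
  if (tr$flip_h) { # flip across the vertical axis: reverse columns
    patch <- patch[, ncol(footprint):1, , drop = FALSE]
    footprint <- footprint[, ncol(footprint):1, drop = FALSE]
  }
  if (tr$flip_v) {
    patch <- patch[nrow(footprint):1, , , drop = FALSE]
    footprint <- footprint[nrow(footprint):1, , drop = FALSE]
  }
  if (tr$angle %% 360 != 0) {
    patch <- rotate_expand(patch, tr$angle, "bilinear")
    footprint <- (rotate_expand(footprint, tr$angle, "bilinear") >= 0.5) * 1
  }
  if (tr$scale != 1) {
    nr <- max(1L, as.integer(round(nrow(footprint) * tr$scale)))
    nc <- max(1L, as.integer(round(ncol(footprint) * tr$scale)))
    patch <- resize_arr(patch, nr, nc)
    footprint <- (resize_arr(footprint, nr, nc) >= 0.5) * 1
  }
  if (!is.null(tr$elastic)) {
    set.seed(tr$elastic$seed)
    patch <- elastic_warp(patch, tr$elastic$alpha, tr$elastic$sigma)
    set.seed(tr$elastic$seed)
    footprint <- elastic_warp(footprint, tr$elastic$alpha, tr$elastic$sigma,
                              binary = TRUE)
  }
  list(patch = clamp01(patch), footprint = footprint)
}

#' Apply a seeded geometric augmentation to a cutout
#'
#' Patch and footprint undergo the identical sampled map. If the transform
#' empties the footprint a new transform is sampled, up to
#' `params$max_retries` times. With identity parameters the cutout is
#' returned unchanged, bit for bit.
#'
#' @param cutout a cutout from [extract_instances()] or [cut_fake_instances()]
#' @param rng_seed integer seed
#' @param params an [aug_params()] object
#' @return the augmented cutout, cropped tight around its footprint; the
#'   sampled transform is attached as attribute "transform"
#' @export
augment_cutout <- function(cutout, rng_seed = 0L, params = aug_params()) {
  set.seed(rng_seed)
  for (try in seq_len(params$max_retries)) {
    tr <- sample_transform(params)
    if (is_identity_transform(tr)) {
      attr(cutout, "transform") <- tr
      return(cutout)
    }
    res <- apply_transform(cutout$patch, cutout$footprint, tr)
    if (sum(res$footprint) > 0) {
      bb <- tight_bbox(res$footprint)
      rows <- (bb[1] + 1L):bb[3]; cols <- (bb[2] + 1L):bb[4]
      out <- new_cutout(res$patch[rows, cols, , drop = FALSE],
                        res$footprint[rows, cols, drop = FALSE],
                        c(0L, 0L, length(rows), length(cols)),
                        cutout$kind, cutout$source_id)
      attr(out, "transform") <- tr
      return(out)
    }
  }
  stop("augmentation failure: transform emptied the footprint after ",
       params$max_retries, " retries")
}

# Paste a cutout onto a canvas centered at (r, c) (1-based), clipping at the
# borders. Returns list(canvas, fp) where fp is the clipped footprint on the
# full canvas (used for mask building and the placement log).
paste_cutout <- function(canvas, patch, footprint, center) {
  H <- dim(canvas)[1]; W <- dim(canvas)[2]
  h <- nrow(footprint); w <- ncol(footprint)
  r0 <- center[1] - floor(h / 2); c0 <- center[2] - floor(w / 2)
  rows <- max(1L, r0):min(H, r0 + h - 1L)
  cols <- max(1L, c0):min(W, c0 + w - 1L)
  fp_full <- matrix(0, H, W)
  if (length(rows) > 0 && length(cols) > 0 && rows[1] <= rows[length(rows)]) {
    prow <- rows - r0 + 1L; pcol <- cols - c0 + 1L
    sub_fp <- footprint[prow, pcol, drop = FALSE]
    for (ch in 1:3) {
      plane <- canvas[rows, cols, ch]
      pp <- patch[prow, pcol, ch]
      plane[sub_fp > 0] <- pp[sub_fp > 0]
      canvas[rows, cols, ch] <- plane
    }
    fp_full[rows, cols] <- sub_fp
  }
  list(canvas = canvas, fp = fp_full)
}

draw_count <- function(n_range) {
  if (n_range[1] == n_range[2]) return(as.integer(n_range[1]))
  n_range[1] + sample.int(n_range[2] - n_range[1] + 1L, 1L) - 1L
}

#' Compose one computationally annotated image
#'
#' Draws independent uniform counts of fake and real cutouts from `n_range`,
#' samples cutouts with replacement, augments each with [augment_cutout()],
#' and overlays them at uniform random centers -- all fakes first, then all
#' reals, in painter's order. The ground-truth mask is the union of the
#' placed real footprints (fakes sit below every real head and contribute no
#' mask pixels). Color augmentation, when on, touches only the composite
#' image, never the mask.
#'
#' @param background a frame (list with $image) or an H x W x 3 array
#' @param real_bank,fake_bank `cutout_set`s of real and fake cutouts
#' @param rng_seed integer seed; the sample is a pure function of its inputs
#' @param n_range inclusive (low, high) range for both head counts
#' @param color_aug apply photometric jitter to the composite image
#' @param aug geometric [aug_params()] for the cutouts
#' @return object of class `synthetic_sample`: list(image, mask, placements,
#'   background_id, seed). Each placement records cutout index, kind, center,
#'   the sampled transform and the transformed footprint, so the mask can be
#'   re-rasterized from the log alone.
#' @export
compose <- function(background, real_bank, fake_bank, rng_seed = 0L,
                    n_range = c(10L, 100L), color_aug = TRUE,
                    aug = aug_params()) {
  img <- if (is.list(background)) background$image else background
  img <- as_image3(img)
  bg_id <- if (is.list(background)) background$clip_id else "array"
  H <- dim(img)[1]; W <- dim(img)[2]
  set.seed(rng_seed)
  n_fake <- draw_count(n_range)
  n_real <- draw_count(n_range)
  if (n_fake > 0 && length(fake_bank$cutouts) == 0)
    stop("fake bank is empty but ", n_fake, " fake placements were drawn")
  if (n_real > 0 && length(real_bank$cutouts) == 0)
    stop("real bank is empty but ", n_real, " real placements were drawn")
  mask <- matrix(0, H, W)
  placements <- vector("list", n_fake + n_real)
  kinds <- c(rep("fake", n_fake), rep("real", n_real))
  for (k in seq_along(kinds)) {
    kind <- kinds[k]
    bank <- if (kind == "fake") fake_bank else real_bank
    pick <- sample.int(length(bank$cutouts), 1L)
    aseed <- sample.int(.Machine$integer.max, 1L)
    co <- augment_cutout(bank$cutouts[[pick]], aseed, aug)
    center <- c(sample.int(H, 1L), sample.int(W, 1L))
    pasted <- paste_cutout(img, co$patch, co$footprint, center)
    img <- pasted$canvas
    if (kind == "real") mask <- pmax(mask, pasted$fp)
    placements[[k]] <- list(cutout_id = sprintf("%s_%03d", kind, pick),
                            kind = kind, center = center,
                            applied_transform = attr(co, "transform"),
                            footprint = co$footprint)
  }
  if (isTRUE(color_aug)) img <- color_augment(img)
  structure(list(image = img, mask = mask, placements = placements,
                 background_id = bg_id, seed = rng_seed),
            class = "synthetic_sample")
}

#' @export
print.synthetic_sample <- function(x, ...) {
  kinds <- vapply(x$placements, `[[`, "", "kind")
  cat("synthetic sample", dim(x$image)[1], "x", dim(x$image)[2], "--",
      sum(kinds == "real"), "real +", sum(kinds == "fake"),
      "fake placements;", sum(x$mask), "mask px\n")
  invisible(x)
}

#' Re-rasterize the mask of a synthetic sample from its placement log
#'
#' Rebuilds the ground-truth mask using only the recorded placements (union
#' of the clipped real footprints). Used to audit mask consistency.
#'
#' @param sample a `synthetic_sample`
#' @return H x W \{0,1\} matrix
#' @export
rasterize_placements <- function(sample) {
  H <- dim(sample$image)[1]; W <- dim(sample$image)[2]
  mask <- matrix(0, H, W)
  for (p in sample$placements) {
    if (p$kind != "real") next
    fp <- p$footprint
    h <- nrow(fp); w <- ncol(fp)
    r0 <- p$center[1] - floor(h / 2); c0 <- p$center[2] - floor(w / 2)
    for (i in seq_len(h)) {
      for (j in seq_len(w)) {
        if (fp[i, j] > 0) {
          r <- r0 + i - 1L; c <- c0 + j - 1L
          if (r >= 1 && r <= H && c >= 1 && c <= W) mask[r, c] <- 1
        }
      }
    }
  }
  mask
}

#' Synthesize a whole computationally annotated dataset
#'
#' Repeats [compose()] `n_images` times. For image i (1-based) the derived
#' seed is `base_seed + i - 1`; it selects the background uniformly and
#' drives the composition, so a rerun with the same `base_seed` is
#' byte-identical on disk.
#'
#' @param background_frames list of background frames
#' @param real_bank,fake_bank cutout banks
#' @param n_images number of images to synthesize
#' @param base_seed integer base seed
#' @param out_dir output directory (created); images/, masks/, manifest.csv
#' @param split split tag recorded in the manifest ("train" or "val")
#' @param stage stage tag recorded in the manifest
#' @inheritParams compose
#' @return the manifest data.frame, invisibly
#' @export
synthesize_dataset <- function(background_frames, real_bank, fake_bank,
                               n_images = 10000L, base_seed = 0L, out_dir,
                               n_range = c(10L, 100L), color_aug = TRUE,
                               aug = aug_params(), split = "train",
                               stage = "S") {
  stopifnot(n_images >= 0, length(background_frames) >= 1)
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    seed_i <- base_seed + i - 1L
    set.seed(seed_i)
    bg <- background_frames[[sample.int(length(background_frames), 1L)]]
    cseed <- sample.int(.Machine$integer.max, 1L)
    s <- compose(bg, real_bank, fake_bank, rng_seed = cseed,
                 n_range = n_range, color_aug = color_aug, aug = aug)
    id <- sprintf("syn_%05d", i - 1L)
    ip <- file.path(out_dir, "images", paste0(id, ".png"))
    mp <- file.path(out_dir, "masks", paste0(id, ".png"))
    write_image(s$image, ip)
    write_mask(s$mask, mp)
    rows[[i]] <- manifest_row(id, ip, mp, split, stage,
                              domain = "synthetic", seed = seed_i)
  }
  manifest <- if (n_images > 0) new_manifest(rows) else empty_manifest()
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}
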