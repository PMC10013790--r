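# Cutout banks (synthesis Step I): real head cutouts extracted from an
# annotated frame, and "fake" cutouts cut with the same footprints (cookie
# cutters) from head-free regions of the same frame. Fakes carry background
# appearance in a head shape, so a model trained on composites cannot rely
# on paste-boundary artifacts alone.

new_cutout <- function(patch, footprint, bbox, kind, source_id) {
  structure(list(patch = patch, footprint = footprint, bbox = as.integer(bbox),
                 kind = kind, source_id = source_id), class = "cutout")
}

new_cutout_set <- function(cutouts, kind, source_id) {
  structure(list(cutouts = cutouts, kind = kind, source_id = source_id),
            class = "cutout_set")
}

#' @export
print.cutout_set <- function(x, ...) {
  cat("cutout set:", length(x$cutouts), x$kind, "cutouts from",
      x$source_id, "\n")
  invisible(x)
}

#' @export
length.cutout_set <- function(x) length(x$cutouts)

# Tight bounding box of a nonempty mask, 0-based half-open (r0, c0, r1, c1).
tight_bbox <- function(mask) {
  w <- which(mask > 0, arr.ind = TRUE)
  c(min(w[, 1]) - 1L, min(w[, 2]) - 1L, max(w[, 1]), max(w[, 2]))
}

#' Split a semantic mask into instance masks by connected components
#'
#' Uses 8-connectivity: diagonally touching pixels belong to one instance.
#'
#' @param mask H x W binary matrix
#' @return list of H x W \{0,1\} instance masks (empty list for an empty mask)
#' @export
instances_from_semantic <- function(mask) {
  lab <- cpp_label8(matrix(as.integer(mask > 0), nrow(mask), ncol(mask)))
  n <- max(lab)
  lapply(seq_len(n), function(k) (lab == k) * 1)
}

#' Extract real head cutouts from an annotated image
#'
#' One cutout per instance mask: the patch is the image restricted to the
#' tight bounding box of the instance, the footprint is the mask cropped to
#' the same box. Patches keep the background pixels outside the footprint;
#' compositing uses the footprint as the alpha channel.
#'
#' @param image H x W x 3 array
#' @param instance_masks list of H x W binary masks, one per head
#' @param source_id provenance label stored on each cutout
#' @return a `cutout_set` with kind "real"
#' @export
extract_instances <- function(image, instance_masks, source_id = "annotated") {
  image <- as_image3(image)
  dm <- dim(image)[1:2]
  cuts <- vector("list", length(instance_masks))
  for (i in seq_along(instance_masks)) {
    m <- instance_masks[[i]]
    if (!all(dim(m) == dm))
      stop("instance mask ", i, " does not match the image shape")
    if (sum(m > 0) == 0)
      stop("instance mask ", i, " is empty")
    bb <- tight_bbox(m)
    rows <- (bb[1] + 1L):bb[3]; cols <- (bb[2] + 1L):bb[4]
    cuts[[i]] <- new_cutout(image[rows, cols, , drop = FALSE],
                            (m[rows, cols, drop = FALSE] > 0) * 1,
                            bb, "real", source_id)
  }
  new_cutout_set(cuts, "real", source_id)
}

#' Cut fake head cutouts from head-free regions (cookie cutters)
#'
#' For each template footprint, a position is drawn uniformly at random
#' (seeded rejection sampling) until the translated footprint does not touch
#' any pixel of `head_union`; the cutout takes the image content there with
#' the template as its footprint.
#'
#' @param image H x W x 3 array
#' @param head_union H x W binary mask marking all head pixels to avoid
#' @param templates list of binary footprint matrices (typically the real
#'   cutouts' footprints)
#' @param rng_seed integer seed
#' @param max_attempts rejection-sampling budget per template
#' @param source_id provenance label
#' @return a `cutout_set` with kind "fake"
#' @export
cut_fake_instances <- function(image, head_union, templates, rng_seed = 0L,
                               max_attempts = 1000L, source_id = "annotated") {
  image <- as_image3(image)
  dm <- dim(image)[1:2]
  stopifnot(all(dim(head_union) == dm))
  set.seed(rng_seed)
  cuts <- vector("list", length(templates))
  for (k in seq_along(templates)) {
    tp <- (templates[[k]] > 0) * 1
    th <- nrow(tp); tw <- ncol(tp)
    if (th > dm[1] || tw > dm[2])
      stop("template ", k, " does not fit inside the image")
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      r0 <- sample.int(dm[1] - th + 1L, 1L) - 1L
      c0 <- sample.int(dm[2] - tw + 1L, 1L) - 1L
      rows <- (r0 + 1L):(r0 + th); cols <- (c0 + 1L):(c0 + tw)
      if (sum(tp * head_union[rows, cols]) == 0) {
        cuts[[k]] <- new_cutout(image[rows, cols, , drop = FALSE], tp,
                                c(r0, c0, r0 + th, c0 + tw), "fake", source_id)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("placement failure for template ", k, ": no head-free position ",
           "found in ", max_attempts, " attempts")
  }
  new_cutout_set(cuts, "fake", source_id)
}

#' Build the real and fake cutout banks from one annotated frame
#'
#' Convenience wrapper for synthesis Step I: extracts real cutouts from the
#' instance masks and cuts one fake per real footprint from head-free
#' regions. Instances below `min_area` pixels (slivers of heads clipped at
#' the frame border) are skipped: they carry no usable texture and cannot
#' survive geometric augmentation.
#'
#' @inheritParams extract_instances
#' @inheritParams cut_fake_instances
#' @param min_area smallest instance (in pixels) worth cutting out
#' @return list(real, fake) of `cutout_set`s
#' @export
build_cutout_banks <- function(image, instance_masks, rng_seed = 0L,
                               max_attempts = 1000L, source_id = "annotated",
                               min_area = 4L) {
  union <- Reduce(pmax, instance_masks)
  instance_masks <- Filter(function(m) sum(m > 0) >= min_area, instance_masks)
  if (length(instance_masks) == 0)
    stop("no instance reaches min_area = ", min_area, " pixels")
  real <- extract_instances(image, instance_masks, source_id)
  fake <- cut_fake_instances(image, union,
                             lapply(real$cutouts, `[[`, "footprint"),
                             rng_seed = rng_seed, max_attempts = max_attempts,
                             source_id = source_id)
  list(real = real, fake = fake)
}

#' Persist a cutout bank as paired PNGs plus a CSV index
#' @param set a `cutout_set`
#' @param dir output directory
#' @return path to the index CSV, invisibly
#' @export
save_cutout_bank <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(set$cutouts), function(i) {
    co <- set$cutouts[[i]]
    id <- sprintf("%s_%03d", set$kind, i)
    write_image(co$patch, file.path(dir, paste0(id, "_patch.png")))
    write_mask(co$footprint, file.path(dir, paste0(id, "_footprint.png")))
    data.frame(id = id, kind = co$kind, r0 = co$bbox[1], c0 = co$bbox[2],
               r1 = co$bbox[3], c1 = co$bbox[4], source_id = co$source_id,
               stringsAsFactors = FALSE)
  })
  csv <- file.path(dir, "index.csv")
  utils::write.csv(do.call(rbind, rows), csv, row.names = FALSE)
  invisible(csv)
}

#' Load a cutout bank saved by [save_cutout_bank()]
#' @param dir bank directory
#' @return a `cutout_set`
#' @export
load_cutout_bank <- function(dir) {
  csv <- file.path(dir, "index.csv")
  if (!file.exists(csv)) stop("no cutout bank index at ", csv)
  idx <- utils::read.csv(csv, stringsAsFactors = FALSE)
  cuts <- lapply(seq_len(nrow(idx)), function(i) {
    new_cutout(read_image(file.path(dir, paste0(idx$id[i], "_patch.png"))),
               read_mask(file.path(dir, paste0(idx$id[i], "_footprint.png"))),
               c(idx$r0[i], idx$c0[i], idx$r1[i], idx$c1[i]),
               idx$kind[i], idx$source_id[i])
  })
  new_cutout_set(cuts, unique(idx$kind), unique(idx$source_id)[1])
}
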