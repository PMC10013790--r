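# Frame extraction and the five-way split of a wheat-clip's frames:
# w_t and w_v seed synthesis, a held-out test set and validation set are
# sampled outside a one-second exclusion window around both, and the
# remainder becomes the unlabeled pool for pseudo-labeling.

#' Extract frames from a directory of PNG frames
#'
#' Frames are read in temporal order. If filenames carry a numeric component
#' (e.g. `frame_00017.png`) it is used as the original frame index; otherwise
#' indices are assigned 0,1,2,... in sorted filename order. With `stride > 1`
#' every stride-th frame is kept, but indices remain the original frame
#' numbers so temporal reasoning (the exclusion window) survives striding.
#'
#' Video containers are not decoded; extract the clip to a PNG directory
#' first (e.g. with ffmpeg) and pass that directory.
#'
#' @param source directory containing PNG frames
#' @param stride positive integer; keep every stride-th frame
#' @return list of frames: list(index, image, clip_id)
#' @export
extract_frames <- function(source, stride = 1L) {
  stopifnot(stride >= 1)
  if (!file.exists(source)) stop("frame source does not exist: ", source)
  if (!dir.exists(source)) {
    stop("cannot decode video container '", source,
         "': extract frames to a PNG directory first")
  }
  files <- sort(list.files(source, pattern = "\\.png$", full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0) {
    others <- list.files(source)
    if (length(others) > 0 && any(grepl("\\.(jpe?g)$", others, ignore.case = TRUE)))
      stop("only PNG frames are supported; found JPEG files in ", source)
    stop("no PNG frames found in source: ", source)
  }
  nums <- suppressWarnings(as.integer(sub("^.*?(\\d+)\\D*$", "\\1", basename(files))))
  idx <- if (anyNA(nums) || anyDuplicated(nums)) seq_along(files) - 1L else nums
  ord <- order(idx)
  files <- files[ord]; idx <- idx[ord]
  keep <- seq(1L, length(files), by = stride)
  lapply(keep, function(i) new_frame(read_image(files[i]), idx[i], basename(source)))
}

#' Original clip indices of a list of frames
#' @param frames list of frames
#' @return integer vector of frame indices
#' @export
frame_indices <- function(frames) vapply(frames, function(f) f$index, 0L)

safe_sample <- function(x, n) x[sample.int(length(x), n)]

#' Partition clip frames into the five pipeline subsets
#'
#' Selects the synthesis frames `w_t` and `w_v`, samples `n_test` held-out
#' test frames and `n_val` validation frames uniformly without replacement
#' from frames lying strictly more than one second (`round(fps)` frame
#' indices) away from both `w_t` and `w_v`, and assigns all remaining frames
#' to the unlabeled pool.
#'
#' @param frames list of frames from [extract_frames()]
#' @param fps clip frame rate (frames per second), positive
#' @param idx_t,idx_v frame indices of `w_t` and `w_v` (must differ)
#' @param n_test,n_val sizes of the test and validation sets
#' @param seed integer seed; the partition is deterministic given the seed
#' @return object of class `frame_partition` with fields w_t, w_v, test_set,
#'   val_set, unlabeled, fps
#' @export
partition_frames <- function(frames, fps, idx_t, idx_v, n_test, n_val,
                             seed = 0L) {
  stopifnot(fps > 0, n_test >= 0, n_val >= 0)
  if (idx_t == idx_v) stop("idx_t and idx_v must differ")
  idx <- frame_indices(frames)
  if (!(idx_t %in% idx) || !(idx_v %in% idx))
    stop("idx_t and idx_v must both be present in the frame list")
  window <- round(fps)
  eligible <- idx[abs(idx - idx_t) > window & abs(idx - idx_v) > window]
  if (length(eligible) < n_test + n_val) {
    stop("not enough eligible frames outside the one-second exclusion ",
         "window: ", length(eligible), " eligible, ", n_test + n_val,
         " requested")
  }
  set.seed(seed)
  test_idx <- safe_sample(eligible, n_test)
  val_idx <- safe_sample(setdiff(eligible, test_idx), n_val)
  taken <- c(idx_t, idx_v, test_idx, val_idx)
  unlab_idx <- setdiff(idx, taken)
  pick <- function(ids) frames[match(ids, idx)]
  structure(list(w_t = pick(idx_t)[[1]], w_v = pick(idx_v)[[1]],
                 test_set = pick(test_idx), val_set = pick(val_idx),
                 unlabeled = pick(unlab_idx), fps = fps),
            class = "frame_partition")
}

#' @export
print.frame_partition <- function(x, ...) {
  cat("frame partition (fps =", x$fps, ")\n")
  cat("  w_t index:", x$w_t$index, " w_v index:", x$w_v$index, "\n")
  cat("  test:", length(x$test_set), " val:", length(x$val_set),
      " unlabeled:", length(x$unlabeled), "\n")
  invisible(x)
}

#' Save a frame partition as PNG frames plus a split manifest CSV
#'
#' Writes each frame under `dir/frames/` and a CSV with columns
#' clip_id,index,path,split (split in wt, wv, test, val, unlabeled).
#'
#' @param partition a [partition_frames()] result
#' @param dir output directory
#' @return path to the CSV, invisibly
#' @export
save_partition <- function(partition, dir) {
  dir.create(file.path(dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  emit <- function(frames, split) {
    lapply(frames, function(f) {
      p <- file.path(dir, "frames", sprintf("frame_%05d.png", f$index))
      write_image(f$image, p)
      data.frame(clip_id = f$clip_id, index = f$index, path = p,
                 split = split, stringsAsFactors = FALSE)
    })
  }
  rows <- c(emit(list(partition$w_t), "wt"), emit(list(partition$w_v), "wv"),
            emit(partition$test_set, "test"), emit(partition$val_set, "val"),
            emit(partition$unlabeled, "unlabeled"))
  csv <- file.path(dir, "partition.csv")
  utils::write.csv(do.call(rbind, rows), csv, row.names = FALSE)
  invisible(csv)
}
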