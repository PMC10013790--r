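make_frame_dir <- function(n, dir = tempfile("frames")) {
  dir.create(dir)
  for (i in seq_len(n) - 1L) {
    img <- array(runif(12 * 12 * 3), c(12, 12, 3))
    write_image(img, file.path(dir, sprintf("frame_%05d.png", i)))
  }
  dir
}

test_that("extract_frames respects stride and keeps original indices", {
  dir <- make_frame_dir(10)
  f1 <- extract_frames(dir, stride = 1)
  expect_length(f1, 10L)
  expect_identical(frame_indices(f1), 0:9)
  f2 <- extract_frames(dir, stride = 2)
  expect_length(f2, 5L)
  expect_identical(frame_indices(f2), c(0L, 2L, 4L, 6L, 8L))
  f3 <- extract_frames(dir, stride = 3)
  expect_length(f3, ceiling(10 / 3))
})

test_that("unreadable or empty sources raise input errors naming the source", {
  empty <- tempfile("empty")
  dir.create(empty)
  expect_error(extract_frames(empty), "no PNG frames")
  expect_error(extract_frames(tempfile("nope")), "does not exist")
  vid <- tempfile(fileext = ".mp4")
  writeLines("x", vid)
  expect_error(extract_frames(vid), "video container")
})

test_that("a single eligible frame is forced into the test set", {
  dir <- make_frame_dir(5)
  frames <- extract_frames(dir)
  part <- partition_frames(frames, fps = 1, idx_t = 0, idx_v = 4,
                           n_test = 1, n_val = 0, seed = 1)
  expect_identical(part$test_set[[1]]$index, 2L)
  expect_length(part$val_set, 0L)
  expect_identical(sort(frame_indices(part$unlabeled)), c(1L, 3L))
})

test_that("exclusion window and disjointness hold on a long clip", {
  frames <- lapply(0:299, function(i)
    wheatseg:::new_frame(array(0.5, c(4, 4, 3)), i, "clip"))
  part <- partition_frames(frames, fps = 30, idx_t = 50, idx_v = 200,
                           n_test = 5, n_val = 2, seed = 7)
  chosen <- c(frame_indices(part$test_set), frame_indices(part$val_set))
  expect_false(any(chosen >= 20 & chosen <= 80))
  expect_false(any(chosen >= 170 & chosen <= 230))
  all_idx <- c(part$w_t$index, part$w_v$index, frame_indices(part$test_set),
               frame_indices(part$val_set), frame_indices(part$unlabeled))
  expect_identical(anyDuplicated(all_idx), 0L)
  expect_true(all(all_idx %in% 0:299))
})

test_that("impossible requests raise a capacity error with the eligible count", {
  frames <- lapply(0:49, function(i)
    wheatseg:::new_frame(array(0, c(2, 2, 3)), i, "c"))
  expect_error(partition_frames(frames, fps = 5, idx_t = 0, idx_v = 49,
                                n_test = 100, n_val = 0, seed = 1),
               "eligible")
})

test_that("partitions are seed-deterministic and seed-sensitive", {
  frames <- lapply(0:199, function(i)
    wheatseg:::new_frame(array(0, c(2, 2, 3)), i, "c"))
  p1 <- partition_frames(frames, fps = 10, idx_t = 20, idx_v = 150,
                         n_test = 20, n_val = 5, seed = 3)
  p2 <- partition_frames(frames, fps = 10, idx_t = 20, idx_v = 150,
                         n_test = 20, n_val = 5, seed = 3)
  p3 <- partition_frames(frames, fps = 10, idx_t = 20, idx_v = 150,
                         n_test = 20, n_val = 5, seed = 4)
  expect_identical(frame_indices(p1$test_set), frame_indices(p2$test_set))
  expect_false(identical(sort(frame_indices(p1$test_set)),
                         sort(frame_indices(p3$test_set))))
})

test_that("exclusion predicate holds over random configurations", {
  frames <- lapply(0:119, function(i)
    wheatseg:::new_frame(array(0, c(2, 2, 3)), i, "c"))
  set.seed(42)
  for (rep in 1:25) {
    fps <- sample(5:20, 1)
    idx <- sample(0:119, 2)
    part <- tryCatch(
      partition_frames(frames, fps, idx[1], idx[2], n_test = 3, n_val = 2,
                       seed = rep),
      error = function(e) NULL)
    if (is.null(part)) next
    chosen <- c(frame_indices(part$test_set), frame_indices(part$val_set))
    expect_true(all(abs(chosen - idx[1]) > round(fps)))
    expect_true(all(abs(chosen - idx[2]) > round(fps)))
  }
})

test_that("partitions round-trip through the on-disk manifest", {
  dir <- make_frame_dir(8)
  frames <- extract_frames(dir)
  part <- partition_frames(frames, fps = 1, idx_t = 0, idx_v = 7,
                           n_test = 2, n_val = 1, seed = 2)
  out <- tempfile("part")
  csv <- save_partition(part, out)
  df <- read.csv(csv)
  expect_setequal(df$split, c("wt", "wv", "test", "val", "unlabeled"))
  expect_identical(nrow(df), 8L)
  expect_true(all(file.exists(df$path)))
})
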