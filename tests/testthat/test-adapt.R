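test_that("rotation datasets expand the canvas and keep exact quarter-turns", {
  sc <- small_scene()
  img <- sc$frame$image
  mask <- sc$union
  out <- tempfile("rot")
  man <- rotations_dataset(img, mask, out, degrees = c(0L, 45L, 90L, 180L))
  expect_identical(nrow(man), 4L)
  expect_true(all(file.exists(man$image_path)))
  # degree 0: files byte-identical to writing the inputs directly
  ref_i <- tempfile(fileext = ".png"); write_image(img, ref_i)
  ref_m <- tempfile(fileext = ".png"); write_mask(mask, ref_m)
  expect_identical(readBin(man$image_path[1], "raw", 1e6),
                   readBin(ref_i, "raw", 1e6))
  expect_identical(readBin(man$mask_path[1], "raw", 1e6),
                   readBin(ref_m, "raw", 1e6))
  # half-turn: foreground count preserved exactly
  m180 <- read_mask(man$mask_path[man$id == "rot_180"])
  expect_identical(sum(m180), sum(mask))
  # 45 degrees: canvas grew, mask stays binary
  m45 <- read_mask(man$mask_path[man$id == "rot_045"])
  expect_gt(nrow(m45), nrow(mask))
  expect_true(all(m45 %in% c(0, 1)))
  expect_error(rotations_dataset(img, mask[1:10, ], tempfile()),
               "different spatial shapes")
})

test_that("epoch selection minimizes the validation loss", {
  expect_identical(select_epoch(c(0.5, 0.3, 0.4)), 2L)
  expect_identical(select_epoch(0.7), 1L)
  expect_identical(select_epoch(c(0.4, 0.2, 0.2)), 2L)
})

test_that("pseudo-labels round-trip: stored mask = rebinarized prediction", {
  ck <- tiny_trained()
  spec <- field_spec(canvas = c(32L, 32L), n_heads = 3L,
                     head_major = c(5, 7), head_minor = c(3, 4))
  clip <- make_clip(spec, n_frames = 4L, drift_px_per_frame = 1, seed = 14)
  out <- tempfile("pl")
  man <- generate_pseudo_labels(ck, clip$frames, threshold = 0.5, out_dir = out)
  expect_identical(nrow(man), 4L)
  for (i in seq_len(nrow(man))) {
    stored <- read_mask(man$mask_path[i])
    again <- binarize(predict_probs_padded(ck$model,
                                           read_image(man$image_path[i])))
    expect_identical(stored, again)
  }
  expect_error(generate_pseudo_labels(ck, list(), out_dir = tempfile()),
               "no frames")
})

make_tiny_manifest <- function(n = 4, seed = 0, size = 32L) {
  sc <- small_scene()
  dir <- tempfile("ds")
  synthesize_dataset(list(small_background(seed + 100)), sc$real, sc$fake,
                     n_images = n, base_seed = seed, out_dir = dir,
                     n_range = c(2L, 5L), aug = identity_aug_params())
}

test_that("training selects the min-val-loss epoch and is deterministic", {
  man <- make_tiny_manifest(4, seed = 60)
  cfg <- stage_config("S", man, man, epochs = 3L, batch_size = 2L, seed = 5L)
  ck1 <- train_stage(cfg)
  ck2 <- train_stage(cfg)
  expect_identical(nrow(ck1$history), 3L)
  expect_identical(ck1$selected_epoch, select_epoch(ck1$history$val_loss))
  expect_lte(ck1$history$val_loss[ck1$selected_epoch],
             min(ck1$history$val_loss))
  expect_identical(ck1$history$val_loss, ck2$history$val_loss)
  expect_identical(ck1$model$weights, ck2$model$weights)
  # single epoch: the only candidate is selected
  ck3 <- train_stage(stage_config("S", man, man, epochs = 1L,
                                  batch_size = 2L, seed = 5L))
  expect_identical(ck3$selected_epoch, 1L)
})

test_that("checkpoints expose the standard modelling methods and persist", {
  ck <- tiny_trained()
  expect_output(print(ck), "stage checkpoint")
  expect_identical(length(coef(ck)), n_params(ck$model))
  img <- small_background(3)$image
  pm <- predict(ck, img)
  expect_true(all(pm %in% c(0, 1)))
  pp <- predict(ck, img, type = "prob")
  expect_true(all(pp > 0 & pp < 1))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(side$selected_epoch, ck$selected_epoch)
  rt <- load_checkpoint(path)
  expect_identical(rt$model$weights, ck$model$weights)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(ck))
})

test_that("warm starts chain stages together", {
  man <- make_tiny_manifest(3, seed = 70)
  ck1 <- train_stage(stage_config("S", man, man, epochs = 1L, seed = 2L))
  ck2 <- train_stage(stage_config("D", man, man, epochs = 1L, seed = 3L,
                                  init_from = ck1))
  expect_identical(ck2$stage_id, "D")
  # one epoch of SGD moved the weights away from the init
  expect_false(identical(ck1$model$weights, ck2$model$weights))
  expect_error(train_stage(stage_config("D", man, man, epochs = 1L,
                                        init_from = tempfile())),
               "not found")
})

test_that("rotation expansion of a manifest mirrors rotations_dataset", {
  man <- make_tiny_manifest(2, seed = 80)
  out <- tempfile("exp")
  ex <- expand_with_rotations(man, out, degrees = c(0L, 90L, 180L))
  expect_identical(nrow(ex), 6L)
  expect_true(all(file.exists(ex$image_path)))
  # the 180-degree record of each source keeps its mask pixel count
  for (i in 1:2) {
    src <- read_mask(man$mask_path[i])
    rot <- read_mask(ex$mask_path[grepl("rot_180", ex$id) &
                                    startsWith(ex$id, man$id[i])])
    expect_identical(sum(rot), sum(src))
  }
})

test_that("pipeline configs are schema-validated with stage-naming errors", {
  expect_error(run_pipeline(list(out_dir = tempfile(), bogus = 1)),
               "unknown configuration key")
  man <- make_tiny_manifest(2, seed = 90)
  mpath <- tempfile(fileext = ".csv")
  write_manifest(man, mpath)
  cfgs <- list(out_dir = tempfile(), seed = 1,
               stages = list(S = list(train_manifest = mpath,
                                      val_manifest = mpath, epochs = 1)))
  expect_error(run_pipeline(cfgs), "stage D")
  cfgs$stages$S$nonsense <- 2
  expect_error(run_pipeline(cfgs), "unknown configuration key")
})

test_that("divergent training reports the epoch", {
  man <- make_tiny_manifest(2, seed = 95)
  cfg <- stage_config("S", man, man, epochs = 4L, learning_rate = 1e150,
                      seed = 1L)
  expect_error(train_stage(cfg), "divergence.*epoch", perl = TRUE)
})
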