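# Staged domain adaptation: rotation-expanded datasets from the annotated
# frames (stage D), pseudo-labeling of the unlabeled pool (stage P),
# few-shot fine-tuning on externally annotated images (stage G), plus the
# conventional supervised Baseline, chained S -> D -> P -> G by warm starts.

#' Build the full-circle rotations dataset of one annotated image
#'
#' Emits one record per integer degree in `degrees` (default 0..359, i.e.
#' the original plus all 359 proper rotations). Images rotate with bilinear
#' interpolation, masks with nearest neighbour; the canvas expands to
#' contain the rotated frame with zero fill. The 0/90/180/270 records are
#' computed exactly, so a half-turn preserves the mask pixel count.
#'
#' @param image H x W x 3 array
#' @param mask H x W binary mask of the same spatial size
#' @param out_dir output directory
#' @param online_augment flag records for on-access strong augmentation
#' @param degrees integer rotation degrees to emit
#' @param split,stage,domain manifest tags
#' @return manifest data.frame (also written as `out_dir/manifest.csv`)
#' @export
rotations_dataset <- function(image, mask, out_dir, online_augment = FALSE,
                              degrees = 0:359, split = "train", stage = "D",
                              domain = "rotations") {
  image <- as_image3(image)
  if (!all(dim(image)[1:2] == dim(mask)))
    stop("image and mask have different spatial shapes")
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  rows <- vector("list", length(degrees))
  for (k in seq_along(degrees)) {
    d <- degrees[k]
    if (d %% 360 == 0) {
      ri <- image; rm <- mask
    } else {
      ri <- rotate_expand(image, d, "bilinear")
      rm <- rotate_mask_expand(mask, d)
    }
    id <- sprintf("rot_%03d", d)
    ip <- file.path(out_dir, "images", paste0(id, ".png"))
    mp <- file.path(out_dir, "masks", paste0(id, ".png"))
    write_image(ri, ip)
    write_mask(rm, mp)
    rows[[k]] <- manifest_row(id, ip, mp, split, stage, domain = domain,
                              seed = d, online_aug = as.integer(online_augment))
  }
  manifest <- new_manifest(rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Pseudo-label a set of unlabeled frames with a trained model
#'
#' Predicts head probabilities for every frame (padding to the model's
#' input-size divisor and cropping back) and stores the thresholded masks as
#' training targets. The masks inherit any model error -- they are noisy
#' labels by construction.
#'
#' @param model a `segnet` or `stage_checkpoint`
#' @param frames list of frames (list(index, image, clip_id)), typically the
#'   unlabeled pool of [partition_frames()]
#' @param threshold binarization threshold
#' @param out_dir output directory
#' @param split,stage manifest tags
#' @return manifest data.frame (also written as `out_dir/manifest.csv`)
#' @export
generate_pseudo_labels <- function(model, frames, threshold = 0.5, out_dir,
                                   split = "train", stage = "P-train") {
  if (inherits(model, "stage_checkpoint")) model <- model$model
  if (length(frames) == 0) stop("no frames to pseudo-label")
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  rows <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    m <- binarize(predict_probs_padded(model, f$image), threshold)
    id <- sprintf("pl_%05d", f$index)
    ip <- file.path(out_dir, "images", paste0(id, ".png"))
    mp <- file.path(out_dir, "masks", paste0(id, ".png"))
    write_image(f$image, ip)
    write_mask(m, mp)
    rows[[k]] <- manifest_row(id, ip, mp, split, stage, domain = f$clip_id,
                              seed = f$index)
  }
  manifest <- new_manifest(rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Expand an annotated manifest with rotations of every record
#'
#' Applies [rotations_dataset()] to each (image, mask) record, mirroring the
#' expansion used for the few-shot fine-tuning stage.
#'
#' @param manifest manifest data.frame with image and mask paths
#' @param out_dir output directory (one subdirectory per record)
#' @param degrees rotation degrees per record
#' @param online_augment flag the emitted records for strong augmentation
#' @return combined manifest data.frame
#' @export
expand_with_rotations <- function(manifest, out_dir, degrees = 0:359,
                                  online_augment = FALSE) {
  parts <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- rotations_dataset(read_image(manifest$image_path[i]),
                           read_mask(manifest$mask_path[i]),
                           file.path(out_dir, manifest$id[i]),
                           online_augment = online_augment,
                           degrees = degrees, split = manifest$split[i],
                           stage = manifest$stage[i],
                           domain = manifest$domain[i])
    m$id <- paste0(manifest$id[i], "_", m$id)
    m
  })
  out <- do.call(rbind, parts)
  write_manifest(out, file.path(out_dir, "manifest.csv"))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_known_keys <- list(
  top = c("out_dir", "seed", "model", "stages", "eval"),
  model = c("encoder", "widths"),
  S = c("train_manifest", "val_manifest", "epochs", "learning_rate",
        "batch_size"),
  D = c("train_manifest", "val_manifest", "epochs", "learning_rate",
        "batch_size", "online_augment"),
  P = c("unlabeled_dir", "val_dir", "threshold", "epochs", "learning_rate",
        "batch_size"),
  G = c("theta_t_manifest", "theta_v_manifest", "rotation_step", "epochs",
        "learning_rate", "batch_size"),
  baseline = c("epochs", "learning_rate", "batch_size"),
  eval = c("manifest", "tta"))

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0)
    stop("unknown configuration key", if (length(extra) > 1) "s", " in ",
         where, ": ", paste(extra, collapse = ", "))
}

need_manifest <- function(path, stage) {
  if (is.null(path) || !file.exists(path))
    stop("configuration error for stage ", stage, ": required dataset ",
         "manifest missing", if (!is.null(path)) paste0(" (", path, ")"))
  read_manifest(path)
}

load_frames_dir <- function(dir, stage) {
  if (is.null(dir) || !dir.exists(dir))
    stop("configuration error for stage ", stage, ": frame directory missing",
         if (!is.null(dir)) paste0(" (", dir, ")"))
  extract_frames(dir)
}

#' Run the full staged training pipeline
#'
#' Trains model S on the synthesized datasets, fine-tunes it into D on the
#' rotation datasets, pseudo-labels the unlabeled pool with D and fine-tunes
#' into P (validated on the pseudo-labeled validation frames), expands the
#' few-shot annotated sets with rotations and fine-tunes into G, and trains
#' the Baseline from scratch on the expanded few-shot sets alone. Every
#' stage selects its minimum-validation-loss epoch. Stage seeds derive from
#' the global seed by fixed offsets.
#'
#' @param config configuration list or path to a YAML file with keys:
#'   out_dir, seed, model (encoder/widths), stages (S, D, P, G, baseline)
#'   and optional eval (manifest, tta). Stage S and D take train/val
#'   manifest CSVs; P takes directories of unlabeled and validation frames;
#'   G takes the few-shot annotated manifests plus a rotation_step.
#'   Unknown keys are rejected.
#' @param verbose print per-epoch losses
#' @return named list of `stage_checkpoint`s (S, D, P, G, baseline), with
#'   checkpoints and logs written under `out_dir`
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  check_keys(config, pipeline_known_keys$top, "pipeline config")
  check_keys(config$model %||% list(), pipeline_known_keys$model, "model")
  stages <- config$stages %||% list()
  check_keys(stages, c("S", "D", "P", "G", "baseline"), "stages")
  for (s in names(stages))
    check_keys(stages[[s]], pipeline_known_keys[[s]], paste0("stage ", s))
  out_dir <- config$out_dir %||% stop("config needs out_dir")
  dir.create(file.path(out_dir, "checkpoints"), recursive = TRUE,
             showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 0L)
  spec <- model_spec(encoder = config$model$encoder %||% "tiny",
                     widths = config$model$widths)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S"), sprintf(...), "\n",
                            file = log_path, append = TRUE)
  logf("pipeline seed %d; stage seeds offsets 1..5", seed)
  checkpoints <- list()
  run_one <- function(stage_id, train_m, val_m, init, offset, sc) {
    cfg <- stage_config(stage_id, train_m, val_m,
                        epochs = sc$epochs %||% 10L,
                        learning_rate = sc$learning_rate %||% 0.01,
                        batch_size = sc$batch_size %||% 8L,
                        seed = seed + offset, init_from = init, spec = spec)
    ck <- train_stage(cfg, verbose = verbose)
    save_checkpoint(ck, file.path(out_dir, "checkpoints",
                                  paste0(stage_id, ".rds")))
    for (e in seq_len(nrow(ck$history)))
      logf("stage %s epoch %d train %.5f val %.5f", stage_id, e,
           ck$history$train_loss[e], ck$history$val_loss[e])
    logf("stage %s selected epoch %d", stage_id, ck$selected_epoch)
    ck
  }
  # Stage S: synthesized data, from scratch
  sc <- stages$S %||% stop("configuration error for stage S: missing block")
  checkpoints$S <- run_one("S", need_manifest(sc$train_manifest, "S"),
                           need_manifest(sc$val_manifest, "S"),
                           "scratch", 1L, sc)
  # Stage D: rotation datasets of the annotated frames, warm start from S
  sc <- stages$D %||% stop("configuration error for stage D: missing block")
  checkpoints$D <- run_one("D", need_manifest(sc$train_manifest, "D"),
                           need_manifest(sc$val_manifest, "D"),
                           checkpoints$S, 2L, sc)
  # Stage P: pseudo-label the unlabeled pool with D, warm start from D
  sc <- stages$P %||% stop("configuration error for stage P: missing block")
  phi <- load_frames_dir(sc$unlabeled_dir, "P")
  delta <- load_frames_dir(sc$val_dir, "P")
  thr <- sc$threshold %||% 0.5
  pl_train <- generate_pseudo_labels(checkpoints$D, phi, thr,
                                     file.path(out_dir, "pseudo", "train"),
                                     split = "train", stage = "P-train")
  pl_val <- generate_pseudo_labels(checkpoints$D, delta, thr,
                                   file.path(out_dir, "pseudo", "val"),
                                   split = "val", stage = "P-val")
  checkpoints$P <- run_one("P", pl_train, pl_val, checkpoints$D, 3L, sc)
  # Stage G: few-shot annotated sets expanded with rotations, from P
  sc <- stages$G %||% stop("configuration error for stage G: missing block")
  step <- as.integer(sc$rotation_step %||% 1L)
  degrees <- seq(0L, 359L, by = step)
  th_t <- expand_with_rotations(need_manifest(sc$theta_t_manifest, "G"),
                                file.path(out_dir, "theta", "train"), degrees)
  th_v <- expand_with_rotations(need_manifest(sc$theta_v_manifest, "G"),
                                file.path(out_dir, "theta", "val"), degrees)
  checkpoints$G <- run_one("G", th_t, th_v, checkpoints$P, 4L, sc)
  # Baseline: the expanded few-shot sets alone, trained from scratch
  sc <- stages$baseline %||% stages$G
  checkpoints$baseline <- run_one("baseline", th_t, th_v, "scratch", 5L, sc)
  # Optional evaluation report over all stages
  if (!is.null(config$eval)) {
    ev_m <- need_manifest(config$eval$manifest, "eval")
    tta <- isTRUE(config$eval$tta)
    reports <- lapply(checkpoints, evaluate, manifest = ev_m, tta = tta)
    for (nm in names(reports))
      write_eval_report(reports[[nm]], file.path(out_dir, "reports"), nm)
    attr(checkpoints, "reports") <- reports
  }
  checkpoints
}
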