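# Stage training: SGD on the combined BCE + Dice loss with per-epoch
# validation and min-validation-loss model selection. train_stage() is the
# single fitting entry point; it returns a classed checkpoint object with
# print/summary/predict/plot/coef methods.

#' Configuration of one training stage
#'
#' @param stage_id one of "S", "D", "P", "G", "baseline" (free-form allowed)
#' @param train_manifest,val_manifest manifest data.frames (or CSV paths)
#'   with image and mask paths
#' @param epochs number of epochs (>= 1)
#' @param learning_rate SGD learning rate (default 0.01)
#' @param batch_size gradient-accumulation batch size
#' @param seed integer seed controlling initialization order, shuffling and
#'   online augmentation
#' @param init_from "scratch", a `segnet`, a `stage_checkpoint`, or a path to
#'   a saved checkpoint
#' @param spec [model_spec()] used when initializing from scratch
#' @param momentum SGD momentum coefficient
#' @param online_augment honour per-record online-augmentation flags in the
#'   training manifest (strong augmentation resampled at every access)
#' @return list of class `stage_config`
#' @export
stage_config <- function(stage_id, train_manifest, val_manifest, epochs = 10L,
                         learning_rate = 0.01, batch_size = 8L, seed = 0L,
                         init_from = "scratch", spec = model_spec(),
                         momentum = 0.9, online_augment = TRUE) {
  if (is.character(train_manifest)) train_manifest <- read_manifest(train_manifest)
  if (is.character(val_manifest)) val_manifest <- read_manifest(val_manifest)
  stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 1)
  if (nrow(train_manifest) == 0) stop("training manifest is empty")
  if (nrow(val_manifest) == 0) stop("validation manifest is empty")
  structure(list(stage_id = stage_id, train_manifest = train_manifest,
                 val_manifest = val_manifest, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 init_from = init_from, spec = spec, momentum = momentum,
                 online_augment = isTRUE(online_augment)),
            class = "stage_config")
}

# Strong augmentation for on-access records: geometric flips applied to
# image and mask together (label inferable), photometric jitter image-only.
strong_augment <- function(image, mask) {
  if (stats::runif(1) < 0.5) {
    image <- image[, dim(image)[2]:1, , drop = FALSE]
    mask <- mask[, ncol(mask):1, drop = FALSE]
  }
  if (stats::runif(1) < 0.5) {
    image <- image[dim(image)[1]:1, , , drop = FALSE]
    mask <- mask[nrow(mask):1, , drop = FALSE]
  }
  image <- clamp01(image * stats::runif(1, 0.85, 1.15))
  if (stats::runif(1) < 0.5)
    image <- add_gaussian_noise(image, stats::runif(1, 0.005, 0.03))
  list(image = image, mask = mask)
}

load_record <- function(row, divisor) {
  img <- read_image(row$image_path)
  msk <- read_mask(row$mask_path)
  pi <- pad_to_multiple(img, divisor)
  pm <- pad_to_multiple(msk, divisor)
  list(x = pi$x, g = pm$x, online = isTRUE(row$online_aug == 1))
}

resolve_init <- function(init_from, spec, seed) {
  if (inherits(init_from, "segnet")) return(init_from)
  if (inherits(init_from, "stage_checkpoint")) return(init_from$model)
  if (identical(init_from, "scratch")) return(build_model(spec, seed))
  if (is.character(init_from)) {
    if (!file.exists(init_from)) stop("init checkpoint not found: ", init_from)
    return(load_checkpoint(init_from)$model)
  }
  stop("init_from must be 'scratch', a model, a checkpoint or a path")
}

sgd_step <- function(weights, vel, grads, lr, momentum, scale) {
  for (nm in names(weights)) {
    vel[[nm]]$w <- momentum * vel[[nm]]$w + grads[[nm]]$w * scale
    vel[[nm]]$b <- momentum * vel[[nm]]$b + grads[[nm]]$b * scale
    weights[[nm]]$w <- weights[[nm]]$w - lr * vel[[nm]]$w
    weights[[nm]]$b <- weights[[nm]]$b - lr * vel[[nm]]$b
  }
  list(weights = weights, vel = vel)
}

zero_like <- function(weights) {
  lapply(weights, function(l) list(w = array(0, dim(l$w)),
                                   b = numeric(length(l$b))))
}

add_grads <- function(acc, g) {
  for (nm in names(acc)) {
    acc[[nm]]$w <- acc[[nm]]$w + g[[nm]]$w
    acc[[nm]]$b <- acc[[nm]]$b + g[[nm]]$b
  }
  acc
}

#' Index of the selected (minimum validation loss) epoch
#' @param val_losses numeric vector of per-epoch validation losses
#' @return integer epoch index (1-based); ties resolve to the earliest epoch
#' @export
select_epoch <- function(val_losses) which.min(val_losses)

#' Train one pipeline stage
#'
#' Minimizes the combined BCE + Dice loss with seeded SGD, evaluating the
#' validation loss after every epoch, and returns the weights of the epoch
#' with the smallest validation loss.
#'
#' @param cfg a [stage_config()]
#' @param epsilon Dice smoothing constant of the loss
#' @param verbose print per-epoch losses
#' @return object of class `stage_checkpoint`: list(stage_id, model, history,
#'   selected_epoch, cfg)
#' @export
train_stage <- function(cfg, epsilon = 1e-5, verbose = FALSE) {
  stopifnot(inherits(cfg, "stage_config"))
  model <- resolve_init(cfg$init_from, cfg$spec, cfg$seed)
  divisor <- model$spec$divisor
  set.seed(cfg$seed)
  train <- lapply(seq_len(nrow(cfg$train_manifest)), function(i)
    load_record(cfg$train_manifest[i, ], divisor))
  val <- lapply(seq_len(nrow(cfg$val_manifest)), function(i)
    load_record(cfg$val_manifest[i, ], divisor))
  n <- length(train)
  vel <- zero_like(model$weights)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(val = Inf, weights = NULL, epoch = NA_integer_)
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    tr_losses <- numeric(0)
    b0 <- 1L
    while (b0 <= n) {
      ids <- perm[b0:min(n, b0 + cfg$batch_size - 1L)]
      acc <- zero_like(model$weights)
      for (i in ids) {
        rec <- train[[i]]
        if (rec$online && cfg$online_augment) {
          sa <- strong_augment(rec$x, rec$g)
          rec$x <- sa$image; rec$g <- sa$mask
        }
        lg <- segnet_loss_grad(model, rec$x, rec$g, epsilon)
        if (!is.finite(lg$loss))
          stop("divergence: non-finite training loss at epoch ", epoch)
        tr_losses <- c(tr_losses, lg$loss)
        acc <- add_grads(acc, lg$grads)
      }
      upd <- sgd_step(model$weights, vel, acc, cfg$learning_rate,
                      cfg$momentum, 1 / length(ids))
      model$weights <- upd$weights
      vel <- upd$vel
      b0 <- b0 + cfg$batch_size
    }
    val_losses <- vapply(val, function(rec) {
      fw <- segnet_forward(model, rec$x)
      loss_grad_single(fw$logits, rec$g, epsilon)$loss
    }, 0)
    vl <- mean(val_losses)
    if (!is.finite(vl))
      stop("divergence: non-finite validation loss at epoch ", epoch)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(tr_losses),
                                         val_loss = vl))
    if (vl < best$val) best <- list(val = vl, weights = model$weights,
                                    epoch = epoch)
    if (verbose)
      message(sprintf("[%s] epoch %d train %.4f val %.4f", cfg$stage_id,
                      epoch, mean(tr_losses), vl))
  }
  model$weights <- best$weights
  structure(list(stage_id = cfg$stage_id, model = model, history = history,
                 selected_epoch = best$epoch, cfg = cfg),
            class = "stage_checkpoint")
}

#' @export
print.stage_checkpoint <- function(x, ...) {
  cat("stage checkpoint '", x$stage_id, "'\n", sep = "")
  cat("  epochs:", nrow(x$history), " selected epoch:", x$selected_epoch,
      sprintf(" (val loss %.4f)\n", x$history$val_loss[x$selected_epoch]))
  invisible(x)
}

#' @export
summary.stage_checkpoint <- function(object, ...) {
  print(object)
  cat("  parameters:", n_params(object$model), "\n")
  print(object$history, row.names = FALSE)
  invisible(object$history)
}

#' Predict a segmentation mask (or probabilities) from a checkpoint
#' @param object a `stage_checkpoint`
#' @param image H x W x 3 array (any size; padded internally)
#' @param type "mask" (binarized at `threshold`) or "prob"
#' @param threshold binarization threshold
#' @param tta use majority-vote test-time augmentation
#' @param ... unused
#' @return H x W matrix
#' @export
predict.stage_checkpoint <- function(object, image, type = c("mask", "prob"),
                                     threshold = 0.5, tta = FALSE, ...) {
  type <- match.arg(type)
  if (type == "prob") return(predict_probs_padded(object$model, image))
  if (tta) return(tta_predict(object$model, image, threshold = threshold))
  binarize(predict_probs_padded(object$model, image), threshold)
}

#' @export
coef.stage_checkpoint <- function(object, ...) {
  unlist(lapply(object$model$weights, function(l) c(l$w, l$b)))
}

#' Plot per-epoch training and validation loss
#' @param x a `stage_checkpoint`
#' @param ... passed to [graphics::matplot()]
#' @export
plot.stage_checkpoint <- function(x, ...) {
  graphics::matplot(x$history$epoch,
                    cbind(x$history$train_loss, x$history$val_loss),
                    type = "b", pch = c(1, 19), lty = 1,
                    xlab = "epoch", ylab = "loss",
                    main = paste("stage", x$stage_id), ...)
  graphics::abline(v = x$selected_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), pch = c(1, 19))
  invisible(x)
}

#' Save a stage checkpoint (weights RDS + JSON sidecar)
#' @param ckpt a `stage_checkpoint`
#' @param path output path for the RDS file; a `.json` sidecar with stage id,
#'   selection record and architecture is written next to it
#' @return `path`, invisibly
#' @export
save_checkpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  side <- list(stage_id = ckpt$stage_id,
               selected_epoch = ckpt$selected_epoch,
               val_loss = ckpt$history$val_loss[ckpt$selected_epoch],
               epochs = nrow(ckpt$history),
               encoder = ckpt$model$spec$encoder,
               widths = ckpt$model$spec$widths,
               seed = ckpt$cfg$seed)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#' @param path RDS path
#' @return a `stage_checkpoint`
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck, "stage_checkpoint")) stop("not a stage checkpoint: ", path)
  ck
}
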