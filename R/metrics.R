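# Overlap metrics, thresholding, photometric majority-vote test-time
# augmentation, and per-domain evaluation reports.

#' Binarize a probability map
#' @param probs H x W matrix of probabilities
#' @param threshold decision threshold in (0,1); a pixel is foreground iff
#'   its probability is >= threshold
#' @return H x W \{0,1\} matrix
#' @export
binarize <- function(probs, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  (probs >= threshold) * 1
}

#' Dice score between two binary masks
#'
#' `2 |O∩E| / (|O| + |E|)`; returns 1 when both masks are empty (perfect
#' agreement convention for the 0/0 case).
#'
#' @param O,E binary masks of identical shape
#' @return Dice score in \[0,1\]
#' @export
dice_score <- function(O, E) {
  if (!all(dim(O) == dim(E))) stop("masks have different shapes")
  o <- sum(O > 0); e <- sum(E > 0)
  if (o + e == 0) return(1)
  2 * sum((O > 0) & (E > 0)) / (o + e)
}

#' Intersection-over-union between two binary masks
#'
#' `|O∩E| / |O∪E|`; returns 1 when both masks are empty.
#'
#' @inheritParams dice_score
#' @return IoU in \[0,1\]
#' @export
iou_score <- function(O, E) {
  if (!all(dim(O) == dim(E))) stop("masks have different shapes")
  un <- sum((O > 0) | (E > 0))
  if (un == 0) return(1)
  sum((O > 0) & (E > 0)) / un
}

#' Pixel-level majority vote over binary masks
#' @param masks list of binary masks of identical shape (odd count avoids ties)
#' @return \{0,1\} matrix; a pixel is foreground iff more than half the masks
#'   vote foreground
#' @export
majority_vote <- function(masks) {
  stopifnot(length(masks) >= 1)
  s <- Reduce(`+`, lapply(masks, function(m) (m > 0) * 1))
  (s > length(masks) / 2) * 1
}

#' Majority-vote test-time augmentation prediction
#'
#' Predicts on the original image plus two photometric variants (Gaussian
#' noise and sepia). Both variants leave pixel positions unchanged, so the
#' three binarized predictions align and are combined by per-pixel majority
#' vote; with three voters there are no ties.
#'
#' @param model a `segnet`
#' @param image H x W x 3 array (any size; padded internally)
#' @param threshold binarization threshold
#' @param rng_seed seed for the Gaussian-noise variant
#' @param noise_sd Gaussian noise standard deviation on the \[0,1\] scale
#' @return H x W \{0,1\} mask
#' @export
tta_predict <- function(model, image, threshold = 0.5, rng_seed = 0L,
                        noise_sd = 0.05) {
  image <- as_image3(image)
  set.seed(rng_seed)
  variants <- list(original = image,
                   gaussian_noise = add_gaussian_noise(image, noise_sd),
                   sepia = sepia(image))
  masks <- lapply(names(variants), function(nm) {
    m <- tryCatch(binarize(predict_probs_padded(model, variants[[nm]]), threshold),
                  error = function(e) stop("TTA variant '", nm, "' failed: ",
                                           conditionMessage(e)))
    m
  })
  majority_vote(masks)
}

#' Evaluate a model over a manifest of annotated images
#'
#' Computes per-image Dice and IoU against the ground-truth masks and
#' macro-averages (mean of per-image scores) overall and per domain.
#'
#' @param model a `segnet` or `stage_checkpoint`
#' @param manifest manifest data.frame (or CSV path) with image_path,
#'   mask_path and domain columns
#' @param tta use majority-vote test-time augmentation
#' @param group_by record column used for per-domain grouping
#' @param threshold binarization threshold
#' @param rng_seed seed for the TTA noise variant
#' @return list of class `eval_report`: records (one row per image: image_id,
#'   domain, dice, iou, tta_used) and summary (overall and per-domain means)
#' @export
evaluate <- function(model, manifest, tta = FALSE, group_by = "domain",
                     threshold = 0.5, rng_seed = 0L) {
  if (inherits(model, "stage_checkpoint")) model <- model$model
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (nrow(manifest) == 0) stop("evaluation manifest is empty")
  missing <- manifest$mask_path[!file.exists(manifest$mask_path)]
  if (length(missing) > 0)
    stop("missing ground-truth mask file: ", missing[1])
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_image(manifest$image_path[i])
    gt <- read_mask(manifest$mask_path[i])
    pred <- if (tta) tta_predict(model, img, threshold, rng_seed)
            else binarize(predict_probs_padded(model, img), threshold)
    data.frame(image_id = manifest$id[i],
               domain = as.character(manifest[[group_by]][i]),
               dice = dice_score(pred, gt), iou = iou_score(pred, gt),
               tta_used = tta, stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rows)
  per_domain <- do.call(rbind, lapply(split(records, records$domain), function(d)
    data.frame(domain = d$domain[1], dice = mean(d$dice), iou = mean(d$iou),
               n = nrow(d), stringsAsFactors = FALSE)))
  rownames(per_domain) <- NULL
  structure(list(records = records,
                 summary = list(overall = list(dice = mean(records$dice),
                                               iou = mean(records$iou),
                                               n = nrow(records)),
                                per_domain = per_domain, tta = tta)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("evaluation over %d images%s: Dice %.4f, IoU %.4f\n",
              x$summary$overall$n, if (x$summary$tta) " (TTA)" else "",
              x$summary$overall$dice, x$summary$overall$iou))
  if (nrow(x$summary$per_domain) > 1) print(x$summary$per_domain, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report (records CSV + summary JSON)
#' @param report an `eval_report` from [evaluate()]
#' @param dir output directory
#' @param prefix file-name prefix
#' @return the directory, invisibly
#' @export
write_eval_report <- function(report, dir, prefix = "eval") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$records, file.path(dir, paste0(prefix, "_records.csv")),
                   row.names = FALSE)
  jsonlite::write_json(report$summary, file.path(dir, paste0(prefix, "_summary.json")),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
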