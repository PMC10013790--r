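# U-Net-style encoder-decoder for binary segmentation, with hand-written
# backpropagation on top of compiled conv/pool/upsample kernels. The final
# 1x1 convolution emits one logit per pixel; probabilities are sigmoids of
# the logits. The architecture is deliberately configurable: the training
# method, not a specific backbone, is the point.

#' Specification of the encoder-decoder architecture
#'
#' `widths` gives the encoder channel widths, one per resolution level; the
#' bottleneck uses twice the deepest width and the decoder mirrors the
#' encoder with skip concatenations. Input sizes must be divisible by
#' `2^length(widths)`.
#'
#' Presets: "tiny" (widths 6, 12; ~17k parameters) for desk-scale training
#' and tests, "base" (widths 16, 32, 64) for larger runs. Pretrained encoder
#' weights are not bundled with the package, so `pretrained_init` must be
#' FALSE; initialization is seeded He-scaled Gaussian.
#'
#' @param encoder preset name, "tiny" or "base"
#' @param widths optional integer vector overriding the preset widths
#' @param pretrained_init must be FALSE (no bundled weights)
#' @return object of class `segnet_spec`
#' @export
model_spec <- function(encoder = c("tiny", "base"), widths = NULL,
                       pretrained_init = FALSE) {
  encoder <- match.arg(encoder)
  if (isTRUE(pretrained_init))
    stop("pretrained encoder weights are not bundled; ",
         "use pretrained_init = FALSE (seeded random initialization)")
  if (is.null(widths))
    widths <- switch(encoder, tiny = c(6L, 12L), base = c(16L, 32L, 64L))
  widths <- as.integer(widths)
  stopifnot(length(widths) >= 1, all(widths >= 1))
  structure(list(encoder = encoder, widths = widths,
                 bottleneck = 2L * widths[length(widths)],
                 divisor = 2L^length(widths), pretrained_init = FALSE),
            class = "segnet_spec")
}

conv_layer <- function(kh, kw, cin, cout) {
  # He-scaled init for ReLU units
  w <- array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
             c(kh, kw, cin, cout))
  list(w = w, b = numeric(cout))
}

#' Build a segmentation model
#'
#' @param spec a [model_spec()]
#' @param seed integer seed for weight initialization
#' @return object of class `segnet`
#' @export
build_model <- function(spec = model_spec(), seed = 0L) {
  stopifnot(inherits(spec, "segnet_spec"))
  set.seed(seed)
  d <- length(spec$widths)
  layers <- list()
  cin <- 3L
  for (l in seq_len(d)) {
    wl <- spec$widths[l]
    layers[[paste0("enc", l, "a")]] <- conv_layer(3, 3, cin, wl)
    layers[[paste0("enc", l, "b")]] <- conv_layer(3, 3, wl, wl)
    cin <- wl
  }
  B <- spec$bottleneck
  layers[["bota"]] <- conv_layer(3, 3, cin, B)
  layers[["botb"]] <- conv_layer(3, 3, B, B)
  up_in <- B
  for (l in rev(seq_len(d))) {
    wl <- spec$widths[l]
    layers[[paste0("dec", l, "a")]] <- conv_layer(3, 3, up_in + wl, wl)
    layers[[paste0("dec", l, "b")]] <- conv_layer(3, 3, wl, wl)
    up_in <- wl
  }
  layers[["out"]] <- conv_layer(1, 1, spec$widths[1], 1L)
  structure(list(spec = spec, weights = layers, seed = seed), class = "segnet")
}

#' Number of trainable parameters of a model
#' @param model a `segnet`
#' @return integer parameter count
#' @export
n_params <- function(model) {
  as.integer(sum(vapply(model$weights, function(l) length(l$w) + length(l$b), 0)))
}

#' @export
print.segnet <- function(x, ...) {
  cat("segnet encoder-decoder ('", x$spec$encoder, "' preset)\n", sep = "")
  cat("  widths:", paste(x$spec$widths, collapse = ", "),
      " bottleneck:", x$spec$bottleneck, "\n")
  cat("  input divisor:", x$spec$divisor, " parameters:", n_params(x), "\n")
  invisible(x)
}

relu <- function(x) { x[x < 0] <- 0; x }

check_input_size <- function(model, x) {
  d <- model$spec$divisor
  dm <- dim(x)
  if (length(dm) != 3L || dm[3] != 3L)
    stop("input must be an H x W x 3 array")
  if (dm[1] %% d != 0 || dm[2] %% d != 0)
    stop("input size ", dm[1], "x", dm[2], " is not divisible by ", d,
         "; pad the image (e.g. with zeros) to a multiple of ", d)
}

cat3 <- function(a, b) {
  array(c(a, b), c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}

# Forward pass; returns logits (H x W matrix) and, optionally, every
# intermediate needed for backprop.
segnet_forward <- function(model, x, keep_cache = FALSE) {
  check_input_size(model, x)
  L <- model$weights
  d <- length(model$spec$widths)
  cache <- list(x = x, enc = vector("list", d), dec = vector("list", d))
  a <- x
  for (l in seq_len(d)) {
    z1 <- cpp_conv2d_fwd(a, L[[paste0("enc", l, "a")]]$w, L[[paste0("enc", l, "a")]]$b)
    a1 <- relu(z1)
    z2 <- cpp_conv2d_fwd(a1, L[[paste0("enc", l, "b")]]$w, L[[paste0("enc", l, "b")]]$b)
    a2 <- relu(z2)
    pool <- cpp_maxpool2_fwd(a2)
    if (keep_cache)
      cache$enc[[l]] <- list(x = a, z1 = z1, a1 = a1, z2 = z2, a2 = a2,
                             idx = pool$idx)
    else
      cache$enc[[l]] <- list(a2 = a2)
    a <- pool$y
  }
  zb1 <- cpp_conv2d_fwd(a, L$bota$w, L$bota$b)
  ab1 <- relu(zb1)
  zb2 <- cpp_conv2d_fwd(ab1, L$botb$w, L$botb$b)
  ab2 <- relu(zb2)
  if (keep_cache) cache$bot <- list(x = a, z1 = zb1, a1 = ab1, z2 = zb2)
  a <- ab2
  for (l in rev(seq_len(d))) {
    u <- cpp_upsample2(a)
    cc <- cat3(u, cache$enc[[l]]$a2)
    z1 <- cpp_conv2d_fwd(cc, L[[paste0("dec", l, "a")]]$w, L[[paste0("dec", l, "a")]]$b)
    a1 <- relu(z1)
    z2 <- cpp_conv2d_fwd(a1, L[[paste0("dec", l, "b")]]$w, L[[paste0("dec", l, "b")]]$b)
    a2 <- relu(z2)
    if (keep_cache)
      cache$dec[[l]] <- list(cc = cc, z1 = z1, a1 = a1, z2 = z2,
                             n_up = dim(u)[3])
    a <- a2
  }
  logits <- cpp_conv2d_fwd(a, L$out$w, L$out$b)
  if (keep_cache) cache$head_in <- a
  list(logits = matrix(logits, dim(logits)[1], dim(logits)[2]),
       cache = if (keep_cache) cache)
}

# Backward pass from dL/dlogits; returns gradients named like the layers.
# The decoder is traversed from the shallowest level (l = 1, where the
# forward pass ended) down to the bottleneck, then the encoder back up.
segnet_backward <- function(model, cache, dlogits) {
  L <- model$weights
  d <- length(model$spec$widths)
  grads <- list()
  dy <- array(dlogits, c(dim(dlogits), 1L))
  bw <- cpp_conv2d_bwd(cache$head_in, L$out$w, dy)
  grads$out <- list(w = bw$dw, b = bw$db)
  da <- bw$dx
  dskips <- vector("list", d)
  for (l in seq_len(d)) {
    dc <- cache$dec[[l]]
    dz2 <- da * (dc$z2 > 0)
    bw2 <- cpp_conv2d_bwd(dc$a1, L[[paste0("dec", l, "b")]]$w, dz2)
    grads[[paste0("dec", l, "b")]] <- list(w = bw2$dw, b = bw2$db)
    dz1 <- bw2$dx * (dc$z1 > 0)
    bw1 <- cpp_conv2d_bwd(dc$cc, L[[paste0("dec", l, "a")]]$w, dz1)
    grads[[paste0("dec", l, "a")]] <- list(w = bw1$dw, b = bw1$db)
    nu <- dc$n_up
    dcc <- bw1$dx
    dskips[[l]] <- dcc[, , (nu + 1):dim(dcc)[3], drop = FALSE]
    da <- cpp_upsample2_bwd(dcc[, , seq_len(nu), drop = FALSE])
  }
  dz <- da * (cache$bot$z2 > 0)
  bwb2 <- cpp_conv2d_bwd(cache$bot$a1, L$botb$w, dz)
  grads$botb <- list(w = bwb2$dw, b = bwb2$db)
  dz <- bwb2$dx * (cache$bot$z1 > 0)
  bwb1 <- cpp_conv2d_bwd(cache$bot$x, L$bota$w, dz)
  grads$bota <- list(w = bwb1$dw, b = bwb1$db)
  da <- bwb1$dx
  for (l in rev(seq_len(d))) {
    ec <- cache$enc[[l]]
    dpool <- cpp_maxpool2_bwd(da, ec$idx, dim(ec$a2)[1], dim(ec$a2)[2])
    da2 <- dpool + dskips[[l]]
    dz2 <- da2 * (ec$z2 > 0)
    bw2 <- cpp_conv2d_bwd(ec$a1, L[[paste0("enc", l, "b")]]$w, dz2)
    grads[[paste0("enc", l, "b")]] <- list(w = bw2$dw, b = bw2$db)
    dz1 <- bw2$dx * (ec$z1 > 0)
    bw1 <- cpp_conv2d_bwd(ec$x, L[[paste0("enc", l, "a")]]$w, dz1)
    grads[[paste0("enc", l, "a")]] <- list(w = bw1$dw, b = bw1$db)
    da <- bw1$dx
  }
  grads
}

#' Combined Dice + binary cross-entropy loss
#'
#' Per image the loss is the soft Dice loss
#' `1 - (2 sum(p g) + eps) / (sum(p) + sum(g) + eps)` plus the mean binary
#' cross-entropy over pixels, where p are sigmoid probabilities of the
#' logits and g the binary targets; the batch loss is the mean over images.
#' Probabilities are clamped to \[1e-7, 1 - 1e-7\] inside the logarithms.
#'
#' @param logits H x W logit matrix, or a list of them (a batch)
#' @param targets binary matrix or list matching `logits`
#' @param epsilon Dice smoothing constant (default 1e-5)
#' @return non-negative scalar loss
#' @export
combined_loss <- function(logits, targets, epsilon = 1e-5) {
  if (!is.list(logits)) { logits <- list(logits); targets <- list(targets) }
  stopifnot(length(logits) == length(targets), epsilon > 0)
  losses <- vapply(seq_along(logits), function(i) {
    loss_grad_single(logits[[i]], targets[[i]], epsilon)$loss
  }, 0)
  mean(losses)
}

# Loss and dL/dlogits for one image.
loss_grad_single <- function(z, g, epsilon = 1e-5) {
  if (!all(dim(z) == dim(g)))
    stop("logits and targets have different shapes")
  if (!all(g %in% c(0, 1)))
    stop("targets must be binary (0/1)")
  p <- stats::plogis(z)
  pc <- pmin(1 - 1e-7, pmax(1e-7, p))
  n <- length(z)
  sp <- sum(p); sg <- sum(g); spg <- sum(p * g)
  denom <- sp + sg + epsilon
  dice_loss <- 1 - (2 * spg + epsilon) / denom
  bce <- -mean(g * log(pc) + (1 - g) * log(1 - pc))
  ddice_dp <- -(2 * g * denom - (2 * spg + epsilon)) / denom^2
  dz <- ddice_dp * p * (1 - p) + (p - g) / n
  list(loss = dice_loss + bce, dlogits = dz)
}

#' Predict per-pixel head probabilities
#'
#' @param model a `segnet`
#' @param image H x W x 3 array; H and W must be divisible by the model's
#'   input-size divisor (see [predict_probs_padded()] for arbitrary sizes)
#' @return H x W matrix of probabilities in (0, 1)
#' @export
predict_probs <- function(model, image) {
  fw <- segnet_forward(model, as_image3(image))
  p <- stats::plogis(fw$logits)
  p[p < 1e-12] <- 1e-12
  p[p > 1 - 1e-12] <- 1 - 1e-12
  p
}

#' Predict probabilities for an image of arbitrary size
#'
#' Zero-pads the image to the next multiple of the model's divisor, predicts
#' and crops back.
#'
#' @inheritParams predict_probs
#' @return H x W probability matrix matching the input size
#' @export
predict_probs_padded <- function(model, image) {
  image <- as_image3(image)
  pd <- pad_to_multiple(image, model$spec$divisor)
  crop_hw(predict_probs(model, pd$x), pd$h, pd$w)
}

# Loss + full gradient for one (image, mask) pair.
segnet_loss_grad <- function(model, x, g, epsilon = 1e-5) {
  fw <- segnet_forward(model, x, keep_cache = TRUE)
  lg <- loss_grad_single(fw$logits, g, epsilon)
  grads <- segnet_backward(model, fw$cache, lg$dlogits)
  list(loss = lg$loss, grads = grads)
}
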