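# Shared fixtures, generated in code and memoised per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, make(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A small annotated field frame plus its cutout banks.
small_scene <- function() {
  fixture("small_scene", function() {
    spec <- field_spec(canvas = c(64L, 64L), n_heads = 5L,
                       head_major = c(6, 10), head_minor = c(3, 5))
    ff <- make_field_frame(spec, seed = 11)
    banks <- build_cutout_banks(ff$frame$image, ff$masks, rng_seed = 7)
    list(spec = spec, frame = ff$frame, masks = ff$masks,
         union = Reduce(pmax, ff$masks), real = banks$real,
         fake = banks$fake)
  })
}

small_background <- function(seed = 21) {
  make_background(field_spec(canvas = c(64L, 64L)), seed = seed)
}

# A trained-for-a-moment tiny model (2 quick epochs on 6 composites);
# weights are arbitrary but finite, good enough for wiring tests.
tiny_trained <- function() {
  fixture("tiny_trained", function() {
    sc <- small_scene()
    dir <- file.path(tempdir(), "tiny_trained_data")
    man <- synthesize_dataset(list(small_background()), sc$real, sc$fake,
                              n_images = 6L, base_seed = 5L, out_dir = dir,
                              n_range = c(3L, 8L),
                              aug = identity_aug_params())
    cfg <- stage_config("S", man, man, epochs = 2L, batch_size = 3L,
                        seed = 1L, spec = model_spec("tiny"))
    train_stage(cfg)
  })
}

# Independent scalar oracle for the combined loss: explicit per-pixel loops,
# no vectorized reuse of the implementation.
loss_oracle <- function(logits_list, targets_list, epsilon = 1e-5) {
  if (!is.list(logits_list)) {
    logits_list <- list(logits_list)
    targets_list <- list(targets_list)
  }
  total <- 0
  for (i in seq_along(logits_list)) {
    z <- logits_list[[i]]; g <- targets_list[[i]]
    sp <- 0; sg <- 0; spg <- 0; bce <- 0
    for (r in seq_len(nrow(z))) {
      for (c in seq_len(ncol(z))) {
        p <- 1 / (1 + exp(-z[r, c]))
        pc <- min(1 - 1e-7, max(1e-7, p))
        sp <- sp + p; sg <- sg + g[r, c]; spg <- spg + p * g[r, c]
        bce <- bce - (g[r, c] * log(pc) + (1 - g[r, c]) * log(1 - pc))
      }
    }
    total <- total + (1 - (2 * spg + epsilon) / (sp + sg + epsilon)) +
      bce / length(z)
  }
  total / length(logits_list)
}
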