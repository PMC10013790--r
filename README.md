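# wheatseg

Semantic segmentation of wheat heads (spikes) in field imagery with almost
no manual annotation. `wheatseg` is for plant-phenotyping researchers who
have a short video clip of a crop field, one or two frames they are willing
to annotate by hand, and no appetite for masking ten thousand images.

## The method

From an annotated frame the package extracts **real head cutouts** and,
using the same footprints as cookie cutters, **fake cutouts** of head-shaped
background texture. Composites are assembled on head-free background frames
— fakes first, then reals, both geometrically augmented — and the union of
the placed real footprints is an exact, computationally derived mask. The
fakes stop the model from keying on paste-boundary artifacts instead of
head appearance.

A U-Net-style encoder–decoder is trained on the composites with the
combined binary cross-entropy + Dice loss (per image):

    L = [1 − (2Σ p·g + ε)/(Σp + Σg + ε)] − (1/N) Σ [g log p + (1−g) log(1−p)]

with ε = 10⁻⁵, sigmoid pixel probabilities p, binary targets g, SGD at
learning rate 0.01, and minimum-validation-loss model selection. Three
domain-adaptation stages then bridge the synthetic-to-real gap:

| stage | training data | warm start |
|-------|---------------|------------|
| S | synthesized composites | scratch |
| D | all 360 integer-degree rotations of the annotated frames, strongly augmented online | S |
| P | pseudo-labeled unlabeled clip frames | D |
| G | a few annotated images, rotation-expanded | P |
| baseline | stage-G data only | scratch |

Prediction offers majority-vote test-time augmentation over the original
image plus Gaussian-noise and sepia variants; evaluation reports Dice
(2|O∩E|/(|O|+|E|)) and IoU (|O∩E|/|O∪E|), overall and per domain.

A procedural field simulator (`field_spec()`, `make_clip()`, ...) generates
textured backgrounds, wheat-like frames with exact instance masks, and
temporally coherent clips, so the entire pipeline is testable end to end
with zero downloads and zero annotation noise.

## Worked example

```r
library(wheatseg)

spec <- field_spec()                                   # 96x96 simulated field
clip <- make_clip(spec, n_frames = 60, drift_px_per_frame = 1, seed = 1)
part <- partition_frames(clip$frames, fps = 5, idx_t = 0, idx_v = 59,
                         n_test = 8, n_val = 4, seed = 1)

banks <- build_cutout_banks(part$w_t$image, clip$masks[[1]], rng_seed = 1)
bgs   <- lapply(1:4, function(i) make_background(spec, seed = 1000 + i))
syn_t <- synthesize_dataset(bgs, banks$real, banks$fake, n_images = 300,
                            base_seed = 0, out_dir = "syn_t")
syn_v <- synthesize_dataset(bgs, banks$real, banks$fake, n_images = 30,
                            base_seed = 100000, out_dir = "syn_v", split = "val")

ckS <- train_stage(stage_config("S", syn_t, syn_v, epochs = 10, seed = 0),
                   verbose = TRUE)
#> [S] epoch 1 train 0.7969 val 0.7261
#> ...
#> [S] epoch 10 train 0.1003 val 0.1050
print(ckS)
#> stage checkpoint 'S'
#>   epochs: 10  selected epoch: 10  (val loss 0.1050)

d_t <- rotations_dataset(part$w_t$image, Reduce(pmax, clip$masks[[1]]),
                         "d_t", online_augment = TRUE)
d_v <- rotations_dataset(part$w_v$image, Reduce(pmax, clip$masks[[60]]),
                         "d_v", split = "val")
ckD <- train_stage(stage_config("D", d_t, d_v, epochs = 2, seed = 1,
                                init_from = ckS))

held_out <- function(ck) mean(sapply(part$test_set, function(f)
  dice_score(predict(ck, f$image), Reduce(pmax, clip$masks[[f$index + 1]]))))
held_out(ckS)   # 0.881  -- trained on composites only
held_out(ckD)   # 0.956  -- after rotation-based domain adaptation
```

The numbers above are from an actual run (seed 1, tiny encoder): the model
trained purely on cut-and-paste composites reaches Dice ≈ 0.88 on held-out
real (simulated) frames, and one adaptation stage on rotations of the two
annotated frames lifts it to ≈ 0.96. `run_pipeline()` chains all five
stages from a single YAML/list config; `inst/cli/wheatseg.R` exposes the
same operations as shell subcommands (`fixtures`, `cutouts`, `synthesize`,
`pipeline`, ...).

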