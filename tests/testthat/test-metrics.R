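rand_mask <- function(h = 8, w = 8, p = 0.4) matrix(as.numeric(rbinom(h * w, 1, p)), h, w)

test_that("binarize follows the >= convention and is idempotent", {
  p <- matrix(0.5, 3, 3)
  expect_identical(binarize(p, 0.5), matrix(1, 3, 3))
  expect_identical(binarize(matrix(0.9, 2, 2), 0.999), matrix(0, 2, 2))
  q <- matrix(runif(25), 5, 5)
  b <- binarize(q)
  expect_identical(binarize(b, 0.5), b)
})

test_that("dice and iou reproduce their closed-form examples", {
  a <- matrix(0, 4, 4); a[1:2, 1:2] <- 1
  expect_identical(dice_score(a, a), 1)
  expect_identical(iou_score(a, a), 1)
  b <- matrix(0, 4, 4); b[3:4, 3:4] <- 1
  expect_identical(dice_score(a, b), 0)
  # |O| = |E| = 4 with overlap 2 -> Dice 0.5, IoU 1/3
  c2 <- matrix(0, 4, 4); c2[1:2, 2:3] <- 1
  expect_identical(dice_score(a, c2), 0.5)
  expect_equal(iou_score(a, c2), 1 / 3, tolerance = 1e-15)
  # both-empty convention
  z <- matrix(0, 3, 3)
  expect_identical(dice_score(z, z), 1)
  expect_identical(iou_score(z, z), 1)
  expect_error(dice_score(a, matrix(0, 3, 3)), "shapes")
  expect_error(iou_score(a, matrix(0, 3, 3)), "shapes")
})

test_that("dice and iou satisfy their functional identity on random pairs", {
  set.seed(12)
  for (rep in 1:200) {
    o <- rand_mask(); e <- rand_mask()
    d <- dice_score(o, e); i <- iou_score(o, e)
    expect_lt(abs(d - 2 * i / (1 + i)), 1e-12)
    expect_true(d >= 0 && d <= 1 && i >= 0 && i <= 1)
  }
})

test_that("majority vote matches a brute-force count and is symmetric", {
  set.seed(3)
  for (rep in 1:20) {
    ms <- list(rand_mask(5, 5), rand_mask(5, 5), rand_mask(5, 5))
    v <- majority_vote(ms)
    brute <- matrix(0, 5, 5)
    for (i in 1:5) for (j in 1:5) {
      votes <- sum(ms[[1]][i, j], ms[[2]][i, j], ms[[3]][i, j])
      brute[i, j] <- as.numeric(votes >= 2)
    }
    expect_identical(v, brute)
    expect_identical(majority_vote(ms[c(3, 1, 2)]), v)
    expect_identical(majority_vote(ms[c(2, 3, 1)]), v)
  }
  # injected votes: (1,1,0) -> 1 and (0,0,1) -> 0
  expect_identical(majority_vote(list(matrix(1, 1, 1), matrix(1, 1, 1),
                                      matrix(0, 1, 1))), matrix(1, 1, 1))
  expect_identical(majority_vote(list(matrix(0, 1, 1), matrix(0, 1, 1),
                                      matrix(1, 1, 1))), matrix(0, 1, 1))
  # unanimity
  m <- rand_mask()
  expect_identical(majority_vote(list(m, m, m)), m)
})

test_that("tta_predict is the majority vote of its three photometric variants", {
  ck <- tiny_trained()
  img <- small_background(33)$image
  tta <- tta_predict(ck$model, img, rng_seed = 6)
  set.seed(6)
  noisy <- add_gaussian_noise(img, 0.05)
  votes <- list(binarize(predict_probs_padded(ck$model, img)),
                binarize(predict_probs_padded(ck$model, noisy)),
                binarize(predict_probs_padded(ck$model, sepia(img))))
  expect_identical(tta, majority_vote(votes))
})

test_that("evaluate macro-averages per image and groups by domain", {
  ck <- tiny_trained()
  dir <- tempfile("eval")
  dir.create(file.path(dir, "img"), recursive = TRUE)
  rows <- list()
  set.seed(9)
  for (i in 1:4) {
    img <- small_background(40 + i)$image
    ip <- file.path(dir, "img", sprintf("im%d.png", i))
    mp <- file.path(dir, "img", sprintf("gt%d.png", i))
    write_image(img, ip)
    pred <- binarize(predict_probs_padded(ck$model, read_image(ip)))
    if (i <= 2) {
      write_mask(pred, mp)  # perfect agreement by construction
    } else {
      write_mask(1 - pred, mp)  # complemented ground truth
    }
    rows[[i]] <- wheatseg:::manifest_row(sprintf("im%d", i), ip, mp, "test",
                                         "eval", domain = c("A", "B")[(i > 2) + 1])
  }
  manifest <- do.call(rbind, rows)
  rep <- evaluate(ck, manifest)
  expect_identical(nrow(rep$records), 4L)
  expect_equal(rep$records$dice[1:2], c(1, 1))
  expect_equal(rep$summary$overall$dice, mean(rep$records$dice))
  pd <- rep$summary$per_domain
  expect_identical(sort(pd$domain), c("A", "B"))
  expect_equal(pd$dice[pd$domain == "A"], 1)
  expect_error(evaluate(ck, manifest[0, ]), "empty")
  file.remove(manifest$mask_path[1])
  expect_error(evaluate(ck, manifest), "missing ground-truth mask")
})
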