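# Pixelwise multi-label metrics and stitched evaluation.

test_that("binarize thresholds with the >= boundary convention", {
  p <- array(c(0, 0.25, 0.5, 0.75, 1), c(5, 1, 1))
  b <- binarize(p, 0.5)
  expect_equal(as.vector(b), c(0, 0, 1, 1, 1))
  expect_true(all(binarize(array(0, c(3, 3, 4))) == 0))
  expect_error(binarize(p, 1.5), "threshold")
  # random map vs naive per-pixel comparison
  set.seed(2)
  pm <- array(runif(8 * 8 * 4), c(8, 8, 4))
  bb <- binarize(pm, 0.3)
  for (i in 1:8) for (j in 1:8) for (ch in 1:4)
    expect_equal(bb[i, j, ch], as.integer(pm[i, j, ch] >= 0.3))
})

test_that("confusion counts match hand-built examples", {
  p <- matrix(0L, 8, 8); t <- matrix(0L, 8, 8)
  p[1, 1:3] <- 1L          # 3 predicted
  t[1, 2:4] <- 1L          # 3 true, 2 shared
  cc <- confusion_counts(p, t)
  expect_equal(c(cc$tp, cc$fp, cc$fn), c(2, 1, 1))
  # identical masks
  cc <- confusion_counts(t, t)
  expect_equal(c(cc$tp, cc$fp, cc$fn), c(3, 0, 0))
  # both empty
  cc <- confusion_counts(matrix(0L, 4, 4), matrix(0L, 4, 4))
  expect_equal(c(cc$tp, cc$fp, cc$fn), c(0, 0, 0))
  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("metric formulas and the degenerate convention", {
  c1 <- data.frame(tp = 2, fp = 1, fn = 1)
  expect_equal(f1_from_counts(c1), 2 / 3)
  expect_equal(sensitivity_from_counts(c1), 2 / 3)
  expect_equal(iou_from_counts(c1), 0.5)
  # harmonic-mean cross-check: precision = recall = 2/3
  expect_equal(f1_from_counts(c1), 2 * (2/3 * 2/3) / (2/3 + 2/3))
  # perfect and degenerate
  cp <- data.frame(tp = 7, fp = 0, fn = 0)
  expect_equal(f1_from_counts(cp), 1)
  c0 <- data.frame(tp = 0, fp = 0, fn = 0)
  expect_equal(f1_from_counts(c0), 1)
  expect_equal(sensitivity_from_counts(c0), 1)
  expect_equal(iou_from_counts(c0), 1)
})

test_that("iou <= f1 and f1 = 2 iou / (1 + iou) on random counts", {
  set.seed(31)
  counts <- data.frame(tp = rpois(300, 5), fp = rpois(300, 3),
                       fn = rpois(300, 3))
  counts <- counts[counts$tp + counts$fp + counts$fn > 0, ]
  f1 <- f1_from_counts(counts)
  iou <- iou_from_counts(counts)
  expect_true(all(iou <= f1 + 1e-12))
  expect_equal(f1, 2 * iou / (1 + iou))
})

test_that("confusion counting agrees with the brute-force pixel loop", {
  set.seed(17)
  for (i in 1:25) {
    pred <- array(rbinom(8 * 8 * 4, 1, 0.4), c(8, 8, 4))
    targ <- array(rbinom(8 * 8 * 4, 1, 0.4), c(8, 8, 4))
    fast <- confusion_counts(pred, targ)
    slow <- brute_confusion(pred, targ)
    expect_equal(fast$tp, slow$tp)
    expect_equal(fast$fp, slow$fp)
    expect_equal(fast$fn, slow$fn)
  }
})

test_that("oracle evaluation is perfect for any tile count", {
  cfg <- tiny_gen_config()
  imgs <- lapply(1:2, function(i) {
    li <- generate_image(cfg, seed = i); li$id <- paste0("im", i); li
  })
  for (nt in c(1, 5, 12)) {
    rep <- evaluate_model(oracle_model(), imgs, n_tiles = nt)
    expect_true(all(rep$per_channel$f1 == 1))
    expect_true(all(rep$per_channel$iou == 1))
  }
})

test_that("an all-zero predictor scores sensitivity and f1 of 0", {
  cfg <- tiny_gen_config()
  li <- generate_image(cfg, seed = 3); li$id <- "im1"
  m <- tiny_model()
  m$params$head$w[] <- 0
  m$params$head$b[] <- -50     # saturated: probabilities ~ 0
  rep <- evaluate_model(m, list(li), n_tiles = 2)
  tab <- rep$per_channel
  nonempty <- tab$tp + tab$fn > 0
  expect_true(all(tab$sensitivity[nonempty] == 0))
  expect_true(all(tab$f1[nonempty] == 0))
})

test_that("micro pooling equals summed per-image brute-force counts", {
  cfg <- tiny_gen_config()
  imgs <- lapply(1:5, function(i) {
    li <- generate_image(cfg, seed = 10 + i); li$id <- paste0("im", i); li
  })
  om <- oracle_model(corrupt_period = 7)
  rep <- evaluate_model(om, imgs, n_tiles = 4)
  # independent accumulation: predict each image in full, count, sum
  acc <- data.frame(tp = rep(0, 4), fp = rep(0, 4), fn = rep(0, 4))
  for (li in imgs) {
    pred <- binarize(tileseg:::predict_image(om, li, 4), 0.5)
    cc <- brute_confusion(pred, li$mask)
    acc$tp <- acc$tp + cc$tp; acc$fp <- acc$fp + cc$fp
    acc$fn <- acc$fn + cc$fn
  }
  tab <- rep$per_channel[1:4, ]
  expect_equal(tab$tp, acc$tp)
  expect_equal(tab$fp, acc$fp)
  expect_equal(tab$fn, acc$fn)
  expect_equal(tab$f1, f1_from_counts(acc))
  # image order does not matter (micro pooling commutes)
  rep_rev <- evaluate_model(om, rev(imgs), n_tiles = 4)
  expect_equal(rep_rev$per_channel, rep$per_channel)
})

test_that("corrupted-oracle metrics are independent of tile count", {
  cfg <- tiny_gen_config()
  imgs <- lapply(1:3, function(i) {
    li <- generate_image(cfg, seed = 20 + i); li$id <- paste0("im", i); li
  })
  om <- oracle_model(corrupt_period = 5)
  reps <- lapply(c(1, 4, 10, 18), function(nt)
    evaluate_model(om, imgs, n_tiles = nt)$per_channel)
  for (k in 2:4) expect_equal(reps[[k]], reps[[1]])
  # and it is genuinely imperfect, so the check has teeth
  expect_lt(reps[[1]]$f1[reps[[1]]$channel == "overall"], 1)
})

test_that("stitched evaluation with one tile equals direct evaluation", {
  cfg <- tiny_gen_config()
  li <- generate_image(cfg, seed = 9); li$id <- "im1"
  m <- tiny_model(input_size = 32, depth = 2, base_width = 4, seed = 2)
  stitched <- tileseg:::predict_image(m, li, 1)
  direct <- predict_tiles(m, list(li$image))[[1]]
  expect_equal(stitched, direct)
})
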