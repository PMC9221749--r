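# Dice loss, augmentation, plateau schedule, fit.

test_that("dice loss closed forms", {
  # perfect binary agreement -> exactly 0 for any eps
  t <- array(rbinom(200, 1, 0.3), c(5, 10, 4))
  expect_equal(dice_loss(t * 1.0, t, eps = 1), 0)
  expect_equal(dice_loss(t * 1.0, t, eps = 1e-7), 0)

  # uniform 0.5 vs all ones, eps -> 0: dice = 2(.5n)/(.5n + n) = 2/3
  p <- array(0.5, c(6, 6, 4, 2))
  t1 <- array(1, c(6, 6, 4, 2))
  expect_equal(dice_loss(p, t1, eps = 1e-12), 1 / 3, tolerance = 1e-9)

  # disjoint single-pixel prediction vs single-pixel target, eps = 1:
  # dice = (0 + 1) / (1 + 1 + 1) = 1/3, loss = 2/3
  p2 <- array(0, c(4, 4, 1, 1)); p2[1, 1, 1, 1] <- 1
  t2 <- array(0, c(4, 4, 1, 1)); t2[2, 2, 1, 1] <- 1
  expect_equal(dice_loss(p2, t2, eps = 1), 2 / 3)

  expect_error(dice_loss(array(0, c(2, 2, 4)), array(0, c(2, 3, 4))),
               "shape")
})

test_that("dice loss stays in [0,1] and is permutation invariant", {
  set.seed(11)
  for (i in 1:20) {
    p <- array(runif(8 * 8 * 4), c(8, 8, 4, 1))
    t <- array(rbinom(8 * 8 * 4, 1, 0.4), c(8, 8, 4, 1))
    l <- dice_loss(p, t)
    expect_gte(l, 0); expect_lte(l, 1)
    # same pixel permutation of probs and targets leaves the loss alone
    perm <- sample(64)
    pp <- p; tt <- t
    for (ch in 1:4) {
      pm <- matrix(p[, , ch, 1], 64)[perm]
      tm <- matrix(t[, , ch, 1], 64)[perm]
      pp[, , ch, 1] <- matrix(pm, 8, 8)
      tt[, , ch, 1] <- matrix(tm, 8, 8)
    }
    expect_equal(dice_loss(pp, tt), l)
  }
})

test_that("dice gradient matches finite differences", {
  set.seed(12)
  p <- array(runif(36, 0.1, 0.9), c(3, 3, 2, 2))
  t <- array(rbinom(36, 1, 0.5), c(3, 3, 2, 2))
  g <- tileseg:::dice_loss_grad(p, t, eps = 1)
  eps <- 1e-6
  for (i in seq(1, 36, by = 5)) {
    pp <- p; pp[i] <- pp[i] + eps
    pm <- p; pm[i] <- pm[i] - eps
    num <- (dice_loss(pp, t, 1) - dice_loss(pm, t, 1)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-6)
  }
})

test_that("augmentation contracts hold", {
  set.seed(3)
  img <- matrix(runif(32 * 48, 0, 255), 32, 48)
  msk <- array(rbinom(32 * 48 * 4, 1, 0.25), c(32, 48, 4))

  # all probabilities zero -> identity on image and mask
  off <- aug_config(p_flip = 0, max_rotate = 0, p_photometric = 0)
  a <- augment(img, msk, off)
  expect_equal(a$image, img)
  expect_identical(a$mask, msk)

  # masks stay binary under any augmentation
  on <- aug_config(p_flip = 1, max_rotate = 10, p_photometric = 1)
  for (i in 1:10) {
    a <- augment(img, msk, on)
    expect_true(all(a$mask %in% c(0, 1)))
    expect_true(all(a$image >= 0 & a$image <= 255))
  }

  # the fused C++ rotation matches the plain R reference
  for (ang in c(-7.3, 0, 9.9)) {
    rot <- tileseg:::cpp_rotate_pair(img, msk, dim(msk), ang)
    expect_equal(rot$image, tileseg:::rotate_map(img, ang, "bilinear"),
                 tolerance = 1e-12)
    for (ch in 1:4)
      expect_true(mean(rot$mask[, , ch] ==
                         tileseg:::rotate_map(msk[, , ch], ang,
                                              "nearest")) > 0.999)
  }

  # horizontal flip is an involution
  flip_only <- aug_config(p_flip = 1, max_rotate = 0, p_photometric = 0)
  once <- augment(img, msk, flip_only)
  twice <- augment(once$image, once$mask, flip_only)
  expect_equal(twice$image, img)
  expect_identical(twice$mask, msk)
})

test_that("plateau schedule reproduces exact trigger epochs", {
  # scripted flat sequence: first epoch improves on Inf, then 10 flat
  # epochs -> reduce after epoch 6, stop after epoch 11
  flat <- rep(0.5, 20)
  s <- plateau_schedule(flat, patience = 5)
  expect_equal(s$lr_reduction_epoch, 6)
  expect_equal(s$stop_epoch, 11)
  expect_equal(s$lr_stage, c(rep(1L, 5), rep(2L, 6)))

  # monotone improvement: never reduce, never stop
  s <- plateau_schedule(seq(1, 0.1, length.out = 30), patience = 5)
  expect_true(is.na(s$lr_reduction_epoch))
  expect_true(is.na(s$stop_epoch))

  # improvement right after the reduction resets the counter
  v <- c(0.5, rep(0.5, 5), 0.3, rep(0.3, 5))
  s <- plateau_schedule(v, patience = 5)
  expect_equal(s$lr_reduction_epoch, 6)
  expect_equal(s$stop_epoch, 12)
})

test_that("schedule agrees with brute-force reference on random sequences", {
  set.seed(99)
  for (i in 1:200) {
    v <- round(runif(sample(5:40, 1)), 2)
    patience <- sample(2:6, 1)
    a <- plateau_schedule(v, patience = patience)
    b <- brute_schedule(v, patience = patience)
    expect_equal(a$lr_reduction_epoch, b$lr_reduction_epoch)
    expect_equal(a$stop_epoch, b$stop_epoch)
    # at most one reduction; stop never precedes reduction
    if (!is.na(a$stop_epoch)) {
      expect_false(is.na(a$lr_reduction_epoch))
      expect_gt(a$stop_epoch, a$lr_reduction_epoch)
    }
  }
})

test_that("train_config validates invariants", {
  expect_error(train_config(initial_lr = 1e-4, reduced_lr = 1e-3), "reduced")
  expect_error(train_config(patience = 0), "patience")
  expect_error(train_config(batch_size = 0), "batch_size")
})

test_that("fit is deterministic and records a consistent history", {
  tiles <- make_tiles(n_images = 2, n_tiles = 4)
  cfg <- train_config(initial_lr = 1e-3, reduced_lr = 1e-4,
                      batch_size = 4, max_epochs = 4, seed = 2)
  m <- tiny_model(input_size = 32, depth = 2, base_width = 4, seed = 6)
  r1 <- fit(m, tiles[1:6], tiles[7:8], cfg)
  r2 <- fit(m, tiles[1:6], tiles[7:8], cfg)
  expect_identical(r1$history$epochs, r2$history$epochs)
  expect_identical(r1$model$params, r2$model$params)
  h <- r1$history$epochs
  expect_equal(h$epoch, seq_len(nrow(h)))
  expect_true(all(diff(h$lr) <= 0))
  expect_lte(r1$history$stop_epoch, cfg$max_epochs)
  expect_error(fit(m, list(), tiles[1:2], cfg), "empty")
})

test_that("the model can overfit a handful of tiles", {
  # capacity check: 5 training tiles, enough epochs, loss below 0.1;
  # batch size 1 gives 5 optimization steps per epoch, enough for the
  # from-scratch net to memorize within the 200-epoch cap
  tiles <- make_tiles(n_images = 2, n_tiles = 4, seed = 40)
  cfg <- train_config(initial_lr = 1e-3, reduced_lr = 1e-4,
                      batch_size = 1, max_epochs = 200, min_delta = 0,
                      seed = 8)
  m <- tiny_model(input_size = 32, depth = 2, base_width = 8, seed = 3)
  off <- aug_config(p_flip = 0, max_rotate = 0, p_photometric = 0)
  res <- fit(m, tiles[1:5], tiles[1:5], cfg, aug = off)
  expect_lt(tail(res$history$epochs$train_loss, 1), 0.1)
})
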