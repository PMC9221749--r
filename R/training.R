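# Training: multi-label soft Dice loss, paired image/mask augmentation,
# Adam, plateau learning-rate reduction and two-stage early stopping.

#' Training configuration
#'
#' The plateau schedule follows the two-stage rule: if the best
#' validation loss has not improved for `patience` consecutive epochs the
#' learning rate drops from `initial_lr` to `reduced_lr`; if after the
#' reduction another `patience` epochs pass without improvement, training
#' stops. "Improvement" means `val_loss < best - min_delta`. Weights from
#' the epoch with the best validation loss are restored at the end.
#'
#' @param initial_lr,reduced_lr Adam learning rates; `reduced_lr <
#'   initial_lr`. Defaults follow the literal protocol values
#'   10 x 10^-4 = 1e-3 and 10 x 10^-5 = 1e-4; the alternative reading
#'   (1e-4/1e-5) is one configuration away.
#' @param beta1 Adam first-moment decay (the "momentum" 0.9).
#' @param beta2 Adam second-moment decay.
#' @param batch_size Tiles per optimization step (reference protocol: 50;
#'   desk-scale default 8).
#' @param patience Epochs without improvement before LR reduction, and
#'   again before stopping.
#' @param max_epochs Hard cap on epochs.
#' @param dice_eps Smoothing constant of the soft Dice loss.
#' @param min_delta Minimum decrease in validation loss that counts as
#'   improvement.
#' @param seed Seed for shuffling and augmentation draws.
#' @return A `train_config` object.
#' @export
train_config <- function(initial_lr = 1e-3, reduced_lr = 1e-4, beta1 = 0.9,
                         beta2 = 0.999, batch_size = 8, patience = 5,
                         max_epochs = 60, dice_eps = 1, min_delta = 1e-4,
                         seed = 1L) {
  if (reduced_lr >= initial_lr) stop("reduced_lr must be < initial_lr")
  if (patience < 1) stop("patience must be >= 1")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(initial_lr = initial_lr, reduced_lr = reduced_lr,
                 beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 dice_eps = dice_eps, min_delta = min_delta,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Soft Dice loss
#'
#' For each channel `c`, the smoothed Dice coefficient is
#' `(2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)`; the loss is one
#' minus its mean. With `batch_pooled = TRUE` (the training default, and
#' how multi-label segmentation libraries compute Dice) the channel sums
#' run over all pixels of the whole batch, which keeps the gradient on
#' sparse classes well conditioned; with `batch_pooled = FALSE` the
#' coefficient is computed per (channel, batch element) and averaged.
#' With binary predictions equal to the targets the loss is exactly 0
#' for any `eps > 0` under either mode.
#'
#' @param probs Probability array, `(H, W, C)` or `(H, W, C, N)`, values
#'   in `[0, 1]`.
#' @param targets Binary array of matching shape.
#' @param eps Smoothing constant.
#' @param batch_pooled Pool the channel sums across the batch (default).
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(probs, targets, eps = 1, batch_pooled = TRUE) {
  if (!identical(dim(probs), dim(targets)))
    stop("probs and targets must have the same shape")
  p <- as4d(probs); t <- as4d(targets)
  d <- dim(p)
  pm <- matrix(p, d[1] * d[2])          # pixels x (C*N)
  tm <- matrix(t, d[1] * d[2])
  inter <- colSums(pm * tm)
  psum <- colSums(pm); tsum <- colSums(tm)
  if (batch_pooled && d[4] > 1) {
    ch <- rep(seq_len(d[3]), times = d[4])
    inter <- tapply(inter, ch, sum)
    psum <- tapply(psum, ch, sum)
    tsum <- tapply(tsum, ch, sum)
  }
  dice <- (2 * inter + eps) / (psum + tsum + eps)
  1 - mean(dice)
}

# gradient of dice_loss wrt probs (same shape as probs)
dice_loss_grad <- function(probs, targets, eps = 1, batch_pooled = TRUE) {
  p <- as4d(probs); t <- as4d(targets)
  d <- dim(p)
  pm <- matrix(p, d[1] * d[2])
  tm <- matrix(t, d[1] * d[2])
  inter <- colSums(pm * tm)
  psum <- colSums(pm); tsum <- colSums(tm)
  if (batch_pooled && d[4] > 1) {
    ch <- rep(seq_len(d[3]), times = d[4])
    num <- (2 * tapply(inter, ch, sum) + eps)[ch]
    den <- (tapply(psum, ch, sum) + tapply(tsum, ch, sum) + eps)[ch]
    k <- d[3]
  } else {
    num <- 2 * inter + eps
    den <- psum + tsum + eps
    k <- d[3] * d[4]
  }
  # d dice_j / dp_i = (2 t_i * den_j - num_j) / den_j^2
  g <- -(sweep(tm, 2, 2 / den, "*") - matrix(num / den^2, d[1] * d[2],
                                             ncol(pm), byrow = TRUE)) / k
  array(g, dim(probs))
}

#' Augmentation configuration
#'
#' Geometric transforms are applied identically to image and mask (the
#' mask via nearest-neighbour resampling, so it stays binary);
#' photometric transforms touch the image only.
#'
#' @param p_flip Probability of a horizontal flip.
#' @param max_rotate Maximum absolute rotation (degrees); the angle is
#'   drawn uniformly in `[-max_rotate, max_rotate]` on every call.
#' @param p_photometric Probability of each photometric transform
#'   (brightness/contrast, blur, sharpen, Gaussian noise).
#' @param brightness,contrast Maximum relative change (0.2 = +/-20%).
#' @param max_blur_sigma Maximum Gaussian blur sigma (pixels).
#' @param max_noise_sd Maximum additive noise SD on the 0..255 scale.
#' @return An `aug_config` object.
#' @export
aug_config <- function(p_flip = 0.5, max_rotate = 10, p_photometric = 0.2,
                       brightness = 0.2, contrast = 0.2,
                       max_blur_sigma = 1.5, max_noise_sd = 5) {
  structure(list(p_flip = p_flip, max_rotate = max_rotate,
                 p_photometric = p_photometric, brightness = brightness,
                 contrast = contrast, max_blur_sigma = max_blur_sigma,
                 max_noise_sd = max_noise_sd),
            class = "aug_config")
}

# rotate by `angle` degrees about the centre via inverse mapping;
# method "bilinear" (image) or "nearest" (mask); out-of-frame pixels get
# `fill`
rotate_map <- function(x, angle, method, fill = 0) {
  co <- rotate_coords(nrow(x), ncol(x), angle)
  if (method == "nearest") rotate_apply_nearest(x, co, fill)
  else rotate_apply_bilinear(x, co, fill)
}

rotate_coords <- function(h, w, angle) {
  th <- angle * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h) - cy, h, w)
  xx <- matrix(rep(seq_len(w) - cx, each = h), h, w)
  sy <- cos(th) * yy - sin(th) * xx + cy
  sx <- sin(th) * yy + cos(th) * xx + cx
  ok <- sy >= 1 & sy <= h & sx >= 1 & sx <= w
  list(h = h, w = w, sy = sy, sx = sx, ok = as.vector(ok))
}

rotate_apply_nearest <- function(x, co, fill = 0) {
  ry <- pmin(pmax(round(co$sy), 1), co$h)
  rx <- pmin(pmax(round(co$sx), 1), co$w)
  idx <- as.vector(ry) + (as.vector(rx) - 1) * co$h
  out <- matrix(fill, co$h, co$w)
  out[co$ok] <- x[idx[co$ok]]
  out
}

rotate_apply_bilinear <- function(x, co, fill = 0) {
  h <- co$h; w <- co$w
  y0 <- floor(co$sy); x0 <- floor(co$sx)
  fy <- as.vector(co$sy - y0); fx <- as.vector(co$sx - x0)
  y0c <- as.vector(pmin(pmax(y0, 1), h)); y1c <- as.vector(pmin(pmax(y0 + 1, 1), h))
  x0c <- as.vector(pmin(pmax(x0, 1), w)); x1c <- as.vector(pmin(pmax(x0 + 1, 1), w))
  v <- (1 - fy) * (1 - fx) * x[y0c + (x0c - 1) * h] +
       (1 - fy) * fx       * x[y0c + (x1c - 1) * h] +
       fy       * (1 - fx) * x[y1c + (x0c - 1) * h] +
       fy       * fx       * x[y1c + (x1c - 1) * h]
  out <- matrix(fill, h, w)
  out[co$ok] <- v[co$ok]
  out
}

gauss_blur <- function(x, sigma) {
  a <- gauss_blur_matrix(nrow(x), sigma)
  b <- gauss_blur_matrix(ncol(x), sigma)
  a %*% x %*% t(b)
}

#' Augment an image/mask pair
#'
#' Geometric: horizontal flip (probability `p_flip`) and rotation
#' (uniform in +/- `max_rotate` degrees), applied identically to image
#' and all mask channels (mask via nearest-neighbour, so values stay
#' binary). Photometric, each with probability `p_photometric`, applied
#' to the image only: brightness/contrast scaling, Gaussian blur,
#' unsharp-mask sharpening, additive Gaussian noise. Draws come from the
#' current RNG state; seed externally for reproducibility.
#'
#' @param image 2-D intensity matrix (0..255).
#' @param mask `(H, W, C)` binary array aligned with `image`.
#' @param config An [aug_config()].
#' @return List with `image` and `mask`.
#' @export
augment <- function(image, mask, config = aug_config()) {
  img <- image
  msk <- mask
  if (config$p_flip > 0 && runif(1) < config$p_flip) {
    img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
    msk <- msk[, rev(seq_len(ncol(img))), , drop = FALSE]
  }
  if (config$max_rotate > 0) {
    ang <- runif(1, -config$max_rotate, config$max_rotate)
    rot <- cpp_rotate_pair(img * 1.0, msk, dim(msk), ang)
    img <- rot$image
    msk <- rot$mask
  }
  if (runif(1) < config$p_photometric) {   # brightness / contrast
    br <- runif(1, -config$brightness, config$brightness) * 255
    ct <- 1 + runif(1, -config$contrast, config$contrast)
    img <- (img - 127.5) * ct + 127.5 + br
  }
  if (runif(1) < config$p_photometric) {   # blur
    # sigma quantized to 0.05 px so blur matrices can be memoised
    img <- gauss_blur(img, round(runif(1, 0.3, config$max_blur_sigma) / 0.05) * 0.05)
  }
  if (runif(1) < config$p_photometric) {   # sharpen (unsharp mask)
    amount <- runif(1, 0.3, 1)
    img <- img + amount * (img - gauss_blur(img, 1))
  }
  if (runif(1) < config$p_photometric) {   # gaussian noise
    img <- img + matrix(rnorm(length(img), 0, runif(1, 0, config$max_noise_sd)),
                        nrow(img))
  }
  img <- pmin(pmax(img, 0), 255)
  list(image = img, mask = msk)
}

# --- plateau/early-stop state machine -----------------------------------
# Exposed as a pure object so the exact trigger epochs can be tested with
# scripted validation losses.

schedule_init <- function(patience, min_delta) {
  list(best = Inf, since = 0L, reduced = FALSE, epoch = 0L,
       patience = as.integer(patience), min_delta = min_delta,
       best_epoch = 0L, reduce_epoch = NA_integer_,
       stop_epoch = NA_integer_)
}

# feed one validation loss; returns the updated state with $action in
# c("none", "reduce", "stop")
schedule_update <- function(state, val_loss) {
  state$epoch <- state$epoch + 1L
  state$action <- "none"
  if (val_loss < state$best - state$min_delta) {
    state$best <- val_loss
    state$best_epoch <- state$epoch
    state$since <- 0L
  } else {
    state$since <- state$since + 1L
    if (state$since >= state$patience) {
      if (!state$reduced) {
        state$reduced <- TRUE
        state$reduce_epoch <- state$epoch
        state$since <- 0L
        state$action <- "reduce"
      } else {
        state$stop_epoch <- state$epoch
        state$action <- "stop"
      }
    }
  }
  state
}

#' Replay the plateau schedule on a scripted loss sequence
#'
#' Pure simulation of the reduce-then-stop state machine, for auditing
#' exact trigger epochs.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param patience Non-improving epochs before each stage triggers.
#' @param min_delta Improvement threshold.
#' @return List with `lr_reduction_epoch`, `stop_epoch` (NA if never
#'   triggered) and `lr_stage` (1 or 2 per epoch actually run).
#' @export
plateau_schedule <- function(val_losses, patience = 5, min_delta = 1e-4) {
  st <- schedule_init(patience, min_delta)
  stages <- integer(0)
  for (v in val_losses) {
    st <- schedule_update(st, v)
    stages <- c(stages, if (st$reduced) 2L else 1L)
    if (st$action == "stop") break
  }
  list(lr_reduction_epoch = st$reduce_epoch, stop_epoch = st$stop_epoch,
       lr_stage = stages)
}

# --- Adam ----------------------------------------------------------------

# Adam over every tensor of every layer (conv weights/biases and the
# instance-norm affine parameters alike).
adam_init <- function(params) {
  lapply(params, function(l)
    lapply(l, function(v) list(m = v * 0, v = v * 0)))
}

adam_step <- function(params, grads, state, lr, beta1, beta2, t,
                      eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    for (f in names(params[[nm]])) {
      s <- state[[nm]][[f]]
      g <- grads[[nm]][[f]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      params[[nm]][[f]] <- params[[nm]][[f]] -
        lr * (s$m / bc1) / (sqrt(s$v / bc2) + eps)
      state[[nm]][[f]] <- s
    }
  }
  list(params = params, state = state)
}

# --- fit -----------------------------------------------------------------

# resize a tile pair to the model input resolution (image bilinear, mask
# nearest, so masks stay binary)
prep_tile <- function(tile, s) {
  list(image = resize_bilinear(tile$image, s, s),
       mask = resize_nearest(tile$mask, s, s))
}

#' Train a model on tiles
#'
#' Runs the epoch loop: seeded shuffling, augmentation of training tiles,
#' soft-Dice optimization with Adam, per-epoch validation loss without
#' augmentation, plateau LR reduction and two-stage early stopping.
#' Normalization statistics (mean/sd of scaled intensities) are computed
#' from the training tiles only and stored in the model. Weights from the
#' epoch with the best validation loss are restored at the end.
#'
#' @param model A `tile_unet` from [build_model()].
#' @param train_tiles,val_tiles Non-empty lists of `list(image, mask)`
#'   tiles (image: 2-D 0..255 matrix; mask: `(h, w, 4)` binary array).
#' @param config A [train_config()].
#' @param aug An [aug_config()]; set `p_flip = 0, max_rotate = 0,
#'   p_photometric = 0` to disable augmentation.
#' @param verbose Print one `epoch=<i> train_loss=<x> val_loss=<y> lr=<z>`
#'   line per epoch.
#' @return List with the trained `model` and `history` (a
#'   `training_history`: per-epoch data frame plus `stop_epoch`,
#'   `lr_reduction_epoch`, `best_epoch`).
#' @export
fit <- function(model, train_tiles, val_tiles, config = train_config(),
                aug = aug_config(), verbose = FALSE) {
  stopifnot(inherits(model, "tile_unet"), inherits(config, "train_config"))
  if (length(train_tiles) == 0 || length(val_tiles) == 0)
    stop("empty training or validation split")
  s <- model$config$input_size

  # normalization from the training split only
  tr_mean <- mean(vapply(train_tiles, function(t) mean(t$image / 255),
                         numeric(1)))
  tr_sd <- sqrt(mean(vapply(train_tiles,
                            function(t) mean((t$image / 255 - tr_mean)^2),
                            numeric(1))))
  model$norm <- c(mean = tr_mean, sd = max(tr_sd, 1e-6))

  train_prep <- lapply(train_tiles, prep_tile, s = s)
  val_prep <- lapply(val_tiles, prep_tile, s = s)

  # pre-assemble the validation batch tensors once
  val_batches <- make_batches(length(val_prep), config$batch_size)
  val_x <- lapply(val_batches, function(ix) {
    arr <- array(0, c(s, s, 1, length(ix)))
    for (j in seq_along(ix)) arr[, , 1, j] <-
        normalize_input(model, val_prep[[ix[j]]]$image)
    arr
  })
  val_t <- lapply(val_batches, function(ix) {
    arr <- array(0, c(s, s, 4, length(ix)))
    for (j in seq_along(ix)) arr[, , , j] <- val_prep[[ix[j]]]$mask
    arr
  })

  opt <- adam_init(model$params)
  sched <- schedule_init(config$patience, config$min_delta)
  lr <- config$initial_lr
  best_params <- model$params
  history <- list()
  t_adam <- 0

  for (epoch in seq_len(config$max_epochs)) {
    set.seed(mix_seed(config$seed, epoch))
    ord <- sample(length(train_prep))
    batches <- make_batches(length(ord), config$batch_size)
    train_losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      ix <- ord[batches[[bi]]]
      x <- array(0, c(s, s, 1, length(ix)))
      tt <- array(0, c(s, s, 4, length(ix)))
      for (j in seq_along(ix)) {
        a <- augment(train_prep[[ix[j]]]$image, train_prep[[ix[j]]]$mask,
                     aug)
        x[, , 1, j] <- normalize_input(model, a$image)
        tt[, , , j] <- a$mask
      }
      fw <- model_forward(model, x, training = TRUE)
      loss <- dice_loss(fw$out, tt, config$dice_eps)
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", epoch, ", batch ", bi)
      train_losses[bi] <- loss
      dout <- dice_loss_grad(fw$out, tt, config$dice_eps)
      grads <- model_backward(model, fw$cache, dout)
      t_adam <- t_adam + 1
      upd <- adam_step(model$params, grads, opt, lr, config$beta1,
                       config$beta2, t_adam)
      model$params <- upd$params
      opt <- upd$state
    }
    # validation loss (no augmentation): dice pooled per channel over
    # the whole validation set, matching the training objective
    vi <- vp <- vt <- rep(0, 4)
    for (bi in seq_along(val_x)) {
      out <- model_forward(model, val_x[[bi]], training = FALSE)$out
      d <- dim(out)
      pm <- matrix(out, d[1] * d[2]); tm <- matrix(val_t[[bi]], d[1] * d[2])
      ch <- rep(seq_len(4), times = d[4])
      vi <- vi + tapply(colSums(pm * tm), ch, sum)
      vp <- vp + tapply(colSums(pm), ch, sum)
      vt <- vt + tapply(colSums(tm), ch, sum)
    }
    val_loss <- 1 - mean((2 * vi + config$dice_eps) /
                           (vp + vt + config$dice_eps))
    if (!is.finite(val_loss))
      stop("non-finite validation loss at epoch ", epoch)

    sched <- schedule_update(sched, val_loss)
    if (sched$best_epoch == sched$epoch) best_params <- model$params
    history[[epoch]] <- data.frame(epoch = epoch,
                                   train_loss = mean(train_losses),
                                   val_loss = val_loss, lr = lr)
    if (verbose)
      cat(sprintf("epoch=%d train_loss=%.5f val_loss=%.5f lr=%g\n",
                  epoch, mean(train_losses), val_loss, lr))
    if (sched$action == "reduce") lr <- config$reduced_lr
    if (sched$action == "stop") break
  }

  model$params <- best_params
  hist_df <- do.call(rbind, history)
  history <- structure(
    list(epochs = hist_df,
         stop_epoch = if (is.na(sched$stop_epoch)) nrow(hist_df)
                      else sched$stop_epoch,
         lr_reduction_epoch = sched$reduce_epoch,
         best_epoch = sched$best_epoch),
    class = "training_history")
  list(model = model, history = history)
}

make_batches <- function(n, batch_size) {
  split(seq_len(n), ceiling(seq_len(n) / batch_size))
}

#' @export
print.training_history <- function(x, ...) {
  cat(sprintf("training_history: %d epochs, stop=%d, lr reduction=%s, best=%d\n",
              nrow(x$epochs), x$stop_epoch,
              ifelse(is.na(x$lr_reduction_epoch), "none",
                     x$lr_reduction_epoch), x$best_epoch))
  invisible(x)
}

#' Write a training history as CSV
#'
#' @param history A `training_history`.
#' @param path Output CSV path.
#' @export
write_history_csv <- function(history, path) {
  write.csv(history$epochs, path, row.names = FALSE)
  invisible(path)
}
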