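# Compact U-Net-style encoder-decoder.
#
# Encoder level l (l = 1..depth): 3x3 conv (+ReLU) at width
# base_width * 2^(l-1), then 2x2 max pooling. Bottleneck: one 3x3 conv at
# the deepest encoder width. Decoder level l: nearest 2x upsampling,
# concatenation with the level-l skip, a 1x1 channel-reduction conv
# (+ReLU) back to the level width, then a 3x3 conv (+ReLU). Head: 1x1
# conv to 4 channels + per-channel logistic (sigmoid) -- channels are
# independent probabilities because masks are multi-label, never softmax.
#
# The bottleneck width is kept equal to the deepest encoder width (not
# doubled) and each block holds a single 3x3 conv; both choices bound CPU
# cost at desk scale and are documented in the methods vignette.

#' Model configuration
#'
#' @param input_size Square input resolution fed to the network; must be
#'   divisible by `2^depth`. Default 224 mirrors common pretrained
#'   pipelines; desk-scale experiments use 64.
#' @param depth Number of encoder levels (poolings).
#' @param base_width Channels at the first encoder level; width doubles
#'   per level.
#' @param n_classes Fixed at 4 (the restoration channels).
#' @return A `model_config` object.
#' @export
model_config <- function(input_size = 224, depth = 4, base_width = 16,
                         n_classes = 4) {
  if (n_classes != 4) stop("n_classes is fixed at 4")
  if (input_size %% (2^depth) != 0)
    stop("input_size must be divisible by 2^depth")
  structure(list(input_size = as.integer(input_size),
                 depth = as.integer(depth),
                 base_width = as.integer(base_width),
                 n_classes = 4L),
            class = "model_config")
}

# layer parameter shapes implied by a config; a pure function of config
layer_shapes <- function(config) {
  d <- config$depth; w <- config$base_width
  enc_w <- w * 2^(seq_len(d) - 1)
  shapes <- list()
  cin <- 1
  for (l in seq_len(d)) {
    shapes[[paste0("enc", l)]] <- c(3, 3, cin, enc_w[l])
    cin <- enc_w[l]
  }
  shapes$bottleneck <- c(3, 3, enc_w[d], enc_w[d])
  up_ch <- enc_w[d]
  for (l in rev(seq_len(d))) {
    cat_ch <- up_ch + enc_w[l]
    shapes[[paste0("dec", l, "_reduce")]] <- c(1, 1, cat_ch, enc_w[l])
    shapes[[paste0("dec", l, "_conv")]] <- c(3, 3, enc_w[l], enc_w[l])
    up_ch <- enc_w[l]
  }
  shapes$head <- c(1, 1, enc_w[1], 4)
  shapes
}

init_layer <- function(shape, normed = TRUE) {
  fan_in <- shape[1] * shape[2] * shape[3]
  out <- list(w = array(rnorm(prod(shape), 0, sqrt(2 / fan_in)), shape),
              b = rep(0, shape[4]))
  if (normed) {
    out$g <- rep(1, shape[4])     # instance-norm scale
    out$nb <- rep(0, shape[4])    # instance-norm shift
  }
  out
}

# the head starts biased toward background (sigmoid(-2) ~ 0.12), the
# usual initialization for heavily imbalanced dense prediction
HEAD_BIAS_INIT <- -2

#' Build a U-Net model
#'
#' Weight initialization (He-normal) is seed-deterministic: the same
#' `(config, seed)` always produce identical weights.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `tile_unet` model object.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  shapes <- layer_shapes(config)
  params <- with_seed(seed, lapply(names(shapes), function(nm)
    init_layer(shapes[[nm]], normed = nm != "head")))
  names(params) <- names(shapes)
  params$head$b <- rep(HEAD_BIAS_INIT, 4)
  structure(list(config = config, params = params,
                 norm = c(mean = 0.5, sd = 0.5), seed = as.integer(seed)),
            class = "tile_unet")
}

#' Number of trainable parameters
#'
#' A pure function of the model configuration.
#'
#' @param model A `tile_unet` or a `model_config`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  shapes <- if (inherits(model, "model_config")) layer_shapes(model)
            else layer_shapes(model$config)
  nm <- names(shapes)
  sum(vapply(seq_along(shapes), function(i) {
    s <- shapes[[i]]
    prod(s) + s[4] + if (nm[i] == "head") 0 else 2 * s[4]
  }, numeric(1)))
}

#' @export
print.tile_unet <- function(x, ...) {
  cat(sprintf("tile_unet: input %dx%d, depth %d, base width %d, %d params\n",
              x$config$input_size, x$config$input_size, x$config$depth,
              x$config$base_width, n_params(x)))
  invisible(x)
}

# leaky ReLU (slope 0.1): with no normalization layers and a sparse
# foreground, plain ReLU nets collapse into the all-background attractor
# of the Dice loss (dead units, saturated sigmoid); the leak keeps
# gradients alive.
LEAKY_SLOPE <- 0.1

relu_fwd <- function(x) cpp_lrelu_fwd(x, LEAKY_SLOPE)

# Instance normalization (fused in C++ with the leaky ReLU): each
# (channel, sample) plane is standardized over its pixels, then scaled
# and shifted by learned per-channel affine parameters, then activated.
# Identical at train and test time (no running statistics). Without it,
# Dice-trained sigmoid heads saturate: a constant flooded (or empty)
# sparse channel is a local optimum with zero gradient.
instnorm_fwd <- function(z, g, nb, eps = 1e-5, slope = 1) {
  out <- cpp_innact_fwd(z, dim(z), g, nb, eps, slope)
  out$d <- dim(z)
  out
}

instnorm_bwd <- function(cache, dy, g, nb, slope = 1) {
  out <- cpp_innact_bwd(cache$xhat, cache$d, cache$istd, g, nb, slope, dy)
  names(out) <- c("dx", "dg", "dnb")
  out
}

sigmoid <- function(x) {
  if (is.null(dim(x))) 1 / (1 + exp(-x)) else cpp_sigmoid(x)
}

as4d <- function(x) {
  d <- dim(x)
  if (length(d) == 2) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3) dim(x) <- c(d, 1L)
  x
}

# Forward pass. x: (S, S, 1, N) normalized input batch.
# Returns list(out = (S,S,4,N) probabilities, cache) -- cache retained
# only when training = TRUE.
#
# Each non-head convolution is followed by instance norm and leaky ReLU.

block_fwd <- function(params, x, kind, x2 = NULL) {
  z <- switch(kind,
    "3x3" = cpp_conv3x3_fwd(x, dim(x), params$w, params$b),
    "1x1" = cpp_conv1x1_fwd(x, dim(x), matrix(params$w, dim(params$w)[3]),
                            params$b),
    "pair" = cpp_conv1x1_pair_fwd(x, dim(x), x2, dim(x2),
                                  matrix(params$w, dim(params$w)[3]),
                                  params$b))
  nrm <- cpp_innact_fwd(z, dim(z), params$g, params$nb, 1e-5, LEAKY_SLOPE)
  list(a = nrm$y, x = x, x2 = x2, xhat = nrm$xhat, istd = nrm$istd,
       zd = dim(z), kind = kind)
}

block_bwd <- function(params, cache, da, need_dx = TRUE) {
  nb <- cpp_innact_bwd(cache$xhat, cache$zd, cache$istd, params$g,
                       params$nb, LEAKY_SLOPE, da)
  dz <- nb$dx
  if (cache$kind == "3x3") {
    g <- cpp_conv3x3_bwd(cache$x, dim(cache$x), params$w, dz, need_dx)
    return(list(grad = list(w = g$dw, b = g$db, g = nb$dg, nb = nb$dnb),
                dx = if (need_dx) g$dx else NULL))
  }
  if (cache$kind == "1x1") {
    g <- cpp_conv1x1_bwd(cache$x, dim(cache$x),
                         matrix(params$w, dim(params$w)[3]), dz)
    return(list(grad = list(w = array(g$dw, dim(params$w)), b = g$db,
                            g = nb$dg, nb = nb$dnb),
                dx = g$dx))
  }
  g <- cpp_conv1x1_pair_bwd(cache$x, dim(cache$x), cache$x2, dim(cache$x2),
                            matrix(params$w, dim(params$w)[3]), dz)
  list(grad = list(w = array(g$dw, dim(params$w)), b = g$db,
                   g = nb$dg, nb = nb$dnb),
       dxa = g$dxa, dxb = g$dxb)
}

model_forward <- function(model, x, training = FALSE) {
  p <- model$params
  d <- model$config$depth
  cache <- list()
  skips <- list()
  cur <- x
  for (l in seq_len(d)) {
    nm <- paste0("enc", l)
    blk <- block_fwd(p[[nm]], cur, "3x3")
    if (training) cache[[nm]] <- blk
    skips[[l]] <- blk$a
    pool <- cpp_maxpool2_fwd(blk$a, dim(blk$a))
    if (training) cache[[paste0(nm, "_which")]] <- pool$which
    cur <- pool$y
  }
  blk <- block_fwd(p$bottleneck, cur, "3x3")
  if (training) cache$bottleneck <- blk
  cur <- blk$a
  for (l in rev(seq_len(d))) {
    up <- cpp_upsample2_fwd(cur, dim(cur))
    rn <- paste0("dec", l, "_reduce"); cn <- paste0("dec", l, "_conv")
    b1 <- block_fwd(p[[rn]], up, "pair", x2 = skips[[l]])
    b2 <- block_fwd(p[[cn]], b1$a, "3x3")
    if (training) {
      cache[[rn]] <- b1
      cache[[cn]] <- b2
    }
    cur <- b2$a
  }
  logits <- cpp_conv1x1_fwd(cur, dim(cur),
                            matrix(p$head$w, dim(p$head$w)[3]), p$head$b)
  out <- sigmoid(logits)
  if (training) { cache$head_in <- cur; cache$out <- out }
  list(out = out, cache = cache)
}

# Backward pass: dout is dL/d(probabilities). Returns gradients with the
# same structure as model$params.
model_backward <- function(model, cache, dout) {
  p <- model$params
  d <- model$config$depth
  grads <- list()
  # through the sigmoid
  dz <- dout * cache$out * (1 - cache$out)
  g <- cpp_conv1x1_bwd(cache$head_in, dim(cache$head_in),
                       matrix(p$head$w, dim(p$head$w)[3]), dz)
  grads$head <- list(w = array(g$dw, dim(p$head$w)), b = g$db)
  dcur <- g$dx
  dskips <- vector("list", d)
  for (l in seq_len(d)) {
    rn <- paste0("dec", l, "_reduce"); cn <- paste0("dec", l, "_conv")
    b2 <- block_bwd(p[[cn]], cache[[cn]], dcur)
    grads[[cn]] <- b2$grad
    b1 <- block_bwd(p[[rn]], cache[[rn]], b2$dx)
    grads[[rn]] <- b1$grad
    dskips[[l]] <- b1$dxb
    dcur <- cpp_upsample2_bwd(b1$dxa, dim(b1$dxa))
  }
  bb <- block_bwd(p$bottleneck, cache$bottleneck, dcur)
  grads$bottleneck <- bb$grad
  dcur <- bb$dx
  for (l in rev(seq_len(d))) {
    nm <- paste0("enc", l)
    which <- cache[[paste0(nm, "_which")]]
    dpool <- cpp_maxpool2_bwd(which, dim(which), dcur)
    da <- dpool + dskips[[l]]
    be <- block_bwd(p[[nm]], cache[[nm]], da, need_dx = l > 1)
    grads[[nm]] <- be$grad
    if (l > 1) dcur <- be$dx
  }
  grads[names(model$params)]
}

# normalize raw 0..255 intensities using the model's stored statistics
normalize_input <- function(model, img) {
  x <- img / 255
  (x - model$norm[["mean"]]) / model$norm[["sd"]]
}

#' Predict probability maps for a list of tiles
#'
#' Each tile is intensity-normalized (scaled to `[0, 1]`, then
#' standardized by the statistics stored in the model at fit time),
#' resized to the model input size (bilinear), run through the network,
#' and its 4-channel probability map is resized back to the tile's native
#' size (bilinear). Output order matches input order.
#'
#' @param model A `tile_unet` (or `oracle_model`).
#' @param tiles Non-empty list of 2-D intensity matrices (0..255).
#' @param ... Passed to methods; `batch_size` controls forward-pass
#'   batching for `tile_unet`.
#' @return List of (h, w, 4) probability arrays at native tile sizes.
#' @export
predict_tiles <- function(model, tiles, ...) UseMethod("predict_tiles")

#' @rdname predict_tiles
#' @param batch_size Tiles per forward pass.
#' @export
predict_tiles.tile_unet <- function(model, tiles, batch_size = 16, ...) {
  if (length(tiles) == 0) stop("empty tile list")
  s <- model$config$input_size
  n <- length(tiles)
  probs <- vector("list", n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    x <- array(0, c(s, s, 1, length(idx)))
    for (j in seq_along(idx)) {
      t_in <- normalize_input(model, tiles[[idx[j]]])
      x[, , 1, j] <- resize_bilinear(t_in, s, s)
    }
    out <- model_forward(model, x, training = FALSE)$out
    for (j in seq_along(idx)) {
      tile <- tiles[[idx[j]]]
      probs[[idx[j]]] <-
        resize_bilinear(out[, , , j, drop = FALSE][, , , 1], dim(tile)[1],
                        dim(tile)[2])
    }
  }
  probs
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the `model_config`, weights, normalization
#' statistics and seed, using R's native serialization.
#'
#' @param model A `tile_unet`.
#' @param path Checkpoint file path (`.rds`).
#' @return `path` (save) or the restored model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "tile_unet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "tile_unet")) stop("not a tile_unet checkpoint")
  model
}
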