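# Shared fixtures, built in code at test time.

# small fast generator config for tests
tiny_gen_config <- function(...) {
  gen_config(height = 64, width = 128, n_teeth = 10, ...)
}

# desk-scale experiment config (also used by the acceptance suite)
desk_gen_config <- function(...) gen_config(height = 128, width = 256, ...)

tiny_model <- function(input_size = 32, depth = 2, base_width = 4, seed = 1) {
  build_model(model_config(input_size = input_size, depth = depth,
                           base_width = base_width), seed = seed)
}

# tiles from a handful of generated images
make_tiles <- function(n_images = 2, n_tiles = 4, cfg = tiny_gen_config(),
                       seed = 1) {
  lis <- lapply(seq_len(n_images),
                function(i) generate_image(cfg, seed = seed + i))
  unlist(lapply(lis, tileseg:::tile_labeled_image, n_tiles = n_tiles),
         recursive = FALSE)
}

# brute-force per-pixel confusion counting (independent oracle)
brute_confusion <- function(pred, target) {
  d <- dim(pred)
  nc <- if (length(d) == 3) d[3] else 1
  out <- data.frame(tp = numeric(nc), fp = numeric(nc), fn = numeric(nc))
  for (ch in seq_len(nc)) {
    p <- if (length(d) == 3) pred[, , ch] else pred
    t <- if (length(d) == 3) target[, , ch] else target
    tp <- fp <- fn <- 0
    for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
      if (p[i, j] == 1 && t[i, j] == 1) tp <- tp + 1
      else if (p[i, j] == 1) fp <- fp + 1
      else if (t[i, j] == 1) fn <- fn + 1
    }
    out$tp[ch] <- tp; out$fp[ch] <- fp; out$fn[ch] <- fn
  }
  out
}

# brute-force reference of the plateau schedule rules
brute_schedule <- function(val_losses, patience = 5, min_delta = 1e-4) {
  best <- Inf; since <- 0; reduced <- FALSE
  reduce_epoch <- NA_integer_; stop_epoch <- NA_integer_
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best - min_delta) {
      best <- val_losses[e]; since <- 0
    } else {
      since <- since + 1
      if (since >= patience) {
        if (!reduced) {
          reduced <- TRUE; reduce_epoch <- e; since <- 0
        } else {
          stop_epoch <- e
          break
        }
      }
    }
  }
  list(lr_reduction_epoch = reduce_epoch, stop_epoch = stop_epoch)
}
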