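# Pixelwise multi-label evaluation: tile -> predict -> stitch on held-out
# full images, then F1 / sensitivity / IoU from pooled confusion counts.
#
# Aggregation is micro: pixel counts are pooled across images (and, for
# the "overall" row, across the four channels) before the metric is
# computed. The degenerate 0/0 case (no positives predicted or present)
# is scored 1.0 -- perfect agreement on an empty class. Specificity is
# deliberately not reported: in semantic segmentation the negative class
# is the background.

#' Threshold probability maps to binary masks
#'
#' A pixel is set iff its probability is `>= threshold` (boundary
#' convention: exactly 0.5 is set), per channel independently.
#'
#' @param prob_map Numeric array of probabilities in `[0, 1]`.
#' @param threshold Scalar in `[0, 1]`.
#' @return Integer array of 0/1 with the same shape.
#' @export
binarize <- function(prob_map, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  out <- (prob_map >= threshold) * 1L
  dim(out) <- dim(prob_map)
  out
}

#' Pixelwise confusion counts per channel
#'
#' @param pred,target Binary arrays of identical shape: matrices or
#'   `(H, W, C)` channel stacks.
#' @return Data frame with one row per channel: `tp`, `fp`, `fn`.
#' @export
confusion_counts <- function(pred, target) {
  if (!identical(dim(pred), dim(target)))
    stop("pred and target must have the same shape")
  p <- as4d(pred); t <- as4d(target)
  d <- dim(p)
  nc <- d[3]
  tp <- fp <- fn <- numeric(nc)
  for (ch in seq_len(nc)) {
    pc <- p[, , ch, , drop = FALSE] != 0
    tc <- t[, , ch, , drop = FALSE] != 0
    tp[ch] <- sum(pc & tc)
    fp[ch] <- sum(pc & !tc)
    fn[ch] <- sum(!pc & tc)
  }
  data.frame(channel = if (nc == 4) CLASS_CHANNELS else paste0("ch", seq_len(nc)),
             tp = tp, fp = fp, fn = fn)
}

metric_or_perfect <- function(num, den) ifelse(den == 0, 1, num / den)

#' Metrics from confusion counts
#'
#' `f1 = 2tp / (2tp + fp + fn)`, `sensitivity = tp / (tp + fn)`,
#' `iou = tp / (tp + fp + fn)`. A degenerate 0/0 scores 1.0 (perfect
#' agreement on an empty class); the identity `f1 = 2 iou / (1 + iou)`
#' holds whenever counts are non-degenerate.
#'
#' @param counts Data frame or list with `tp`, `fp`, `fn` (vectorized).
#' @return Numeric vector of the metric.
#' @export
f1_from_counts <- function(counts) {
  metric_or_perfect(2 * counts$tp, 2 * counts$tp + counts$fp + counts$fn)
}

#' @rdname f1_from_counts
#' @export
sensitivity_from_counts <- function(counts) {
  metric_or_perfect(counts$tp, counts$tp + counts$fn)
}

#' @rdname f1_from_counts
#' @export
iou_from_counts <- function(counts) {
  metric_or_perfect(counts$tp, counts$tp + counts$fp + counts$fn)
}

#' Evaluate a model on held-out full images
#'
#' For each image: choose the grid for `n_tiles`, extract image tiles,
#' predict per-tile probability maps, stitch them back to a full-image
#' 4-channel map, binarize, and accumulate per-channel confusion counts
#' pooled (micro) across all test images. The "overall" row pools counts
#' over the four channels.
#'
#' @param model A `tile_unet` or [oracle_model()].
#' @param test_images Non-empty list of `labeled_image` objects.
#' @param n_tiles Tile count used for prediction (should match training).
#' @param threshold Binarization threshold.
#' @param macro If `TRUE`, additionally report per-image macro-averaged
#'   metrics (mean of per-image metric values) as attribute `macro`.
#' @return A `metrics_report`: list with `per_channel` (data frame:
#'   channel, tp, fp, fn, f1, sensitivity, iou; last row "overall"),
#'   `n_images`, `tile_count`.
#' @export
evaluate_model <- function(model, test_images, n_tiles, threshold = 0.5,
                           macro = FALSE) {
  if (length(test_images) == 0) stop("empty test set")
  counts <- data.frame(channel = CLASS_CHANNELS, tp = 0, fp = 0, fn = 0)
  per_image <- list()
  for (li in test_images) {
    pred <- predict_image(model, li, n_tiles)
    bin <- binarize(pred, threshold)
    cc <- confusion_counts(bin, li$mask)
    counts$tp <- counts$tp + cc$tp
    counts$fp <- counts$fp + cc$fp
    counts$fn <- counts$fn + cc$fn
    if (macro) per_image[[length(per_image) + 1]] <- cc
  }
  overall <- data.frame(channel = "overall", tp = sum(counts$tp),
                        fp = sum(counts$fp), fn = sum(counts$fn))
  tab <- rbind(counts, overall)
  tab$f1 <- f1_from_counts(tab)
  tab$sensitivity <- sensitivity_from_counts(tab)
  tab$iou <- iou_from_counts(tab)
  rep <- structure(list(per_channel = tab,
                        n_images = length(test_images),
                        tile_count = as.integer(n_tiles)),
                   class = "metrics_report")
  if (macro) {
    mac <- lapply(per_image, function(cc) {
      data.frame(channel = cc$channel, f1 = f1_from_counts(cc),
                 sensitivity = sensitivity_from_counts(cc),
                 iou = iou_from_counts(cc))
    })
    mac <- do.call(rbind, mac)
    attr(rep, "macro") <- aggregate(cbind(f1, sensitivity, iou) ~ channel,
                                    mac, mean)
  }
  rep
}

# full-image 4-channel probability map via tile -> predict -> stitch
predict_image <- function(model, labeled_image, n_tiles) {
  h <- dim(labeled_image$image)[1]; w <- dim(labeled_image$image)[2]
  layout <- select_grid(n_tiles, h, w)
  regions <- tile_bounds(layout, h, w)
  tiles <- extract_tiles(labeled_image$image, regions)
  probs <- predict_tiles(model, tiles, image = labeled_image,
                         regions = regions)
  stitch_tiles(probs, regions, h, w)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report: %d images, %d tiles\n", x$n_images,
              x$tile_count))
  print(x$per_channel, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' @param report A `metrics_report`.
#' @param path Optional path; if `NULL` the JSON string is returned.
#' @export
metrics_to_json <- function(report, path = NULL) {
  obj <- list(n_images = report$n_images, tile_count = report$tile_count,
              per_channel = report$per_channel)
  if (is.null(path)) return(jsonlite::toJSON(obj, dataframe = "rows",
                                             auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Ground-truth oracle predictor
#'
#' A stand-in "model" whose predictions are the true masks of the images
#' it is asked about (optionally corrupted by a deterministic
#' full-image-coordinate pattern). It bypasses the network and the
#' resize path, so its stitched full-image prediction is exactly
#' independent of the tile count -- which makes it the reference for
#' checking that tiling bookkeeping does not corrupt evaluation.
#'
#' @param corrupt_period If > 0, predictions are flipped on a fixed
#'   checkerboard-like pattern (`(row + col) %% period == 0` in
#'   full-image coordinates), giving imperfect but tiling-invariant
#'   predictions.
#' @return An `oracle_model`.
#' @export
oracle_model <- function(corrupt_period = 0) {
  structure(list(corrupt_period = corrupt_period), class = "oracle_model")
}

#' @rdname predict_tiles
#' @param image The `labeled_image` the tiles came from (supplied by
#'   [evaluate_model()]).
#' @param regions Tile regions matching `tiles`.
#' @export
predict_tiles.oracle_model <- function(model, tiles, image = NULL,
                                       regions = NULL, ...) {
  if (length(tiles) == 0) stop("empty tile list")
  if (is.null(image) || is.null(regions))
    stop("oracle_model needs image and regions context")
  mask_tiles <- extract_tiles(image$mask, regions)
  lapply(seq_along(mask_tiles), function(k) {
    m <- mask_tiles[[k]] * 1.0
    if (model$corrupt_period > 0) {
      r <- regions[[k]]
      rows <- (r$row_start + 1):r$row_end
      cols <- (r$col_start + 1):r$col_end
      pat <- outer(rows - 1, cols - 1, "+") %% model$corrupt_period == 0
      for (ch in seq_len(dim(m)[3]))
        m[, , ch][pat] <- 1 - m[, , ch][pat]
    }
    m
  })
}
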