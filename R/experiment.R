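# Repeated k-fold cross-validation over a tile-count sweep.
#
# The reference protocol is five-times-repeated three-fold CV: the ids
# are shuffled once (seeded) and cut into 5 contiguous hold-out test
# groups of ~20%; within each repetition the remaining ids are cut into
# 3 folds, fold f serving as validation and the other two as training.
# That yields 15 (repetition, fold) model entries, whose test scores feed
# the mean +/- 95% Student-t confidence intervals.

#' Build a repeated k-fold cross-validation plan
#'
#' @param image_ids Character or integer vector of ids (>= 15 for the
#'   default plan so every split is non-empty).
#' @param seed Shuffle seed; the plan is deterministic given
#'   `(image_ids, seed)`.
#' @param repetitions Number of hold-out repetitions actually run
#'   (default 5).
#' @param folds Train/validation splits per repetition (default 3).
#' @param groups Number of hold-out test groups the ids are partitioned
#'   into (default 5, i.e. 20% test). A reduced plan keeps `groups = 5`
#'   but runs fewer repetitions.
#' @return A `cv_plan`: list with `entries` (list of
#'   `list(repetition, fold, test_ids, train_ids, val_ids)`), `seed`,
#'   `repetitions`, `folds`.
#' @export
make_cv_plan <- function(image_ids, seed = 1L, repetitions = 5, folds = 3,
                         groups = 5) {
  n <- length(image_ids)
  if (repetitions > groups) stop("repetitions cannot exceed groups")
  if (n < groups * folds)
    stop("need at least ", groups * folds, " ids")
  if (anyDuplicated(image_ids)) stop("image ids must be unique")
  shuffled <- with_seed(seed, image_ids[sample(n)])
  # first (n mod k) groups get the extra element
  group_of <- function(n, k) rep(seq_len(k), times =
    (n %/% k) + (seq_len(k) <= n %% k))
  test_group <- group_of(n, groups)
  entries <- list()
  for (r in seq_len(repetitions)) {
    test_ids <- shuffled[test_group == r]
    rest <- shuffled[test_group != r]
    fold_group <- group_of(length(rest), folds)
    for (f in seq_len(folds)) {
      entries[[length(entries) + 1]] <- list(
        repetition = r, fold = f,
        test_ids = test_ids,
        val_ids = rest[fold_group == f],
        train_ids = rest[fold_group != f])
    }
  }
  structure(list(entries = entries, seed = as.integer(seed),
                 repetitions = as.integer(repetitions),
                 folds = as.integer(folds), groups = as.integer(groups)),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  e1 <- x$entries[[1]]
  cat(sprintf("cv_plan: %d repetitions x %d folds = %d entries (|test|=%d, |val|=%d, |train|=%d)\n",
              x$repetitions, x$folds, length(x$entries),
              length(e1$test_ids), length(e1$val_ids),
              length(e1$train_ids)))
  invisible(x)
}

#' Mean and 95% confidence interval of model scores
#'
#' Two-sided Student-t interval: `mean +/- t(0.975, n-1) * sd / sqrt(n)`
#' with the sample standard deviation.
#'
#' @param scores Numeric vector, `n >= 2`.
#' @return A `summary_stat`: list with `mean`, `ci_low`, `ci_high`, `n`.
#' @export
aggregate_ci <- function(scores) {
  n <- length(scores)
  if (n < 2) stop("need at least 2 scores for a confidence interval")
  m <- mean(scores)
  half <- qt(0.975, n - 1) * sd(scores) / sqrt(n)
  structure(list(mean = m, ci_low = m - half, ci_high = m + half, n = n),
            class = "summary_stat")
}

# cut a labeled image into (image, mask) tile pairs for a tile count
tile_labeled_image <- function(li, n_tiles) {
  h <- dim(li$image)[1]; w <- dim(li$image)[2]
  regions <- tile_bounds(select_grid(n_tiles, h, w), h, w)
  imgs <- extract_tiles(li$image, regions)
  msks <- extract_tiles(li$mask, regions)
  lapply(seq_along(regions), function(k)
    list(image = imgs[[k]], mask = msks[[k]]))
}

#' Run the tile-count sweep experiment
#'
#' For each tile count and each cross-validation entry: tile the training
#' and validation images, train a model ([fit()]), evaluate it on the
#' entry's held-out test images with stitched full-image prediction
#' ([evaluate_model()]), and collect per-channel metrics plus the stop
#' epoch. Results are aggregated per (tile_count, channel, metric) with
#' [aggregate_ci()].
#'
#' Per-entry training seeds are derived deterministically from `seed`,
#' the tile count and the entry index, so runs are bit-reproducible.
#'
#' @param dataset A `tileseg_dataset` (images must carry masks).
#' @param tile_counts Non-empty vector of tile counts to sweep.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param seed Master seed for the CV plan and per-entry training.
#' @param repetitions,folds,groups CV plan shape (reference protocol:
#'   5 repetitions x 3 folds over 5 hold-out groups); see
#'   [make_cv_plan()].
#' @param aug An [aug_config()].
#' @param oracle Optional [oracle_model()]; if given, training is skipped
#'   and the oracle is evaluated instead (plumbing checks).
#' @param out_dir Optional directory for `results.csv` (per-entry rows),
#'   `summary.csv` (aggregated) and `convergence.csv`.
#' @param verbose Print progress lines.
#' @return An `experiment_result`: list with `results` (per-entry data
#'   frame: tile_count, repetition, fold, channel, f1, sensitivity, iou,
#'   tp, fp, fn, stop_epoch), `summary` (aggregated data frame:
#'   tile_count, channel, metric, mean, ci_low, ci_high, n,
#'   mean_epochs_to_stop), `convergence` (tile_count, repetition, fold,
#'   stop_epoch) and `plan`.
#' @export
run_experiment <- function(dataset, tile_counts, model_cfg = model_config(),
                           train_cfg = train_config(), seed = 1L,
                           repetitions = 5, folds = 3, groups = 5,
                           aug = aug_config(), oracle = NULL,
                           out_dir = NULL, verbose = FALSE) {
  images <- dataset$images
  if (length(tile_counts) == 0) stop("tile_counts must be non-empty")
  ids <- vapply(images, function(li) li$id, character(1))
  names(images) <- ids
  plan <- make_cv_plan(ids, seed = seed, repetitions = repetitions,
                       folds = folds, groups = groups)
  rows <- list()
  for (tc in tile_counts) {
    for (ei in seq_along(plan$entries)) {
      entry <- plan$entries[[ei]]
      entry_seed <- mix_seed(seed, tc * 1000 + ei)
      if (is.null(oracle)) {
        train_tiles <- unlist(lapply(images[entry$train_ids],
                                     tile_labeled_image, n_tiles = tc),
                              recursive = FALSE)
        val_tiles <- unlist(lapply(images[entry$val_ids],
                                   tile_labeled_image, n_tiles = tc),
                            recursive = FALSE)
        model <- build_model(model_cfg, seed = entry_seed)
        tcfg <- train_cfg
        tcfg$seed <- entry_seed
        fitres <- fit(model, train_tiles, val_tiles, tcfg, aug = aug)
        model <- fitres$model
        stop_epoch <- fitres$history$stop_epoch
      } else {
        model <- oracle
        stop_epoch <- 0L
      }
      rep_ <- evaluate_model(model, images[entry$test_ids], n_tiles = tc)
      tab <- rep_$per_channel
      rows[[length(rows) + 1]] <- data.frame(
        tile_count = tc, repetition = entry$repetition, fold = entry$fold,
        channel = tab$channel, f1 = tab$f1,
        sensitivity = tab$sensitivity, iou = tab$iou,
        tp = tab$tp, fp = tab$fp, fn = tab$fn,
        stop_epoch = stop_epoch)
      if (verbose)
        cat(sprintf("tiles=%d rep=%d fold=%d overall_f1=%.4f stop=%d\n",
                    tc, entry$repetition, entry$fold,
                    tab$f1[tab$channel == "overall"], stop_epoch))
    }
  }
  results <- do.call(rbind, rows)

  # aggregate: one row per (tile_count, channel, metric)
  summ <- list()
  for (tc in unique(results$tile_count)) {
    sub_tc <- results[results$tile_count == tc, ]
    mean_stop <- mean(sub_tc$stop_epoch[sub_tc$channel == "overall"])
    for (ch in unique(sub_tc$channel)) {
      sub <- sub_tc[sub_tc$channel == ch, ]
      for (metric in c("f1", "sensitivity", "iou")) {
        ci <- aggregate_ci(sub[[metric]])
        summ[[length(summ) + 1]] <- data.frame(
          tile_count = tc, channel = ch, metric = metric,
          mean = ci$mean, ci_low = ci$ci_low, ci_high = ci$ci_high,
          n = ci$n, mean_epochs_to_stop = mean_stop)
      }
    }
  }
  summary_df <- do.call(rbind, summ)
  convergence <- unique(results[results$channel == "overall",
                                c("tile_count", "repetition", "fold",
                                  "stop_epoch")])
  rownames(convergence) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(results, file.path(out_dir, "results.csv"),
              row.names = FALSE)
    write.csv(summary_df, file.path(out_dir, "summary.csv"),
              row.names = FALSE)
    write.csv(convergence, file.path(out_dir, "convergence.csv"),
              row.names = FALSE)
  }
  structure(list(results = results, summary = summary_df,
                 convergence = convergence, plan = plan),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment_result\n")
  ov <- x$summary[x$summary$channel == "overall" & x$summary$metric == "f1", ]
  print(ov[, c("tile_count", "mean", "ci_low", "ci_high",
               "mean_epochs_to_stop")], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Desk-scale default settings for the tiling experiment
#'
#' The scaled-down stand-in for the reference protocol: 90 synthetic
#' 128 x 256 images, a depth-3 U-Net with base width 8 at 64 x 64 input,
#' batch size 8, up to 25 epochs, tile counts 1 / 4 / 8.
#'
#' @return List with `gen`, `model`, `train`, `tile_counts`, `n_images`.
#' @export
desk_scale_defaults <- function() {
  list(gen = gen_config(height = 128, width = 256),
       model = model_config(input_size = 64, depth = 3, base_width = 8),
       train = train_config(batch_size = 8, max_epochs = 25),
       tile_counts = c(1, 4, 8),
       n_images = 90)
}
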