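# Synthetic panoramic-radiograph generator.
#
# The scenes are stylized, not anatomical: what matters for the tiling
# study is the *size and frequency structure* of the four restoration
# classes, not realism. Teeth are filled ellipses along two arch curves;
# fillings are compact blobs in the crown half; crowns are caps over the
# occlusal half; root-canal fillings are thin tapered cones along the
# root axis (the small, infrequent class); implants are threaded
# rectangles replacing a tooth. Restorations render bright (radiopaque)
# over darker anatomy. Masks record exact pre-noise, pre-blur geometry.

#' Synthetic scene configuration
#'
#' Defaults encode the qualitative structure of restoration classes on
#' panoramic radiographs: root-canal fillings are the smallest and among
#' the least frequent classes, implants the rarest, fillings the most
#' common. Default per-class area ranges (in pixels) are derived for the
#' default 256 x 512 canvas and scale with canvas area.
#'
#' @param height,width Canvas size in pixels; `width >= height`
#'   (panoramic aspect).
#' @param n_teeth Total teeth across the two arches.
#' @param p_filling,p_crown,p_root_canal,p_implant Independent per-tooth
#'   probabilities in `[0, 1]`.
#' @param size_ranges 4 x 2 matrix of per-class pixel-area ranges
#'   (rows in [CLASS_CHANNELS] order, columns min/max). The root-canal
#'   range must lie strictly below the crown and implant ranges.
#' @param background_noise_sd Gaussian intensity noise (0..255 scale)
#'   added to the image only, never the mask.
#' @param blur_sigma Gaussian blur in pixels applied to the image only.
#' @param seed Default base seed used by [generate_dataset()].
#' @return A `gen_config` object.
#' @export
gen_config <- function(height = 256, width = 512, n_teeth = 28,
                       p_filling = 0.45, p_crown = 0.25,
                       p_root_canal = 0.15, p_implant = 0.05,
                       size_ranges = NULL,
                       background_noise_sd = 8, blur_sigma = 1,
                       seed = 1L) {
  if (height <= 0 || width <= 0) stop("canvas dimensions must be positive")
  if (width < height) stop("panoramic aspect requires width >= height")
  p <- c(filling = p_filling, crown = p_crown,
         root_canal = p_root_canal, implant = p_implant)
  if (any(p < 0 | p > 1)) stop("class probabilities must be in [0, 1]")
  if (n_teeth < 1) stop("n_teeth must be >= 1")
  if (is.null(size_ranges)) {
    scale <- (height * width) / (256 * 512)
    size_ranges <- rbind(
      filling    = c(100, 260),
      crown      = c(300, 700),
      root_canal = c(30, 90),
      implant    = c(250, 550)) * scale
    size_ranges <- pmax(size_ranges, 3)
  }
  size_ranges <- as.matrix(size_ranges)
  rownames(size_ranges) <- CLASS_CHANNELS
  if (max(size_ranges["root_canal", ]) >= min(size_ranges["crown", ]) ||
      max(size_ranges["root_canal", ]) >= min(size_ranges["implant", ]))
    stop("root_canal size range must lie strictly below crown and implant")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_teeth = as.integer(n_teeth), p = p,
                 size_ranges = size_ranges,
                 background_noise_sd = background_noise_sd,
                 blur_sigma = blur_sigma, seed = as.integer(seed)),
            class = "gen_config")
}

#' @export
print.gen_config <- function(x, ...) {
  cat(sprintf("gen_config: %dx%d canvas, %d teeth\n", x$height, x$width,
              x$n_teeth))
  cat("  p:", paste(sprintf("%s=%.2f", names(x$p), x$p), collapse = ", "),
      "\n")
  invisible(x)
}

# indices of pixels inside an axis-aligned ellipse, clipped to canvas
ellipse_idx <- function(h, w, cy, cx, ry, rx) {
  r0 <- max(1, floor(cy - ry)); r1 <- min(h, ceiling(cy + ry))
  c0 <- max(1, floor(cx - rx)); c1 <- min(w, ceiling(cx + rx))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- r0:r1; cc <- c0:c1
  inside <- outer(((rr - cy) / ry)^2, ((cc - cx) / rx)^2, "+") <= 1
  as.vector(outer(rr, (cc - 1) * h, "+"))[as.vector(inside)]
}

# tapered cone (triangle) along the vertical axis: full width `bw` at
# row `y_base`, apex at row `y_apex`
cone_idx <- function(h, w, cx, y_base, y_apex, bw) {
  dir <- sign(y_apex - y_base)
  ys <- seq(round(y_base), round(y_apex), by = dir)
  len <- length(ys)
  idx <- vector("list", len)
  for (i in seq_len(len)) {
    hw <- (bw / 2) * (1 - (i - 1) / max(len - 1, 1))
    c0 <- max(1, round(cx - hw)); c1 <- min(w, round(cx + hw))
    y <- ys[i]
    if (y >= 1 && y <= h && c0 <= c1)
      idx[[i]] <- y + (c0:c1 - 1) * h
  }
  unlist(idx)
}

# rectangle with thread notches (implant screw)
screw_idx <- function(h, w, cx, y0, y1, width) {
  ys <- seq(round(min(y0, y1)), round(max(y0, y1)))
  idx <- vector("list", length(ys))
  for (i in seq_along(ys)) {
    hw <- width / 2 - if (i %% 4 %in% c(0, 1)) 0 else 1  # thread pattern
    c0 <- max(1, round(cx - hw)); c1 <- min(w, round(cx + hw))
    y <- ys[i]
    if (y >= 1 && y <= h && c0 <= c1)
      idx[[i]] <- y + (c0:c1 - 1) * h
  }
  unlist(idx)
}

.blur_cache <- new.env(parent = emptyenv())

gauss_blur_matrix <- function(n, sigma) {
  if (sigma <= 0) return(NULL)
  key <- paste0(n, "_", round(sigma, 3))
  hit <- .blur_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- max(1, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmin(pmax(i + seq(-r, r), 1), n)  # clamp at edges
    for (t in seq_along(j)) m[i, j[t]] <- m[i, j[t]] + k[t]
  }
  m <- m / rowSums(m)
  .blur_cache[[key]] <- m
  m
}

#' Generate one synthetic panoramic-like scene
#'
#' Renders a dental arch band of `n_teeth` tooth shapes on a dark
#' background; per tooth, each restoration class is drawn independently
#' with its configured probability. Restorations are bright (radiopaque).
#' The returned mask holds the exact rendered geometry before noise and
#' blur, so channels may overlap (e.g. a root-canal cone reaches into a
#' crown cap).
#'
#' @param config A [gen_config()].
#' @param seed Integer seed; identical `(config, seed)` give bit-identical
#'   output.
#' @return A `labeled_image`: list with `image` (integer matrix, 0..255),
#'   `mask` (H x W x 4 integer array, values 0/1, channels in
#'   [CLASS_CHANNELS] order), `metadata` (one row per rendered object:
#'   class, tooth, bounding box, pixel area) and `seed`.
#' @export
generate_image <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "gen_config"))
  with_seed(seed, {
    h <- config$height; w <- config$width
    img <- matrix(25, h, w)
    # diffuse jaw-bone band
    yy <- seq_len(h)
    band <- 35 * exp(-((yy - 0.5 * h) / (0.28 * h))^2)
    img <- img + matrix(band, h, w)
    mask <- array(0L, c(h, w, 4))
    meta <- list()

    n_up <- ceiling(config$n_teeth / 2)
    n_low <- config$n_teeth - n_up
    margin <- 0.06 * w
    tooth_len <- 0.16 * h

    draw_restoration <- function(ch, idx, tooth_i, intensity) {
      idx <- idx[idx >= 1 & idx <= h * w]
      if (length(idx) == 0) return()
      chan <- mask[, , ch]
      new_px <- sum(chan[idx] == 0L)
      chan[idx] <- 1L
      mask[, , ch] <<- chan
      img[idx] <<- pmax(img[idx], intensity)
      rows <- (idx - 1) %% h + 1
      cols <- (idx - 1) %/% h + 1
      meta[[length(meta) + 1]] <<- data.frame(
        class = CLASS_CHANNELS[ch], tooth = tooth_i,
        row_min = min(rows), row_max = max(rows),
        col_min = min(cols), col_max = max(cols),
        area = new_px)
    }

    draw_arch <- function(n_arch, upper) {
      if (n_arch == 0) return()
      slot <- (w - 2 * margin) / n_arch
      for (i in seq_len(n_arch)) {
        cx <- margin + (i - 0.5) * slot
        u <- (cx - w / 2) / (w / 2)
        # occlusal line: gentle smile curve, gap between the arches
        y_occ <- if (upper) 0.46 * h - 0.05 * h * u^2
                 else 0.54 * h + 0.05 * h * u^2
        dir <- if (upper) -1 else 1     # direction from occlusal to root
        cy <- y_occ + dir * tooth_len    # tooth centre
        ax <- 0.38 * slot
        ay <- tooth_len
        tooth <- ellipse_idx(h, w, cy, cx, ay, ax)
        img[tooth] <<- pmax(img[tooth], 115 + runif(1, -10, 10))
        tooth_i <- if (upper) i else n_up + i

        draws <- runif(4) < config$p
        areas <- config$size_ranges[, 1] +
          runif(4) * (config$size_ranges[, 2] - config$size_ranges[, 1])

        if (draws["implant"]) {
          a <- areas[4]
          iw <- max(2, sqrt(a / 2.8))
          il <- a / iw
          # the screw reaches past the tooth centre toward the occlusal
          # side (implants carry crowns), so it overlaps a crown cap
          # whenever both are drawn
          idx <- screw_idx(h, w, cx, cy - dir * 0.25 * tooth_len,
                           cy + dir * min(il, 1.9 * tooth_len), iw)
          draw_restoration(4L, idx, tooth_i, 250)
        }
        if (draws["crown"]) {
          a <- areas[2]
          rx <- ax * runif(1, 0.95, 1.15)
          ry <- 2 * a / (pi * rx)
          idx <- ellipse_idx(h, w, cy, cx, ry, rx)
          rows <- (idx - 1) %% h + 1
          occl_side <- if (upper) rows >= cy else rows <= cy
          draw_restoration(2L, idx[occl_side], tooth_i, 225)
        }
        if (draws["root_canal"] && !draws["implant"]) {
          a <- areas[3]
          bw <- runif(1, 3, 8) * sqrt((h * w) / (256 * 512))
          bw <- max(bw, 2)
          len <- max(2 * a / bw, 4)
          # base sits past the tooth centre toward the occlusal side, so
          # the cone overlaps a crown cap when both are present
          y_base <- cy - dir * 0.25 * tooth_len
          y_apex <- y_base + dir * min(len, 1.6 * tooth_len)
          idx <- cone_idx(h, w, cx, y_base, y_apex, bw)
          draw_restoration(3L, idx, tooth_i, 245)
        }
        if (draws["filling"] && !draws["implant"]) {
          a <- areas[1]
          asp <- runif(1, 0.6, 1.6)
          rx <- sqrt(a * asp / pi)
          ry <- a / (pi * rx)
          fy <- cy - dir * runif(1, 0.35, 0.65) * tooth_len
          fx <- cx + runif(1, -0.3, 0.3) * ax
          idx <- ellipse_idx(h, w, fy, fx, ry, rx)
          draw_restoration(1L, idx, tooth_i, 235)
        }
      }
    }

    draw_arch(n_up, upper = TRUE)
    draw_arch(n_low, upper = FALSE)

    if (config$blur_sigma > 0) {
      a <- gauss_blur_matrix(h, config$blur_sigma)
      b <- gauss_blur_matrix(w, config$blur_sigma)
      img <- a %*% img %*% t(b)
    }
    if (config$background_noise_sd > 0)
      img <- img + matrix(rnorm(h * w, 0, config$background_noise_sd), h, w)
    img <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), h, w)

    metadata <- if (length(meta)) do.call(rbind, meta) else
      data.frame(class = character(0), tooth = integer(0),
                 row_min = integer(0), row_max = integer(0),
                 col_min = integer(0), col_max = integer(0),
                 area = integer(0))
    structure(list(image = img, mask = mask, metadata = metadata,
                   seed = as.integer(seed)),
              class = "labeled_image")
  })
}

#' Generate a dataset of synthetic scenes
#'
#' Image `i` uses the derived seed `mix_seed(seed, i)` (a documented
#' Lehmer-style mix), so a dataset can be extended without reshuffling
#' earlier images. If `out_dir` is given, images and per-channel masks
#' are written as 8-bit PNGs plus a JSON manifest.
#'
#' @param config A [gen_config()].
#' @param n_images Number of scenes (>= 1).
#' @param seed Base seed (default: `config$seed`).
#' @param out_dir Optional output directory.
#' @return A `tileseg_dataset`: list with `images` (list of
#'   `labeled_image`, each carrying an `id`), `manifest` (data frame) and
#'   `config`.
#' @export
generate_dataset <- function(config, n_images, seed = config$seed,
                             out_dir = NULL) {
  stopifnot(inherits(config, "gen_config"))
  if (n_images < 1) stop("n_images must be >= 1")
  images <- vector("list", n_images)
  manifest <- vector("list", n_images)
  mask_suffix <- c("_filling", "_crown", "_rootcanal", "_implant")
  if (!is.null(out_dir)) {
    ok <- dir.create(file.path(out_dir, "images"), recursive = TRUE,
                     showWarnings = FALSE)
    dir.create(file.path(out_dir, "masks"), recursive = TRUE,
               showWarnings = FALSE)
    if (!dir.exists(file.path(out_dir, "images")))
      stop("cannot create output directory: ", out_dir)
  }
  for (i in seq_len(n_images)) {
    si <- mix_seed(seed, i)
    li <- generate_image(config, seed = si)
    li$id <- sprintf("img_%04d", i)
    images[[i]] <- li
    image_path <- file.path("images", paste0(li$id, ".png"))
    mask_paths <- file.path("masks", paste0(li$id, mask_suffix, ".png"))
    manifest[[i]] <- data.frame(
      id = li$id, image_path = image_path,
      mask_paths = I(list(mask_paths)),
      height = config$height, width = config$width, seed = si)
    if (!is.null(out_dir)) {
      write_png_gray(li$image, file.path(out_dir, image_path))
      for (ch in 1:4)
        write_png_gray(li$mask[, , ch] * 255L,
                       file.path(out_dir, mask_paths[ch]))
    }
  }
  manifest <- do.call(rbind, manifest)
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      lapply(seq_len(n_images), function(i) list(
        id = manifest$id[i], image_path = manifest$image_path[i],
        mask_paths = manifest$mask_paths[[i]],
        height = config$height, width = config$width,
        seed = manifest$seed[i])),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  }
  structure(list(images = images, manifest = manifest, config = config),
            class = "tileseg_dataset")
}

#' Load a dataset written by [generate_dataset()]
#'
#' @param dir Directory containing `manifest.json`.
#' @return A `tileseg_dataset` (without the generating config).
#' @export
load_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  images <- lapply(man, function(rec) {
    img <- read_png_gray(file.path(dir, rec$image_path))
    mask <- array(0L, c(rec$height, rec$width, 4))
    for (ch in 1:4) {
      m <- read_png_gray(file.path(dir, rec$mask_paths[[ch]]))
      mask[, , ch] <- as.integer(m >= 128)
    }
    structure(list(id = rec$id, image = img, mask = mask,
                   metadata = NULL, seed = rec$seed),
              class = "labeled_image")
  })
  manifest <- do.call(rbind, lapply(man, function(rec) data.frame(
    id = rec$id, image_path = rec$image_path,
    mask_paths = I(list(unlist(rec$mask_paths))),
    height = rec$height, width = rec$width, seed = rec$seed)))
  structure(list(images = images, manifest = manifest, config = NULL),
            class = "tileseg_dataset")
}

#' Per-class object and prevalence statistics of a dataset
#'
#' Verifies the size/frequency structure the generator is meant to
#' produce: root-canal fillings should have the smallest mean object area
#' and low per-image frequency.
#'
#' @param dataset A `tileseg_dataset` or list of `labeled_image`.
#' @return Data frame with one row per channel: `channel`,
#'   `object_count`, `mean_object_area`, `pixel_prevalence` (set pixels /
#'   total pixels over all images).
#' @export
class_frequency_report <- function(dataset) {
  images <- if (inherits(dataset, "tileseg_dataset")) dataset$images
            else dataset
  if (length(images) == 0) stop("dataset is empty")
  total_px <- sum(vapply(images, function(li) prod(dim(li$image)),
                         numeric(1)))
  set_px <- rep(0, 4)
  for (li in images)
    set_px <- set_px + apply(li$mask, 3, sum)
  meta <- do.call(rbind, lapply(images, function(li) li$metadata))
  out <- data.frame(channel = CLASS_CHANNELS,
                    object_count = 0L,
                    mean_object_area = NA_real_,
                    pixel_prevalence = set_px / total_px)
  if (!is.null(meta) && nrow(meta)) {
    for (ch in seq_along(CLASS_CHANNELS)) {
      sel <- meta$class == CLASS_CHANNELS[ch]
      out$object_count[ch] <- sum(sel)
      if (any(sel)) out$mean_object_area[ch] <- mean(meta$area[sel])
    }
  }
  out
}
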