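# Grid tiling: map a tile count to a rows x cols grid, cut images into
# exact, non-overlapping rectangular crops, and stitch crops back.
#
# Conventions (part of the package contract):
#   * pixel coordinates are 0-based, half-open [start, end), row-major;
#   * grid boundaries use the floor formula floor(i * extent / k), so
#     per-axis tile sizes differ by at most one pixel and regions
#     partition the image exactly;
#   * tiles never overlap -- stitching writes every pixel exactly once.

#' Choose the rows x cols grid for a tile count
#'
#' Among all factor pairs `rows * cols = n_tiles`, picks the pair whose
#' tiles are closest to square on an image of the given extent, i.e. the
#' pair minimizing `|log((width/cols) / (height/rows))|`. Ties are broken
#' toward more columns, since panoramic images are wider than tall.
#'
#' @param n_tiles Number of tiles (>= 1).
#' @param height,width Image extent in pixels; each axis must allow at
#'   least one pixel per tile.
#' @return A `grid_layout`: list with `n_tiles`, `rows`, `cols`.
#' @examples
#' select_grid(12, 128, 256)  # 2 x 6
#' @export
select_grid <- function(n_tiles, height, width) {
  if (!is.numeric(n_tiles) || length(n_tiles) != 1 || n_tiles < 1 ||
      n_tiles != round(n_tiles))
    stop("n_tiles must be a single integer >= 1")
  if (height < 1 || width < 1) stop("height and width must be positive")
  n_tiles <- as.integer(n_tiles)
  divs <- which(n_tiles %% seq_len(n_tiles) == 0)
  rows <- divs
  cols <- n_tiles %/% divs
  if (any(rows > height) || any(cols > width)) {
    keep <- rows <= height & cols <= width
    if (!any(keep)) stop("image too small for ", n_tiles, " tiles")
    rows <- rows[keep]; cols <- cols[keep]
  }
  score <- abs(log((width / cols) / (height / rows)))
  # exact ties (e.g. 2x6 vs 3x4 on a 2:1 image) can differ by float noise;
  # round before tie-breaking toward more columns
  score <- signif(score, 12)
  best <- order(score, -cols)[1]
  structure(list(n_tiles = n_tiles, rows = rows[best], cols = cols[best]),
            class = "grid_layout")
}

#' @export
print.grid_layout <- function(x, ...) {
  cat(sprintf("grid_layout: %d tiles = %d rows x %d cols\n",
              x$n_tiles, x$rows, x$cols))
  invisible(x)
}

#' Pixel rectangles of a grid layout
#'
#' Boundary `i` on an axis of extent `e` split into `k` parts sits at
#' `floor(i * e / k)`, so the regions partition `[0, height) x [0, width)`
#' exactly and per-axis sizes differ by at most 1 pixel. Regions are
#' returned in row-major order.
#'
#' @param layout A [select_grid()] result (or list with `rows`, `cols`).
#' @param height,width Image extent in pixels.
#' @return List of `tile_region` objects: lists with 0-based half-open
#'   `row_start`, `row_end`, `col_start`, `col_end`.
#' @export
tile_bounds <- function(layout, height, width) {
  rows <- layout$rows; cols <- layout$cols
  if (height < rows || width < cols)
    stop("tiles would be smaller than 1 pixel on some axis")
  rb <- floor(seq(0, rows) * height / rows)
  cb <- floor(seq(0, cols) * width / cols)
  regions <- vector("list", rows * cols)
  k <- 1
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      regions[[k]] <- structure(
        list(row_start = rb[r], row_end = rb[r + 1],
             col_start = cb[cc], col_end = cb[cc + 1]),
        class = "tile_region")
      k <- k + 1
    }
  }
  regions
}

#' Serialize tile regions to JSON
#'
#' @param regions List of `tile_region` objects from [tile_bounds()].
#' @return A JSON array string with fields row_start, row_end, col_start,
#'   col_end per region.
#' @export
regions_to_json <- function(regions) {
  df <- do.call(rbind, lapply(regions, function(r)
    data.frame(row_start = r$row_start, row_end = r$row_end,
               col_start = r$col_start, col_end = r$col_end)))
  jsonlite::toJSON(df, dataframe = "rows", auto_unbox = TRUE)
}

check_region_in <- function(r, height, width) {
  if (r$row_start < 0 || r$col_start < 0 ||
      r$row_end > height || r$col_end > width ||
      r$row_start >= r$row_end || r$col_start >= r$col_end)
    stop("tile region outside array extent")
}

#' Extract tiles from an image or mask array
#'
#' Crops are exact sub-arrays: no interpolation, no padding. Works on 2-D
#' matrices and on (H, W, C) channel-stacked arrays.
#'
#' @param x Matrix or 3-D array.
#' @param regions Regions from [tile_bounds()] for this array's extent.
#' @return List of crops in the order of `regions`.
#' @export
extract_tiles <- function(x, regions) {
  nd <- length(dim(x))
  if (!nd %in% c(2, 3)) stop("x must be a matrix or 3-D array")
  h <- dim(x)[1]; w <- dim(x)[2]
  lapply(regions, function(r) {
    check_region_in(r, h, w)
    ri <- (r$row_start + 1):r$row_end
    ci <- (r$col_start + 1):r$col_end
    if (nd == 2) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
  })
}

#' Stitch tiles back into a full array
#'
#' Inverse of [extract_tiles()]: places each crop at its region. The
#' regions must tile the full extent; every output pixel is written
#' exactly once, which is asserted.
#'
#' @param crops List of crops (matrices or (h, w, C) arrays, all with the
#'   same number of channels).
#' @param regions Matching regions from [tile_bounds()].
#' @param height,width Output extent in pixels.
#' @return Matrix or 3-D array of the stitched result.
#' @export
stitch_tiles <- function(crops, regions, height, width) {
  if (length(crops) != length(regions))
    stop("crops and regions must have the same length")
  if (length(crops) == 0) stop("no tiles to stitch")
  nd <- length(dim(crops[[1]]))
  nc <- if (nd == 3) dim(crops[[1]])[3] else 1L
  out <- if (nd == 3) array(NA_real_, c(height, width, nc))
         else matrix(NA_real_, height, width)
  covered <- matrix(FALSE, height, width)
  for (k in seq_along(crops)) {
    r <- regions[[k]]
    check_region_in(r, height, width)
    ri <- (r$row_start + 1):r$row_end
    ci <- (r$col_start + 1):r$col_end
    cr <- crops[[k]]
    if (length(dim(cr)) != nd ||
        dim(cr)[1] != length(ri) || dim(cr)[2] != length(ci))
      stop("crop ", k, " does not match its region's shape")
    if (any(covered[ri, ci]))
      stop("overlapping regions: pixel written twice")
    covered[ri, ci] <- TRUE
    if (nd == 2) out[ri, ci] <- cr else out[ri, ci, ] <- cr
  }
  if (!all(covered)) stop("regions do not cover the full extent")
  # preserve integer/logical storage if all crops agree
  if (all(vapply(crops, is.integer, logical(1)))) storage.mode(out) <- "integer"
  out
}
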