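# Minimal 8-bit grayscale PNG codec.
#
# The environment offers no PNG package, so the package carries its own
# codec for the one PNG flavour it needs: 8-bit grayscale, non-interlaced.
# base R's memCompress(type = "gzip") emits an RFC 1950 zlib stream, which
# is exactly what an IDAT chunk holds; chunk CRCs come from the compiled
# CRC-32. The writer emits filter type 0 on every scanline; the reader
# additionally understands filters 1 (Sub) and 2 (Up).

u32_to_raw <- function(x) {
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

raw_to_u32 <- function(r) {
  sum(as.numeric(r) * c(16777216, 65536, 256, 1))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32_to_raw(length(data)), body, u32_to_raw(cpp_crc32(body)))
}

#' Write an 8-bit grayscale PNG
#'
#' @param img Numeric or integer matrix with values in 0..255 (rows = image
#'   rows, top to bottom). Values are rounded and clamped.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_png_gray <- function(img, path) {
  stopifnot(is.matrix(img))
  h <- nrow(img); w <- ncol(img)
  v <- pmin(pmax(round(img), 0), 255)
  # scanlines: filter byte 0 + row bytes, rows top to bottom
  lines <- rbind(0L, t(v))               # (w+1) x h, column i = scanline i
  raw_data <- as.raw(as.integer(lines))
  ihdr <- c(u32_to_raw(w), u32_to_raw(h),
            as.raw(c(8L, 0L, 0L, 0L, 0L)))  # depth 8, gray, deflate, adaptive, no interlace
  idat <- memCompress(raw_data, type = "gzip")   # zlib stream
  out <- c(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Read an 8-bit grayscale PNG
#'
#' Supports 8-bit grayscale, non-interlaced PNGs with any of the five
#' scanline filter types (externally written files included).
#'
#' @param path PNG file path.
#' @return Integer matrix of intensities in 0..255.
#' @export
read_png_gray <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  sig <- as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A))
  if (length(raw) < 8 || !identical(raw[1:8], sig))
    stop("not a PNG file: ", path)
  pos <- 9
  width <- height <- NULL
  idat <- list()
  while (pos + 7 <= length(raw)) {
    len <- raw_to_u32(raw[pos:(pos + 3)])
    type <- rawToChar(raw[(pos + 4):(pos + 7)])
    data <- if (len > 0) raw[(pos + 8):(pos + 7 + len)] else raw(0)
    if (type == "IHDR") {
      width <- raw_to_u32(data[1:4])
      height <- raw_to_u32(data[5:8])
      if (as.integer(data[9]) != 8 || as.integer(data[10]) != 0)
        stop("only 8-bit grayscale PNG is supported")
      if (as.integer(data[13]) != 0)
        stop("interlaced PNG is not supported")
    } else if (type == "IDAT") {
      idat[[length(idat) + 1]] <- data
    } else if (type == "IEND") break
    pos <- pos + 12 + len
  }
  if (is.null(width)) stop("missing IHDR chunk")
  stream <- memDecompress(do.call(c, idat), type = "gzip")
  bpl <- width + 1  # filter byte + pixels
  if (length(stream) != bpl * height)
    stop("corrupt PNG pixel data")
  m <- matrix(as.integer(stream), nrow = bpl, ncol = height)
  filters <- m[1, ]
  rows <- m[-1, , drop = FALSE]  # column i = scanline i
  prev <- integer(width)
  for (i in seq_len(height)) {
    f <- filters[i]
    r <- rows[, i]
    if (f == 1) {        # Sub: add left neighbour
      for (j in seq_len(width)[-1]) r[j] <- (r[j] + r[j - 1]) %% 256
    } else if (f == 2) { # Up: add pixel above
      r <- (r + prev) %% 256
    } else if (f == 3) { # Average of left and above
      r[1] <- (r[1] + prev[1] %/% 2) %% 256
      for (j in seq_len(width)[-1])
        r[j] <- (r[j] + (r[j - 1] + prev[j]) %/% 2) %% 256
    } else if (f == 4) { # Paeth predictor
      for (j in seq_len(width)) {
        a <- if (j > 1) r[j - 1] else 0L
        b <- prev[j]
        cc <- if (j > 1) prev[j - 1] else 0L
        pa <- abs(b - cc); pb <- abs(a - cc); pc <- abs(a + b - 2L * cc)
        pred <- if (pa <= pb && pa <= pc) a else if (pb <= pc) b else cc
        r[j] <- (r[j] + pred) %% 256
      }
    } else if (f != 0) {
      stop("unsupported PNG filter type ", f)
    }
    rows[, i] <- r
    prev <- r
  }
  # rows holds scanlines as columns; transpose to (height x width)
  t(rows)
}
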