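# Minimal PNG codec.
#
# The package carries its own reader/writer for 8-bit, non-interlaced PNG
# (grayscale, RGB, and RGBA on read; grayscale/RGB on write) built on base
# R's zlib bindings. Scanline unfiltering and CRC32 live in compiled code.

PNG_SIG <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))

int_to_be4 <- function(x) {
  x <- as.double(x)
  as.raw(c(x %/% 16777216, x %/% 65536, x %/% 256, x) %% 256)
}

be4_to_int <- function(r) {
  sum(as.double(r) * c(16777216, 65536, 256, 1))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(int_to_be4(length(data)), body, int_to_be4(cpp_crc32(body)))
}

#' Write an 8-bit PNG image
#'
#' @param img a numeric/integer matrix (grayscale) or H x W x 3 array (RGB),
#'   values in 0..255.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_png <- function(img, path) {
  if (is.matrix(img)) {
    h <- nrow(img); w <- ncol(img); ch <- 1L; colortype <- 0L
    bytes <- as.integer(round(t(img)))
  } else if (length(dim(img)) == 3 && dim(img)[3] == 3) {
    h <- dim(img)[1]; w <- dim(img)[2]; ch <- 3L; colortype <- 2L
    bytes <- as.integer(round(aperm(img, c(3, 2, 1))))
  } else stop("write_png: img must be a matrix or an H x W x 3 array")
  if (anyNA(bytes) || min(bytes) < 0 || max(bytes) > 255)
    stop("write_png: pixel values must be finite and within 0..255")
  # prepend filter byte 0 to every scanline
  m <- matrix(bytes, nrow = w * ch, ncol = h)
  scan <- as.raw(rbind(0L, m))
  ihdr <- c(int_to_be4(w), int_to_be4(h), as.raw(c(8L, colortype, 0L, 0L, 0L)))
  idat <- memCompress(scan, type = "gzip")  # zlib stream, as PNG requires
  out <- c(PNG_SIG,
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Read an 8-bit PNG image
#'
#' Supports non-interlaced 8-bit grayscale, RGB and RGBA (alpha discarded).
#'
#' @param path file path.
#' @return a matrix (grayscale) or H x W x 3 integer array (RGB).
#' @export
read_png <- function(path) {
  if (!file.exists(path)) stop("read_png: no such file: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8 || !identical(raw[1:8], PNG_SIG))
    stop("read_png: not a PNG file: ", path)
  pos <- 9L
  w <- h <- depth <- colortype <- interlace <- NULL
  idat <- list()
  while (pos + 8 <= length(raw)) {
    len <- be4_to_int(raw[pos:(pos + 3)])
    type <- rawToChar(raw[(pos + 4):(pos + 7)])
    data <- if (len > 0) raw[(pos + 8):(pos + 7 + len)] else raw(0)
    pos <- pos + 12L + len
    if (type == "IHDR") {
      w <- be4_to_int(data[1:4]); h <- be4_to_int(data[5:8])
      depth <- as.integer(data[9]); colortype <- as.integer(data[10])
      interlace <- as.integer(data[13])
    } else if (type == "IDAT") {
      idat[[length(idat) + 1]] <- data
    } else if (type == "IEND") break
  }
  if (is.null(w)) stop("read_png: missing IHDR")
  if (depth != 8) stop("read_png: only 8-bit PNGs are supported")
  if (interlace != 0) stop("read_png: interlaced PNGs are not supported")
  ch <- switch(as.character(colortype), "0" = 1L, "2" = 3L, "4" = 2L, "6" = 4L,
               stop("read_png: unsupported color type ", colortype))
  scan <- memDecompress(do.call(c, idat), type = "gzip")
  v <- as.integer(cpp_png_unfilter(scan, h, w, ch))
  if (ch == 1L) return(matrix(v, nrow = h, ncol = w, byrow = TRUE))
  a <- aperm(array(v, dim = c(ch, w, h)), c(3, 2, 1))
  if (ch == 2L) return(a[, , 1])
  if (ch == 4L) a <- a[, , 1:3, drop = FALSE]
  a
}
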