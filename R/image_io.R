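# Image containers and file I/O.
#
# Images are plain numeric matrices (rows x cols) on an 8-bit gray scale
# [0, 255]; intermediate results may be fractional. Files are written as
# uncompressed baseline grayscale TIFF (8- or 16-bit) or 8-bit PNG. No TIFF
# package ships with the runtime, so a minimal reader/writer for the
# uncompressed baseline subset lives here.

#' Write a grayscale image to TIFF
#'
#' Writes a single-strip, uncompressed, little-endian baseline TIFF.
#' Input values are taken on the 0..255 scale and rescaled to the target
#' bit depth (16-bit multiplies by 257), then rounded and clipped.
#'
#' @param image numeric or integer matrix, values on \code{[0, 255]} for
#'   intensity images; for label masks pass \code{bits = 16} and
#'   \code{rescale = FALSE} to store labels verbatim.
#' @param path output file path.
#' @param bits 8 or 16.
#' @param rescale rescale 0..255 data to the full target range (default
#'   TRUE); set FALSE to store integer values (e.g. instance labels) as-is.
#' @return \code{path}, invisibly.
#' @export
write_tiff <- function(image, path, bits = 16, rescale = TRUE) {
  stopifnot(is.matrix(image), bits %in% c(8L, 16L))
  maxv <- if (bits == 8) 255 else 65535
  v <- if (rescale && bits == 16) image * 257 else image
  v <- as.integer(round(clamp(v, 0, maxv)))
  nr <- nrow(image); nc <- ncol(image)
  # pixel data in row-major order
  px <- as.integer(t(matrix(v, nr, nc)))

  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  n_tags <- 8L
  ifd_offset <- 8L
  data_offset <- ifd_offset + 2L + n_tags * 12L + 4L
  writeChar("II", con, nchars = 2, eos = NULL)
  w2(42); w4(ifd_offset)
  tag <- function(id, type, count, value) { w2(id); w2(type); w4(count); w4(value) }
  w2(n_tags)
  tag(256, 3, 1, nc)                       # ImageWidth
  tag(257, 3, 1, nr)                       # ImageLength
  tag(258, 3, 1, bits)                     # BitsPerSample
  tag(259, 3, 1, 1)                        # Compression = none
  tag(262, 3, 1, 1)                        # Photometric = BlackIsZero
  tag(273, 4, 1, data_offset)              # StripOffsets
  tag(277, 3, 1, 1)                        # SamplesPerPixel
  tag(279, 4, 1, nr * nc * (bits %/% 8L))  # StripByteCounts
  w4(0)                                    # next IFD = none
  if (bits == 8) {
    writeBin(as.raw(px), con)
  } else {
    px[px > 32767L] <- px[px > 32767L] - 65536L  # two's complement for writeBin
    w2(px)
  }
  invisible(path)
}

#' Read a grayscale TIFF written by this package
#'
#' Supports uncompressed, single-sample, little-endian baseline TIFF with
#' one or more strips (the subset \code{\link{write_tiff}} emits).
#'
#' @param path file path.
#' @param rescale if TRUE (default), 16-bit data are divided by 257 back to
#'   the 0..255 working scale; set FALSE for label masks.
#' @return numeric matrix.
#' @export
read_tiff <- function(path, rescale = TRUE) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (rawToChar(raw[1:2]) != "II") stopf("only little-endian TIFF supported: %s", path)
  u <- function(idx, size) sum(as.integer(raw[idx + seq_len(size) - 1]) * 256^(0:(size - 1)))
  ifd <- u(5, 4)
  n_tags <- u(ifd + 1, 2)
  fields <- list()
  for (k in seq_len(n_tags)) {
    off <- ifd + 2 + (k - 1) * 12
    id <- u(off + 1, 2); type <- u(off + 3, 2); count <- u(off + 5, 4)
    tsize <- c(1, 1, 2, 4)[type]  # BYTE ASCII SHORT LONG
    if (is.na(tsize)) next
    vals <- if (tsize * count <= 4) {
      vapply(seq_len(count), function(i) u(off + 9 + (i - 1) * tsize, tsize), 0)
    } else {
      voff <- u(off + 9, 4)
      vapply(seq_len(count), function(i) u(voff + 1 + (i - 1) * tsize, tsize), 0)
    }
    fields[[as.character(id)]] <- vals
  }
  g <- function(id, default = NULL) fields[[as.character(id)]] %||% default
  if (g(259, 1) != 1) stopf("compressed TIFF not supported: %s", path)
  if (g(277, 1) != 1) stopf("multi-sample TIFF not supported: %s", path)
  nc <- g(256); nr <- g(257); bits <- g(258, 8)
  offsets <- g(273); counts <- g(279)
  bytes <- raw[unlist(mapply(function(o, n) o + seq_len(n), offsets, counts,
                             SIMPLIFY = FALSE))]
  px <- if (bits == 8) as.integer(bytes) else {
    readBin(bytes, "integer", n = nr * nc, size = 2, signed = FALSE, endian = "little")
  }
  img <- t(matrix(px, nc, nr))  # stored row-major
  if (rescale && bits == 16) img <- img / 257
  img
}

#' Write a grayscale image as 8-bit PNG
#' @param image numeric matrix on \code{[0, 255]}.
#' @param path output path.
#' @export
write_png <- function(image, path) {
  png::writePNG(clamp(image, 0, 255) / 255, path)
  invisible(path)
}

#' Read a grayscale image (TIFF or PNG) onto the 0..255 working scale
#' @param path file path ending in .tif/.tiff/.png.
#' @return numeric matrix.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return(read_tiff(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) a <- a[, , 1]
    return(a * 255)
  }
  stopf("unsupported image format: %s", path)
}
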