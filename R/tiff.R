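# Minimal multi-page TIFF support: uncompressed 8/16-bit grayscale,
# little-endian.  Only what the tracking pipeline needs -- none of the
# installed packages reads TIFF, so the subset is implemented here and
# cross-checked against an independent reader in the tests.

#' Write an image stack as a multi-page TIFF
#'
#' Uncompressed 16-bit grayscale, little-endian, one strip per page.
#' Values are clamped to `[0, 65535]` and rounded.
#'
#' @param stack numeric array, rows x cols x frames (a single matrix is
#'   treated as one page).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(stack, path) {
  if (length(dim(stack)) == 2L) dim(stack) <- c(dim(stack), 1L)
  nr <- dim(stack)[1]; nc <- dim(stack)[2]; np <- dim(stack)[3]
  page_bytes <- nr * nc * 2L
  n_tags <- 10L
  ifd_size <- 2L + n_tags * 12L + 4L
  data_off <- 8L
  ifd0_off <- data_off + np * page_bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd0_off, con, size = 4, endian = "little")
  for (p in seq_len(np)) {
    v <- as.integer(pmin(pmax(round(t(stack[, , p])), 0), 65535))
    writeBin(v, con, size = 2, endian = "little")
  }
  tag <- function(id, type, count, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {                    # SHORT, left-justified in 4 bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (p in seq_len(np)) {
    writeBin(n_tags, con, size = 2, endian = "little")
    tag(256, 4, 1, nc)                   # ImageWidth
    tag(257, 4, 1, nr)                   # ImageLength
    tag(258, 3, 1, 16)                   # BitsPerSample
    tag(259, 3, 1, 1)                    # Compression: none
    tag(262, 3, 1, 1)                    # Photometric: BlackIsZero
    tag(273, 4, 1, data_off + (p - 1L) * page_bytes)   # StripOffsets
    tag(277, 3, 1, 1)                    # SamplesPerPixel
    tag(278, 4, 1, nr)                   # RowsPerStrip
    tag(279, 4, 1, page_bytes)           # StripByteCounts
    tag(339, 3, 1, 1)                    # SampleFormat: unsigned int
    next_ifd <- if (p < np) ifd0_off + p * ifd_size else 0L
    writeBin(next_ifd, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a multi-page TIFF image stack
#'
#' Supports uncompressed grayscale 8- or 16-bit TIFF, either byte order,
#' multiple strips per page.
#'
#' @param path file path.
#' @return Numeric array, rows x cols x frames.
#' @export
read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file: ", path, call. = FALSE))
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
                               signed = FALSE, endian = endian)
  u32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer", size = 4,
                               endian = endian)
  if (u16(2) != 42L) stop("not a TIFF file: ", path, call. = FALSE)
  pages <- list()
  ifd <- u32(4)
  while (ifd != 0L) {
    n_tags <- u16(ifd)
    tags <- list()
    for (i in seq_len(n_tags)) {
      base <- ifd + 2L + (i - 1L) * 12L
      id <- u16(base); type <- u16(base + 2L); count <- u32(base + 4L)
      size <- switch(as.character(type),
                     "1" = 1L, "2" = 1L, "3" = 2L, "4" = 4L, "6" = 1L,
                     "7" = 1L, 8L)      # RATIONAL/LONG8/etc: never inline
      total <- size * count
      voff <- if (total <= 4L) base + 8L else u32(base + 8L)
      vals <- if (type == 3L) vapply(seq_len(count) - 1L,
                                     function(j) u16(voff + 2L * j), 0L)
      else vapply(seq_len(count) - 1L, function(j) u32(voff + 4L * j), 0L)
      tags[[as.character(id)]] <- vals
    }
    width <- tags[["256"]][1]; height <- tags[["257"]][1]
    bits <- (tags[["258"]] %||% 1L)[1]
    if (!is.null(tags[["259"]]) && tags[["259"]][1] != 1L)
      stop("compressed TIFF not supported", call. = FALSE)
    if (!bits %in% c(8L, 16L))
      stop("only 8/16-bit grayscale TIFF supported", call. = FALSE)
    offs <- tags[["273"]]; counts <- tags[["279"]]
    bytes <- unlist(lapply(seq_along(offs), function(s)
      raw[(offs[s] + 1):(offs[s] + counts[s])]))
    vals <- readBin(bytes, "integer", n = width * height, size = bits / 8L,
                    signed = FALSE, endian = endian)
    pages[[length(pages) + 1L]] <- t(matrix(vals, nrow = width, ncol = height))
    ifd <- u32(ifd + 2L + n_tags * 12L)
  }
  if (!length(pages)) stop("TIFF contains no pages", call. = FALSE)
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}
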