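# BMP content plugin: header/pixel-array cross-checks and the pixel <->
# decoded-cell translation used for visual tagging.
#
# Supported: uncompressed BI_RGB bitmaps with the 40-byte info header
# (BITMAPINFOHEADER) or the 12-byte OS/2 core header; anything compressed
# is rejected.

BMP_SIGNATURES <- c("BM", "BA", "CI", "CP", "IC", "PT")

#' Build a bottom-up 24-bit BMP file in memory
#'
#' Minimal writer used to generate image fixtures programmatically (no
#' binary assets are shipped): BITMAPINFOHEADER, BI_RGB, rows padded to 4
#' bytes, bottom-up row order.
#'
#' @param width,height image dimensions in pixels
#' @param pixels raw vector of `3 * width * height` bytes, BGR per pixel,
#'   top-down row-major (converted to the stored bottom-up order here)
#' @return raw vector: the BMP file
#' @export
bmp_build <- function(width, height, pixels) {
  stopifnot(is.raw(pixels), length(pixels) == 3 * width * height)
  row_size <- ((3 * width + 3) %/% 4) * 4
  img_size <- row_size * height
  file_size <- 14 + 40 + img_size
  hdr <- c(charToRaw("BM"), u32_to_bytes_le(file_size),
           raw(4), u32_to_bytes_le(54))
  dib <- c(u32_to_bytes_le(40), u32_to_bytes_le(width),
           u32_to_bytes_le(height), u16_to_bytes_le(1), u16_to_bytes_le(24),
           u32_to_bytes_le(0), u32_to_bytes_le(img_size),
           u32_to_bytes_le(2835), u32_to_bytes_le(2835),
           u32_to_bytes_le(0), u32_to_bytes_le(0))
  px <- raw(img_size)
  for (y in seq_len(height)) {
    src <- ((y - 1) * width * 3 + 1):(y * width * 3)
    dst0 <- (height - y) * row_size
    px[(dst0 + 1):(dst0 + 3 * width)] <- pixels[src]
  }
  c(hdr, dib, px)
}

bmp_field <- function(bytes, offset, size) {
  # offset is 0-based file offset, as BMP documentation states them
  bytes[(offset + 1):(offset + size)]
}

#' Cross-check a decoded BMP against its structural invariants
#'
#' Parses the bitmap file header (signature, stored file size, reserved
#' words, pixel-array offset) and the DIB header (width, height, planes,
#' bits per pixel, compression), and cross-checks them against the decoded
#' length and against each other: the stored size must equal the decoded
#' length, planes must be 1, the pixel array must span exactly from its
#' stored offset to the end, and `rowsize(width, bpp) * height` must match.
#' Mismatching bytes are marked invalid, with the expected value suggested
#' where it is forced.
#'
#' @param dr a `decode_result` whose file is a candidate BMP
#' @return list with `error_matrix` (over the solution rows), `header`
#'   (parsed fields), `ok` (per-check logical vector)
#' @export
bmp_analyze <- function(dr) {
  stopifnot(inherits(dr, "decode_result"))
  solution <- dr$solution
  cs <- ncol(solution)
  n_data <- dr$n_chunks - 1L
  bytes <- as.vector(t(solution[1L + seq_len(n_data), , drop = FALSE]))
  decoded_len <- if (!is.null(dr$header))
    (n_data - 1L) * cs + dr$header$last_chunk_length else length(bytes)
  if (decoded_len < 54) stop("data too short for a BMP file")
  bytes <- bytes[seq_len(decoded_len)]

  em <- error_matrix(nrow(solution), cs)
  mark <- function(em, pos0, size, state, suggest = NULL) {
    em_mark_file_bytes(em, (pos0 + 1):(pos0 + size), state, suggest,
                       chunk_size = cs)
  }
  ok <- logical(0)

  sig <- rawToChar(bmp_field(bytes, 0, 2))
  sig_ok <- sig %in% BMP_SIGNATURES
  ok["signature"] <- sig_ok
  if (sig_ok) {
    em <- mark(em, 0, 2, 0L)
  } else {
    # per-byte: suggest the bytes of the common "BM" signature
    sug <- as.integer(charToRaw("BM"))
    cur <- as.integer(bmp_field(bytes, 0, 2))
    for (i in 1:2) {
      if (cur[i] != sug[i]) em <- mark(em, i - 1, 1, 1L, sug[i])
      else em <- mark(em, i - 1, 1, 0L)
    }
  }

  stored_size <- bytes_le_to_u32(bmp_field(bytes, 2, 4))
  size_ok <- stored_size == decoded_len
  ok["file_size"] <- size_ok
  em <- if (size_ok) mark(em, 2, 4, 0L)
        else mark(em, 2, 4, 1L, as.integer(u32_to_bytes_le(decoded_len)))

  pix_off <- bytes_le_to_u32(bmp_field(bytes, 10, 4))
  dib_size <- bytes_le_to_u32(bmp_field(bytes, 14, 4))
  core <- dib_size == 12
  if (!(dib_size %in% c(12, 40))) {
    # neither supported header size: flag, assume the common 40-byte header
    em <- mark(em, 14, 4, 1L, as.integer(u32_to_bytes_le(40)))
    dib_size <- 40
    core <- FALSE
    ok["dib_size"] <- FALSE
  } else {
    em <- mark(em, 14, 4, 0L)
    ok["dib_size"] <- TRUE
  }

  if (core) {
    width <- bytes_le_to_u16(bmp_field(bytes, 18, 2))
    height <- bytes_le_to_u16(bmp_field(bytes, 20, 2))
    planes <- bytes_le_to_u16(bmp_field(bytes, 22, 2))
    bpp <- bytes_le_to_u16(bmp_field(bytes, 24, 2))
    planes_off <- 22; bpp_off <- 24
    compression <- 0
  } else {
    width <- bytes_le_to_u32(bmp_field(bytes, 18, 4))
    height <- bytes_le_to_u32(bmp_field(bytes, 22, 4))
    planes <- bytes_le_to_u16(bmp_field(bytes, 26, 2))
    bpp <- bytes_le_to_u16(bmp_field(bytes, 28, 2))
    planes_off <- 26; bpp_off <- 28
    compression <- bytes_le_to_u32(bmp_field(bytes, 30, 4))
  }
  if (compression != 0)
    stop("compressed BMP variants are not supported")

  planes_ok <- planes == 1
  ok["planes"] <- planes_ok
  em <- if (planes_ok) mark(em, planes_off, 2, 0L)
        else mark(em, planes_off, 2, 1L, as.integer(u16_to_bytes_le(1)))

  off_expect <- 14 + dib_size
  off_ok <- pix_off == off_expect
  ok["pixel_offset"] <- off_ok
  em <- if (off_ok) mark(em, 10, 4, 0L)
        else mark(em, 10, 4, 1L, as.integer(u32_to_bytes_le(off_expect)))

  row_size <- ((bpp * width + 31) %/% 32) * 4
  geom_ok <- is.finite(row_size) && row_size > 0 &&
    (pix_off + row_size * height == decoded_len ||
     off_expect + row_size * height == decoded_len)
  ok["geometry"] <- geom_ok
  wh_off <- 18
  wh_len <- if (core) 4 else 8
  em <- if (geom_ok) mark(em, wh_off, wh_len, 0L)
        else mark(em, wh_off, wh_len, 1L)

  list(error_matrix = em,
       header = list(signature = sig, file_size = stored_size,
                     pixel_offset = pix_off, dib_size = dib_size,
                     width = width, height = height, planes = planes,
                     bpp = bpp, compression = compression,
                     row_size = row_size, decoded_len = decoded_len),
       ok = ok)
}

#' Translate image pixels to decoded-solution cells
#'
#' Accounts for the bottom-up row order, the per-pixel byte width and the
#' 4-byte row padding of the stored pixel array, plus the header chunk
#' offset of the decoded solution.  Pixel (1, 1) is the top-left image
#' pixel, which lives in the LAST stored pixel-array row.
#'
#' @param header parsed header list from [bmp_analyze()]
#' @param pixels 2-column matrix (x, y) of pixel coordinates, 1-based
#' @param chunk_size bytes per decoded chunk
#' @return data.frame with `x`, `y`, `byte` (1-based position within the
#'   decoded file), `row`, `col` (solution coordinates, header row = 1)
#' @export
bmp_pixel_to_cells <- function(header, pixels, chunk_size) {
  pixels <- matrix(as.integer(pixels), ncol = 2)
  if (any(pixels[, 1] < 1 | pixels[, 1] > header$width |
          pixels[, 2] < 1 | pixels[, 2] > header$height))
    stop("pixel coordinates out of range")
  bytes_pp <- header$bpp %/% 8
  out <- do.call(rbind, lapply(seq_len(nrow(pixels)), function(i) {
    x <- pixels[i, 1]; y <- pixels[i, 2]
    stored_row <- header$height - y  # bottom-up
    off0 <- header$pixel_offset + stored_row * header$row_size +
      (x - 1) * bytes_pp
    byte <- (off0 + 1):(off0 + bytes_pp)
    data.frame(x = x, y = y, byte = byte)
  }))
  out$row <- 1L + ((out$byte - 1L) %/% chunk_size) + 1L
  out$col <- ((out$byte - 1L) %% chunk_size) + 1L
  out
}

#' Translate a decoded-solution cell back to an image pixel
#'
#' Inverse of [bmp_pixel_to_cells()] for cells inside the pixel array.
#'
#' @param header parsed header list from [bmp_analyze()]
#' @param row,col solution coordinates (header chunk is row 1)
#' @param chunk_size bytes per decoded chunk
#' @return list with `x`, `y` or `NULL` when the cell is outside the
#'   pixel array
#' @export
bmp_cell_to_pixel <- function(header, row, col, chunk_size) {
  byte <- (row - 2L) * chunk_size + col  # 1-based within file
  off0 <- byte - 1L
  if (off0 < header$pixel_offset) return(NULL)
  rel <- off0 - header$pixel_offset
  stored_row <- rel %/% header$row_size
  inrow <- rel %% header$row_size
  bytes_pp <- header$bpp %/% 8
  x <- inrow %/% bytes_pp + 1L
  if (x > header$width) return(NULL)  # padding byte
  y <- header$height - stored_row
  list(x = as.integer(x), y = as.integer(y))
}
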