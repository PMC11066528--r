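# CRC-32 (reflected polynomial 0xEDB88320), table-driven.
# Used for the optional file-wide checksum in the header chunk and for ZIP
# entry validation.

crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    crc <- i
    for (k in 1:8) {
      crc <- if (bitwAnd(crc, 1L) != 0L) {
        bitwXor(bitwShiftR(crc, 1L), -306674912L)  # 0xEDB88320 as signed
      } else {
        bitwShiftR(crc, 1L)
      }
    }
    tab[i + 1] <- crc
  }
  tab
})

#' CRC-32 checksum of a raw vector
#'
#' Standard CRC-32 (the ZIP / zlib variant, reflected polynomial
#' 0xEDB88320, initial and final XOR 0xFFFFFFFF).
#'
#' @param data raw vector
#' @return checksum as a double in `[0, 2^32)` (R integers cannot hold
#'   unsigned 32-bit values)
#' @export
crc32 <- function(data) {
  stopifnot(is.raw(data))
  .crc32_cpp(data)
}

# pure-R reference used as an independent oracle in the tests
crc32_ref <- function(data) {
  crc <- -1L  # 0xFFFFFFFF
  for (byte in as.integer(data)) {
    idx <- bitwAnd(bitwXor(crc, byte), 255L)
    crc <- bitwXor(bitwShiftR(crc, 8L), crc32_table[idx + 1])
  }
  crc <- bitwXor(crc, -1L)
  if (crc < 0) crc + 4294967296 else as.double(crc)
}

# 32-bit value <-> 4 bytes little-endian (ZIP field order)
u32_to_bytes_le <- function(x) {
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}
bytes_le_to_u32 <- function(b) {
  stopifnot(length(b) == 4)
  v <- as.integer(b)
  v[1] + v[2] * 256 + v[3] * 65536 + v[4] * 16777216
}
# big-endian variants (header chunk layout)
u32_to_bytes_be <- function(x) rev(u32_to_bytes_le(x))
bytes_be_to_u32 <- function(b) bytes_le_to_u32(rev(b))
u16_to_bytes_le <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))
bytes_le_to_u16 <- function(b) as.integer(b[1]) + as.integer(b[2]) * 256
u16_to_bytes_be <- function(x) rev(u16_to_bytes_le(x))
bytes_be_to_u16 <- function(b) bytes_le_to_u16(rev(b))
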