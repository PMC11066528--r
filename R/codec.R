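# Seeded fountain encoding / decoding of files into fixed-length packets.

HEADER_CRC_FLAG <- as.raw(0x01)

#' Serialize the header chunk
#'
#' Layout (bytes, in order): 4-byte last-chunk length (big-endian), 2-byte
#' filename length, filename (UTF-8), 1-byte CRC marker, optional 4-byte
#' CRC-32 of the whole file, zero padding up to `chunk_size`.
#'
#' @param last_chunk_length bytes of real data in the final data chunk
#' @param filename stored file name (UTF-8)
#' @param file_crc32 optional CRC-32 of the original file (double), or `NULL`
#' @param chunk_size chunk size in bytes
#' @return raw vector of length `chunk_size`
#' @export
serialize_header <- function(last_chunk_length, filename, file_crc32,
                             chunk_size) {
  fn <- charToRaw(enc2utf8(filename))
  fixed <- 4 + 2 + length(fn) + 1 + if (is.null(file_crc32)) 0 else 4
  if (fixed > chunk_size)
    stop("filename too long for the header chunk capacity")
  out <- c(
    u32_to_bytes_be(last_chunk_length),
    u16_to_bytes_be(length(fn)),
    fn,
    if (is.null(file_crc32)) as.raw(0x00) else HEADER_CRC_FLAG,
    if (is.null(file_crc32)) raw(0) else u32_to_bytes_be(file_crc32)
  )
  c(out, raw(chunk_size - length(out)))
}

#' Parse a header chunk
#' @param bytes raw vector (a decoded header chunk row)
#' @return list with `last_chunk_length`, `filename`, `file_crc32` (or NULL)
#' @export
parse_header <- function(bytes) {
  stopifnot(is.raw(bytes), length(bytes) >= 7)
  lcl <- bytes_be_to_u32(bytes[1:4])
  fl <- bytes_be_to_u16(bytes[5:6])
  if (6 + fl + 1 > length(bytes)) stop("malformed header chunk")
  filename <- rawToChar(bytes[seq_len(fl) + 6])
  pos <- 6 + fl + 1
  crc <- NULL
  if (bytes[pos] == HEADER_CRC_FLAG) {
    if (pos + 4 > length(bytes)) stop("malformed header chunk (CRC)")
    crc <- bytes_be_to_u32(bytes[(pos + 1):(pos + 4)])
  }
  list(last_chunk_length = lcl, filename = filename, file_crc32 = crc)
}

#' Split a file into a header chunk plus zero-padded data chunks
#'
#' Chunk 1 is the serialized header; data chunks follow in file order, the
#' last one zero-padded to `chunk_size`.
#'
#' @param data raw vector (the file)
#' @param chunk_size bytes per chunk
#' @param filename name recorded in the header
#' @param with_crc store a file-wide CRC-32 in the header?
#' @return raw matrix, one chunk per row (`1 + ceiling(length(data)/chunk_size)`
#'   rows)
#' @export
split_with_header <- function(data, chunk_size, filename = "data.bin",
                              with_crc = TRUE) {
  stopifnot(is.raw(data), length(data) > 0, chunk_size > 0)
  n_data <- ceiling(length(data) / chunk_size)
  last_len <- length(data) - (n_data - 1) * chunk_size
  padded <- c(data, raw(n_data * chunk_size - length(data)))
  chunks <- matrix(padded, nrow = n_data, ncol = chunk_size, byrow = TRUE)
  hdr <- serialize_header(last_len, filename,
                          if (with_crc) crc32(data) else NULL, chunk_size)
  rbind(matrix(hdr, nrow = 1), chunks)
}

#' Reassemble a file from decoded chunk rows
#'
#' @param chunks raw matrix of decoded chunk rows (header first)
#' @return list with `file` (raw), `header` (parsed), `crc_ok` (`NA` when no
#'   checksum is stored)
#' @export
reassemble_file <- function(chunks) {
  hdr <- parse_header(chunks[1, ])
  n_data <- nrow(chunks) - 1
  if (n_data < 1) stop("no data chunks")
  if (hdr$last_chunk_length < 0 || hdr$last_chunk_length > ncol(chunks))
    stop("malformed header: last-chunk length exceeds the chunk size")
  body <- as.vector(t(chunks[-1, , drop = FALSE]))
  keep <- (n_data - 1) * ncol(chunks) + hdr$last_chunk_length
  file <- body[seq_len(keep)]
  crc_ok <- if (is.null(hdr$file_crc32)) NA else crc32(file) == hdr$file_crc32
  list(file = file, header = hdr, crc_ok = crc_ok)
}

#' Does the stored file-wide checksum validate a candidate file?
#' @param file raw vector
#' @param header parsed header (see [parse_header()])
#' @return logical
#' @export
file_checksum_valid <- function(file, header) {
  if (is.null(header$file_crc32))
    stop("no checksum present in header")
  crc32(file) == header$file_crc32
}

#' Encoder configuration
#'
#' @param chunk_size bytes per chunk (payload bytes per packet)
#' @param n_packets number of packets to emit; defaults to
#'   `n_chunks + overhead` at encode time when `NULL`
#' @param overhead packets beyond the chunk count (used when `n_packets`
#'   is `NULL`)
#' @param distribution a [degree_distribution()]
#' @param seed_len seed length in bytes carried by each packet
#' @param use_header prepend a header chunk?
#' @param with_crc store the file-wide CRC-32 in the header?
#' @param n_padding_chunks number of artificial all-zero chunks appended for
#'   the zero-byte-padding recovery scheme (each packet then XORs exactly
#'   one of them, chosen uniformly by its seed)
#' @param ecc_sym Reed-Solomon parity bytes appended per packet
#' @param reject_duplicates reject seeds that reproduce an already-emitted
#'   chunk set (degenerate encodings)
#' @param max_attempts cap on candidate seeds tried per accepted packet
#' @return object of class `encoder_config`
#' @export
encoder_config <- function(chunk_size,
                           n_packets = NULL,
                           overhead = 2,
                           distribution = degree_distribution("raptor"),
                           seed_len = 4,
                           use_header = TRUE,
                           with_crc = TRUE,
                           n_padding_chunks = 0,
                           ecc_sym = 0,
                           reject_duplicates = FALSE,
                           max_attempts = 1000) {
  stopifnot(chunk_size > 0, seed_len >= 1, n_padding_chunks >= 0)
  structure(list(chunk_size = chunk_size, n_packets = n_packets,
                 overhead = overhead, distribution = distribution,
                 seed_len = seed_len, use_header = use_header,
                 with_crc = with_crc, n_padding_chunks = n_padding_chunks,
                 ecc_sym = ecc_sym, reject_duplicates = reject_duplicates,
                 max_attempts = max_attempts, prng = "lcg32"),
            class = "encoder_config")
}

# padding-chunk pick for a seed: one uniform draw from a stream re-seeded
# with a fixed tweak, so the decoder can reproduce it from the seed alone
padding_pick <- function(seed, n_padding) {
  if (n_padding == 0) return(integer(0))
  s <- lcg_next(mix32(xor32(seed %% 4294967296, 1515870810)))  # 0x5A5A5A5A
  min(floor((s / 4294967296) * n_padding) + 1, n_padding)
}

seed_to_bytes <- function(seed, seed_len) {
  out <- raw(seed_len)
  x <- seed
  for (i in seed_len:1) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

bytes_to_seed <- function(bytes) {
  x <- 0
  for (b in bytes) x <- x * 256 + as.integer(b)
  x
}

#' Fountain-encode a file into packets
#'
#' Candidate packets are generated from strictly increasing seeds; each
#' seed deterministically selects the chunk set to XOR.  When `constraints`
#' is supplied, each candidate's DNA rendition (seed bytes + payload +
#' optional RS parity, 2 bits/base) is screened and rejected candidates are
#' skipped, which is how fountain codes absorb DNA synthesis constraints
#' without extra overhead.
#'
#' @param data raw vector (the file)
#' @param config an [encoder_config()]
#' @param constraints a [constraint_set()] or `NULL` to skip screening
#' @param filename name recorded in the header chunk
#' @param first_seed first candidate seed
#' @param ensure_decodable restart from fresh seeds until the emitted packet
#'   set has full rank (decodable without further packets); raw fountain
#'   sampling occasionally yields rank-deficient sets at small overheads
#' @return object of class `packet_set`: list with `packets` (each with
#'   `seed`, `chunks`, `payload`, `ecc`), `n_chunks` (header + data),
#'   `n_padding`, `config`
#' @export
encode <- function(data, config, constraints = NULL,
                   filename = "data.bin", first_seed = 1,
                   ensure_decodable = FALSE) {
  stopifnot(inherits(config, "encoder_config"))
  if (ensure_decodable) {
    fs <- first_seed
    for (i in 1:100) {
      pk <- encode(data, config, constraints, filename, fs,
                   ensure_decodable = FALSE)
      sys <- packets_to_system(pk$packets, pk$n_chunks, pk$n_padding, config)
      if (gf2_rank(sys$A) == ncol(sys$A)) return(pk)
      fs <- max(vapply(pk$packets, function(p) p$seed, numeric(1))) + 1
    }
    stop("could not reach a full-rank packet set")
  }
  chunks <- if (config$use_header) {
    split_with_header(data, config$chunk_size, filename, config$with_crc)
  } else {
    n_data <- ceiling(length(data) / config$chunk_size)
    padded <- c(data, raw(n_data * config$chunk_size - length(data)))
    matrix(padded, nrow = n_data, ncol = config$chunk_size, byrow = TRUE)
  }
  n_chunks <- nrow(chunks)
  npad <- config$n_padding_chunks
  n_packets <- config$n_packets
  if (is.null(n_packets)) n_packets <- n_chunks + npad + config$overhead

  packets <- vector("list", n_packets)
  seen_sets <- character(0)
  seed <- first_seed
  got <- 0
  attempts <- 0
  while (got < n_packets) {
    attempts <- attempts + 1
    if (attempts > config$max_attempts * n_packets)
      stop("unencodable under constraints: candidate cap exceeded")
    sel <- chunks_from_seed(seed, n_chunks, config$distribution)
    pad_sel <- padding_pick(seed, npad)
    key <- paste(c(sel, if (npad > 0) n_chunks + pad_sel), collapse = ",")
    ok <- TRUE
    if (config$reject_duplicates && key %in% seen_sets) ok <- FALSE
    payload <- NULL
    ecc <- raw(0)
    if (ok) {
      payload <- chunks[sel[1], ]
      for (j in sel[-1]) payload <- xor_raw(payload, chunks[j, ])
      # padding chunks are all-zero: payload unchanged
      if (config$ecc_sym > 0) {
        body <- rs_encode(c(seed_to_bytes(seed, config$seed_len), payload),
                          config$ecc_sym)
        ecc <- body[(length(body) - config$ecc_sym + 1):length(body)]
      }
      if (!is.null(constraints)) {
        dna <- to_dna(c(seed_to_bytes(seed, config$seed_len), payload, ecc))
        ok <- check_constraints(dna, constraints)$pass
      }
    }
    if (ok) {
      got <- got + 1
      packets[[got]] <- list(seed = seed, chunks = sel,
                             padding_chunk = pad_sel,
                             payload = payload, ecc = ecc)
      seen_sets <- c(seen_sets, key)
    }
    seed <- seed + 1
  }
  structure(list(packets = packets, n_chunks = n_chunks, n_padding = npad,
                 config = config, filename = filename),
            class = "packet_set")
}

#' @export
print.packet_set <- function(x, ...) {
  cat(sprintf(
    "Fountain packet set: %d packets over %d chunks (%d byte chunks%s)\n",
    length(x$packets), x$n_chunks, x$config$chunk_size,
    if (x$n_padding > 0) sprintf(", %d padding chunks", x$n_padding) else ""))
  invisible(x)
}

# system matrix [A] and payload rows [b] from a packet list
packets_to_system <- function(packets, n_chunks, n_padding, config) {
  M <- length(packets)
  N <- n_chunks + n_padding
  A <- matrix(0L, nrow = M, ncol = N)
  b <- matrix(as.raw(0), nrow = M, ncol = config$chunk_size)
  for (i in seq_len(M)) {
    p <- packets[[i]]
    sel <- chunks_from_seed(p$seed, n_chunks, config$distribution)
    A[i, sel] <- 1L
    if (n_padding > 0)
      A[i, n_chunks + padding_pick(p$seed, n_padding)] <- 1L
    b[i, ] <- p$payload
  }
  list(A = A, b = b)
}

#' Decode fountain packets back into a file
#'
#' Rebuilds the GF(2) system from the packet seeds and runs tracked
#' Gaussian elimination.  Status is `"solved"` when every data-chunk row is
#' solved and the system is consistent, `"inconsistent"` when the augmented
#' rank exceeds `rank(A)` (a corrupted packet is present), `"partial"` when
#' rows remain unsolved (insufficient packets).
#'
#' @param pk a `packet_set` (from [encode()]) or a bare list of packets
#' @param n_chunks chunk count (header + data); taken from `pk` when absent
#' @param config the [encoder_config()] used at encoding time
#' @param n_padding number of padding chunks used at encoding time
#' @return object of class `decode_result`: `system` (a `tracked_system`),
#'   `status`, `file` (raw or `NULL`), `header`, `crc_ok`, `solution` (raw
#'   matrix of decoded chunk rows), plus the system inputs
#' @export
decode <- function(pk, n_chunks = NULL, config = NULL, n_padding = NULL) {
  if (inherits(pk, "packet_set")) {
    packets <- pk$packets
    if (is.null(n_chunks)) n_chunks <- pk$n_chunks
    if (is.null(config)) config <- pk$config
    if (is.null(n_padding)) n_padding <- pk$n_padding
  } else {
    packets <- pk
    if (is.null(n_chunks) || is.null(config))
      stop("n_chunks and config are required for a bare packet list")
    if (is.null(n_padding)) n_padding <- config$n_padding_chunks
  }
  lens <- vapply(packets, function(p) length(p$payload), integer(1))
  if (length(unique(lens)) > 1) stop("mixed payload lengths")
  sys <- packets_to_system(packets, n_chunks, n_padding, config)
  decode_system(sys$A, sys$b, n_chunks, n_padding, config)
}

# decode from an explicit (A, b) system; shared by decode() and the repair
# machinery
decode_system <- function(A, b, n_chunks, n_padding, config) {
  N <- ncol(A)
  storage.mode(A) <- "integer"
  # one tracked elimination yields rank(A) (all chunk rows solved iff
  # rank = N) and consistency (residual rows with non-zero payload)
  res <- .gf2_eliminate_cpp(A, b, seq_len(nrow(A)) - 1L, 0L)
  t <- new_tracked_system(A, b, res, seq_len(nrow(A)), "full")
  consistent <- !has_inconsistent_residual(t)
  if (!all(t$solved_mask)) t <- partial_eliminate(A, b)
  data_rows <- seq_len(n_chunks)
  all_solved <- all(t$solved_mask[data_rows])
  status <- if (!consistent) "inconsistent"
            else if (all_solved) "solved"
            else "partial"
  solution <- t$reduced_b[seq_len(N), , drop = FALSE]
  file <- NULL; header <- NULL; crc_ok <- NA
  if (all_solved && config$use_header) {
    asm <- tryCatch(
      reassemble_file(solution[data_rows, , drop = FALSE]),
      error = function(e) NULL)
    if (!is.null(asm)) {
      file <- asm$file; header <- asm$header; crc_ok <- asm$crc_ok
    }
  } else if (all_solved) {
    file <- as.vector(t(solution[data_rows, , drop = FALSE]))
  }
  structure(list(system = t, A = A, b = b, n_chunks = n_chunks,
                 n_padding = n_padding, config = config, status = status,
                 solution = solution, file = file, header = header,
                 crc_ok = crc_ok),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("Fountain decode: status %s\n", x$status))
  cat(sprintf("  chunks solved: %d / %d\n",
              sum(x$system$solved_mask[seq_len(x$n_chunks)]), x$n_chunks))
  if (!is.null(x$file))
    cat(sprintf("  file: %d bytes%s\n", length(x$file),
                if (is.na(x$crc_ok)) "" else
                  if (x$crc_ok) " (checksum OK)" else " (CHECKSUM MISMATCH)"))
  unsolved <- which(!x$system$solved_mask[seq_len(x$n_chunks)])
  if (length(unsolved) > 0)
    cat("  unsolved chunk rows:", paste(unsolved, collapse = ", "), "\n")
  invisible(x)
}
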