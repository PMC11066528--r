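# ZIP content plugin.  ZIP archives duplicate per-file metadata between
# each local file header and its central-directory twin, and every entry
# carries a CRC-32 of its uncompressed payload; this structural redundancy
# cross-checks decoded bytes.  Headers are located by scanning the whole
# stream for the three signatures, so a corrupted length field cannot
# truncate a following header region.

SIG_LOCAL <- as.raw(c(0x50, 0x4b, 0x03, 0x04))
SIG_CENTRAL <- as.raw(c(0x50, 0x4b, 0x01, 0x02))
SIG_EOCD <- as.raw(c(0x50, 0x4b, 0x05, 0x06))

find_signature <- function(bytes, sig) {
  n <- length(bytes)
  if (n < length(sig)) return(integer(0))
  hits <- which(bytes == sig[1])
  hits <- hits[hits <= n - length(sig) + 1]
  for (k in 2:length(sig)) hits <- hits[bytes[hits + k - 1] == sig[k]]
  hits  # 1-based positions
}

# raw deflate stream -> bytes, via a gzip container around the stream
inflate_raw <- function(data, expected_size = NA) {
  gz <- c(as.raw(c(0x1f, 0x8b, 0x08, 0, 0, 0, 0, 0, 0, 0xff)), data,
          u32_to_bytes_le(0), u32_to_bytes_le(0))
  tryCatch(memDecompress(gz, type = "gzip"), error = function(e) NULL)
}

#' Build a stored-method ZIP archive in memory
#'
#' Minimal writer used to generate archive fixtures programmatically:
#' every entry is stored uncompressed (method 0) with its CRC-32.
#'
#' @param files named list of raw vectors (entry name -> content)
#' @return raw vector: the ZIP file
#' @export
zip_build <- function(files) {
  stopifnot(length(files) > 0, !is.null(names(files)))
  locals <- raw(0)
  centrals <- raw(0)
  offsets <- integer(length(files))
  for (i in seq_along(files)) {
    name <- charToRaw(names(files)[i])
    data <- files[[i]]
    crc <- crc32(data)
    offsets[i] <- length(locals)
    lh <- c(SIG_LOCAL, u16_to_bytes_le(20), u16_to_bytes_le(0),
            u16_to_bytes_le(0), u16_to_bytes_le(0x6020),
            u16_to_bytes_le(0x5821), u32_to_bytes_le(crc),
            u32_to_bytes_le(length(data)), u32_to_bytes_le(length(data)),
            u16_to_bytes_le(length(name)), u16_to_bytes_le(0), name)
    locals <- c(locals, lh, data)
    ch <- c(SIG_CENTRAL, u16_to_bytes_le(20), u16_to_bytes_le(20),
            u16_to_bytes_le(0), u16_to_bytes_le(0), u16_to_bytes_le(0x6020),
            u16_to_bytes_le(0x5821), u32_to_bytes_le(crc),
            u32_to_bytes_le(length(data)), u32_to_bytes_le(length(data)),
            u16_to_bytes_le(length(name)), u16_to_bytes_le(0),
            u16_to_bytes_le(0), u16_to_bytes_le(0), u16_to_bytes_le(0),
            u32_to_bytes_le(0), u32_to_bytes_le(offsets[i]), name)
    centrals <- c(centrals, ch)
  }
  eocd <- c(SIG_EOCD, u16_to_bytes_le(0), u16_to_bytes_le(0),
            u16_to_bytes_le(length(files)), u16_to_bytes_le(length(files)),
            u32_to_bytes_le(length(centrals)),
            u32_to_bytes_le(length(locals)), u16_to_bytes_le(0))
  c(locals, centrals, eocd)
}

parse_local <- function(bytes, pos) {
  # pos: 1-based offset of the signature; returns NULL if truncated
  if (pos + 29 > length(bytes)) return(NULL)
  g <- function(off, n) bytes[(pos + off):(pos + off + n - 1)]
  fnlen <- bytes_le_to_u16(g(26, 2))
  exlen <- bytes_le_to_u16(g(28, 2))
  name_end <- pos + 30 + fnlen - 1
  if (name_end > length(bytes)) { fnlen <- 0; name_end <- pos + 29 }
  list(offset = pos - 1L,
       flags = bytes_le_to_u16(g(6, 2)), method = bytes_le_to_u16(g(8, 2)),
       time = bytes_le_to_u16(g(10, 2)), date = bytes_le_to_u16(g(12, 2)),
       crc = bytes_le_to_u32(g(14, 4)), csize = bytes_le_to_u32(g(18, 4)),
       usize = bytes_le_to_u32(g(22, 4)), fnlen = fnlen, exlen = exlen,
       name = if (fnlen > 0) bytes[(pos + 30):name_end] else raw(0),
       data_start = pos + 30 + fnlen + exlen)  # 1-based
}

parse_central <- function(bytes, pos) {
  if (pos + 45 > length(bytes)) return(NULL)
  g <- function(off, n) bytes[(pos + off):(pos + off + n - 1)]
  fnlen <- bytes_le_to_u16(g(28, 2))
  name_end <- pos + 46 + fnlen - 1
  if (name_end > length(bytes)) { fnlen <- 0; name_end <- pos + 45 }
  list(offset = pos - 1L,
       flags = bytes_le_to_u16(g(8, 2)), method = bytes_le_to_u16(g(10, 2)),
       time = bytes_le_to_u16(g(12, 2)), date = bytes_le_to_u16(g(14, 2)),
       crc = bytes_le_to_u32(g(16, 4)), csize = bytes_le_to_u32(g(20, 4)),
       usize = bytes_le_to_u32(g(24, 4)), fnlen = fnlen,
       local_offset = bytes_le_to_u32(g(42, 4)),
       name = if (fnlen > 0) bytes[(pos + 46):name_end] else raw(0))
}

# (0-based field offset within header, length) for the duplicated fields
LOCAL_FIELD_POS <- list(flags = c(6, 2), method = c(8, 2), time = c(10, 2),
                        date = c(12, 2), crc = c(14, 4), csize = c(18, 4),
                        usize = c(22, 4))
CENTRAL_FIELD_POS <- list(flags = c(8, 2), method = c(10, 2), time = c(12, 2),
                          date = c(14, 2), crc = c(16, 4), csize = c(20, 4),
                          usize = c(24, 4))

#' Structural cross-check of a decoded ZIP archive
#'
#' Scans the decoded bytes for local-file-header, central-directory and
#' end-of-central-directory signatures, parses every header found (a bad
#' length field therefore cannot hide a later header), follows
#' central-directory offsets to locals, and cross-checks each duplicated
#' field (CRC-32, sizes, flags, method, modification time/date, filename)
#' between the two copies.  Matching fields become valid cells; a mismatch
#' yields an alternating candidate pair, since either copy may be the
#' corrupt one.  Entry payloads are additionally checked against their
#' CRC-32, which can break the tie.
#'
#' @param dr a `decode_result` whose file is a candidate ZIP
#' @return list with `error_matrix`, `pairs` (alternating candidates:
#'   byte positions of both copies plus the field name), `entries`,
#'   `n_local`, `n_central`, `eocd_ok`
#' @export
zip_analyze <- function(dr) {
  stopifnot(inherits(dr, "decode_result"))
  solution <- dr$solution
  cs <- ncol(solution)
  n_data <- dr$n_chunks - 1L
  bytes <- as.vector(t(solution[1L + seq_len(n_data), , drop = FALSE]))
  if (!is.null(dr$header))
    bytes <- bytes[seq_len((n_data - 1L) * cs + dr$header$last_chunk_length)]

  loc_pos <- find_signature(bytes, SIG_LOCAL)
  cen_pos <- find_signature(bytes, SIG_CENTRAL)
  eocd_pos <- find_signature(bytes, SIG_EOCD)
  if (length(loc_pos) + length(cen_pos) + length(eocd_pos) == 0)
    stop("not a ZIP: no signature found")

  em <- error_matrix(nrow(solution), cs)
  markf <- function(em, pos0, size, state, suggest = NULL) {
    em_mark_file_bytes(em, (pos0 + 1):(pos0 + size), state, suggest,
                       chunk_size = cs)
  }
  for (p in c(loc_pos, cen_pos, eocd_pos)) em <- markf(em, p - 1, 4, 0L)

  locals <- Filter(Negate(is.null), lapply(loc_pos, parse_local,
                                           bytes = bytes))
  centrals <- Filter(Negate(is.null), lapply(cen_pos, parse_central,
                                             bytes = bytes))
  # follow central offsets to locals the signature scan may have missed
  for (ce in centrals) {
    pos <- ce$local_offset + 1L
    if (!(ce$local_offset %in% vapply(locals, function(x) as.numeric(x$offset), numeric(1))) &&
        pos + 3 <= length(bytes) &&
        identical(bytes[pos:(pos + 3)], SIG_LOCAL)) {
      lh <- parse_local(bytes, pos)
      if (!is.null(lh)) locals[[length(locals) + 1]] <- lh
    }
  }
  if (length(locals) > 1)
    locals <- locals[order(vapply(locals, function(x) as.numeric(x$offset), numeric(1)))]

  pairs <- list()
  # payload CRC check per local entry
  for (lh in locals) {
    if (lh$csize == 0 || lh$data_start + lh$csize - 1 > length(bytes)) next
    payload <- bytes[lh$data_start:(lh$data_start + lh$csize - 1)]
    un <- if (lh$method == 0) payload
          else if (lh$method == 8) inflate_raw(payload)
          else NULL
    if (!is.null(un) && crc32(un) == lh$crc) {
      em <- markf(em, lh$data_start - 1, lh$csize, 0L)
      em <- markf(em, lh$offset + LOCAL_FIELD_POS$crc[1], 4, 0L)
    }
  }

  # local <-> central cross-checks
  match_central <- function(lh, i) {
    off <- vapply(centrals, function(x) as.numeric(x$local_offset), numeric(1))
    hit <- which(off == lh$offset)
    if (length(hit) == 1) return(centrals[[hit]])
    if (i <= length(centrals)) return(centrals[[i]])
    NULL
  }
  for (i in seq_along(locals)) {
    lh <- locals[[i]]
    ce <- match_central(lh, i)
    if (is.null(ce)) next
    for (f in names(LOCAL_FIELD_POS)) {
      lp <- LOCAL_FIELD_POS[[f]]; cp <- CENTRAL_FIELD_POS[[f]]
      l_bytes <- (lh$offset + lp[1] + 1):(lh$offset + lp[1] + lp[2])
      c_bytes <- (ce$offset + cp[1] + 1):(ce$offset + cp[1] + cp[2])
      if (identical(lh[[f]], ce[[f]])) {
        em <- em_mark_file_bytes(em, c(l_bytes, c_bytes), 0L,
                                 chunk_size = cs)
      } else {
        diff_b <- which(bytes[l_bytes] != bytes[c_bytes])
        pairs[[length(pairs) + 1]] <-
          list(field = f, entry = i, local_bytes = l_bytes[diff_b],
               central_bytes = c_bytes[diff_b])
      }
    }
    # filenames
    lnm <- lh$name; cnm <- ce$name
    l_bytes <- lh$offset + 30 + seq_len(lh$fnlen)
    c_bytes <- ce$offset + 46 + seq_len(ce$fnlen)
    if (lh$fnlen == ce$fnlen && lh$fnlen > 0) {
      if (identical(lnm, cnm)) {
        em <- em_mark_file_bytes(em, c(l_bytes, c_bytes), 0L,
                                 chunk_size = cs)
      } else {
        diff_b <- which(lnm != cnm)
        pairs[[length(pairs) + 1]] <-
          list(field = "filename", entry = i,
               local_bytes = l_bytes[diff_b],
               central_bytes = c_bytes[diff_b])
      }
    }
  }

  eocd_ok <- FALSE
  if (length(eocd_pos) >= 1) {
    p <- eocd_pos[length(eocd_pos)]
    if (p + 21 <= length(bytes)) {
      nrec <- bytes_le_to_u16(bytes[(p + 10):(p + 11)])
      eocd_ok <- nrec == length(centrals)
    }
  }
  list(error_matrix = em, pairs = pairs, entries = locals,
       centrals = centrals, n_local = length(locals),
       n_central = length(centrals), eocd_ok = eocd_ok,
       bytes = bytes, chunk_size = cs)
}

byte_to_cell <- function(byte_pos, chunk_size) {
  cbind(row = 1L + ((byte_pos - 1L) %/% chunk_size) + 1L,
        col = ((byte_pos - 1L) %% chunk_size) + 1L)
}

#' Localize a corrupted packet from ZIP cross-check columns
#'
#' Classifies decoded rows using only the columns where the archive
#' analysis found information: a row is valid if every inspected cell is 0
#' and invalid if any is 1.  Alternating candidate pairs (local vs central
#' copy) are resolved by trying both assignments and keeping those whose
#' correct/incorrect partition is consistent with a common corrupted
#' packet; a tie is reported as ambiguous rather than silently picked.
#'
#' @param dr a `decode_result`
#' @param za result of [zip_analyze()]
#' @param columns columns to restrict to (default: all columns carrying
#'   pair or invalid cells; falls back to all informative columns)
#' @return list with `tags`, `candidates` (packet indices), `ambiguous`,
#'   `assignment` (chosen side per pair: "local" or "central")
#' @export
zip_column_localize <- function(dr, za, columns = NULL) {
  cs <- za$chunk_size
  pairs <- za$pairs
  pair_cells <- lapply(pairs, function(p) {
    rbind(byte_to_cell(p$local_bytes, cs), byte_to_cell(p$central_bytes, cs))
  })
  if (is.null(columns)) {
    columns <- sort(unique(c(
      unlist(lapply(pair_cells, function(m) m[, "col"])),
      which(apply(za$error_matrix$states == 1L, 2, any)))))
  }
  if (length(columns) == 0) stop("insufficient information: no columns")
  solved_rows <- which(dr$system$solved_mask[seq_len(dr$n_chunks)])

  if (length(pairs) > 6) {
    # too many pairs for joint enumeration: resolve each pair on its own
    # (both sides tried with the others ignored), then evaluate the
    # combined assignment once
    sides <- integer(length(pairs))
    for (q in seq_along(pairs)) {
      ok_side <- logical(2)
      for (side in 1:2) {
        zaq <- za
        zaq$pairs <- pairs[q]
        res_q <- zip_column_localize(dr, zaq, columns)
        ok_side[side] <- length(res_q$candidates) > 0 && !res_q$ambiguous
        if (ok_side[side] && sides[q] == 0L) sides[q] <- side
        if (side == 1 && ok_side[1]) break  # prefer the first viable side
      }
      if (sides[q] == 0L) sides[q] <- 1L
    }
    assignments <- as.data.frame(as.list(sides))
  } else {
    assignments <- if (length(pairs) == 0) list(integer(0)) else
      do.call(expand.grid, rep(list(c(1L, 2L)), length(pairs)))
  }
  results <- list()
  n_assign <- if (length(pairs) == 0) 1 else nrow(assignments)
  for (a in seq_len(n_assign)) {
    em <- za$error_matrix
    choice <- character(0)
    if (length(pairs) > 0) {
      for (q in seq_along(pairs)) {
        side <- assignments[a, q]
        bad <- if (side == 1L) pairs[[q]]$local_bytes
               else pairs[[q]]$central_bytes
        good <- if (side == 1L) pairs[[q]]$central_bytes
                else pairs[[q]]$local_bytes
        em <- em_mark_file_bytes(em, bad, 1L, chunk_size = cs)
        em <- em_mark_file_bytes(em, good, 0L, chunk_size = cs)
        choice <- c(choice, c("local", "central")[side])
      }
    }
    tags <- tryCatch(
      error_matrix_tags(em, columns, rows = solved_rows),
      error = function(e) NULL)
    if (is.null(tags) || length(tags$incorrect) == 0) next
    cand <- tryCatch(localize_from_tags(dr$system, tags),
                     error = function(e) integer(0))
    if (length(cand) == 0) next
    # column-consistency filter: a corrupted packet hits the same columns
    # in every affected row, so a candidate whose affected rows carry
    # byte-level valid evidence in the implied delta columns is impossible
    inv_cells <- which(em$states == 1L, arr.ind = TRUE)
    delta_cols <- unique(inv_cells[, 2])
    tracker <- dr$system$tracker[seq_len(dr$n_chunks), , drop = FALSE]
    ok_cand <- vapply(cand, function(p) {
      rows_p <- intersect(which(tracker[, p] == 1L), solved_rows)
      base_valid <- za$error_matrix$states[rows_p, delta_cols,
                                           drop = FALSE] == 0L
      # invalid rows must be affected by p
      inv_rows <- unique(inv_cells[, 1])
      if (!all(inv_rows %in% rows_p)) return(FALSE)
      !any(base_valid)
    }, logical(1))
    cand <- cand[ok_cand]
    if (length(cand) >= 1)
      results[[length(results) + 1]] <-
        list(tags = tags, candidates = cand, assignment = choice,
             n_tagged = length(tags$incorrect) + length(tags$correct))
  }
  if (length(results) == 0)
    return(list(tags = NULL, candidates = integer(0), ambiguous = FALSE,
                assignment = NULL))
  cand_sets <- unique(lapply(results, `[[`, "candidates"))
  if (length(cand_sets) > 1) {
    return(list(tags = NULL,
                candidates = sort(unique(unlist(cand_sets))),
                ambiguous = TRUE,
                assignment = lapply(results, `[[`, "assignment")))
  }
  best <- results[[which.max(vapply(results, `[[`, integer(1), "n_tagged"))]]
  list(tags = best$tags, candidates = best$candidates, ambiguous = FALSE,
       assignment = best$assignment)
}

#' Strictly validate a ZIP archive
#'
#' `TRUE` iff at least one entry exists, every entry payload matches its
#' CRC-32, all duplicated local/central fields (including filenames) agree,
#' and the end-of-central-directory record count matches.
#'
#' @param bytes raw vector (candidate archive)
#' @return logical
#' @export
zip_validate <- function(bytes) {
  loc_pos <- find_signature(bytes, SIG_LOCAL)
  cen_pos <- find_signature(bytes, SIG_CENTRAL)
  eocd_pos <- find_signature(bytes, SIG_EOCD)
  if (length(loc_pos) == 0 || length(eocd_pos) == 0) return(FALSE)
  locals <- Filter(Negate(is.null), lapply(loc_pos, parse_local,
                                           bytes = bytes))
  centrals <- Filter(Negate(is.null), lapply(cen_pos, parse_central,
                                             bytes = bytes))
  if (length(locals) == 0 || length(locals) != length(centrals))
    return(FALSE)
  for (i in seq_along(locals)) {
    lh <- locals[[i]]; ce <- centrals[[i]]
    for (f in c(names(LOCAL_FIELD_POS), "name")) {
      if (!identical(lh[[f]], ce[[f]])) return(FALSE)
    }
    if (lh$data_start + lh$csize - 1 > length(bytes)) return(FALSE)
    payload <- if (lh$csize > 0)
      bytes[lh$data_start:(lh$data_start + lh$csize - 1)] else raw(0)
    un <- if (lh$method == 0) payload
          else if (lh$method == 8) inflate_raw(payload)
          else NULL
    if (is.null(un) || crc32(un) != lh$crc) return(FALSE)
  }
  p <- eocd_pos[length(eocd_pos)]
  if (p + 21 > length(bytes)) return(FALSE)
  bytes_le_to_u16(bytes[(p + 10):(p + 11)]) == length(centrals)
}

#' Brute-force ZIP repair over candidate packets
#'
#' Applies a known error delta to each candidate packet in turn,
#' re-decodes, and keeps only the files whose full reparse (every entry
#' CRC-valid, all duplicated fields consistent) succeeds.
#'
#' @param dr a `decode_result`
#' @param beta candidate packet indices
#' @param delta raw error delta (chunk size bytes)
#' @param validator override validator, default [zip_validate()]
#' @return list with `files`, `packets` (candidate index per surviving
#'   file), `unique`, `noop` (`TRUE` when delta was all-zero)
#' @export
zip_bruteforce_repair <- function(dr, beta, delta, validator = zip_validate) {
  stopifnot(inherits(dr, "decode_result"))
  if (all(delta == as.raw(0)))
    return(list(files = list(dr$file), packets = NA_integer_,
                unique = TRUE, noop = TRUE))
  files <- list(); packs <- integer(0)
  for (idx in beta) {
    dr2 <- redecode_with_fix(dr, idx, delta)
    if (dr2$status != "solved" || is.null(dr2$file)) next
    if (isTRUE(validator(dr2$file))) {
      is_new <- !any(vapply(files, identical, logical(1), y = dr2$file))
      if (is_new) {
        files[[length(files) + 1]] <- dr2$file
        packs <- c(packs, idx)
      }
    }
  }
  list(files = files, packets = packs, unique = length(files) == 1,
       noop = FALSE)
}
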