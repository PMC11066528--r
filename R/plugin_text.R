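# Plain-text content plugin: a pluggable corrector proposes an equal-length
# corrected version of each decoded row; the per-column histogram of error
# deltas between decoded and corrected text separates the systematic
# column-aligned error of a corrupted packet from scattered false-positive
# corrections.

#' Dictionary-based reference corrector
#'
#' Replaces each alphabetic word by the equal-length dictionary word with
#' the smallest Hamming distance (case-insensitive); ties or distances
#' larger than `max_dist` keep the original word.  Output length always
#' equals input length, as required for fixed-size chunks.
#'
#' @param words character vector (the dictionary)
#' @param max_dist maximum Hamming distance still considered a correction
#' @return corrector object: list with `name` and `correct(text)`
#' @export
dictionary_corrector <- function(words, max_dist = 2) {
  words <- unique(tolower(words))
  by_len <- split(words, nchar(words))
  split_chars <- lapply(by_len, function(w)
    do.call(rbind, strsplit(w, "", fixed = TRUE)))
  correct_word <- function(w) {
    lw <- tolower(w)
    L <- nchar(w)
    pool <- by_len[[as.character(L)]]
    if (is.null(pool)) return(w)
    if (lw %in% pool) return(w)
    mat <- split_chars[[as.character(L)]]
    ch <- strsplit(lw, "", fixed = TRUE)[[1]]
    d <- rowSums(sweep(mat, 2, ch, FUN = "!="))
    dmin <- min(d)
    if (dmin > max_dist || sum(d == dmin) != 1) return(w)
    pool[which.min(d)]
  }
  correct <- function(text) {
    m <- gregexpr("[A-Za-z]+", text)[[1]]
    if (m[1] == -1) return(text)
    out <- text
    lens <- attr(m, "match.length")
    for (i in seq_along(m)) {
      w <- substr(text, m[i], m[i] + lens[i] - 1)
      cw <- correct_word(w)
      if (nchar(cw) != nchar(w)) cw <- w
      substr(out, m[i], m[i] + lens[i] - 1) <- cw
    }
    out
  }
  list(name = "dictionary", correct = correct)
}

row_to_text <- function(row) {
  # embedded NULs and non-ASCII bytes become SUB so the row stays printable
  row[row == as.raw(0)] <- as.raw(0x1a)
  row[as.integer(row) > 127L] <- as.raw(0x1a)
  rawToChar(row)
}

#' Column-delta analysis of decoded text rows
#'
#' Runs the corrector over every requested row, XORs the decoded and the
#' corrected bytes into a difference matrix, and histograms the non-zero
#' deltas per column.  A corrupted packet hits the same column(s) of every
#' affected row with the same delta, so the dominant per-column delta
#' stands out against scattered correction noise.
#'
#' @param solution raw matrix of decoded chunk rows
#' @param corrector a corrector (see [dictionary_corrector()])
#' @param rows rows to analyze (default all)
#' @return list with `error_matrix`, `histogram` (per column: table of
#'   delta byte -> count), `bdelta` (raw difference matrix), `corrected`
#' @export
text_error_histogram <- function(solution, corrector,
                                 rows = seq_len(nrow(solution))) {
  cs <- ncol(solution)
  corrected <- solution
  for (r in rows) {
    txt <- row_to_text(solution[r, ])
    fixed <- corrector$correct(txt)
    if (nchar(fixed) != nchar(txt))
      stop("corrector changed the text length")
    fb <- charToRaw(fixed)
    orig <- solution[r, ]
    tb <- charToRaw(txt)
    changed <- fb != tb
    new_row <- orig
    new_row[changed] <- fb[changed]
    corrected[r, ] <- new_row
  }
  bdelta <- matrix(as.raw(bitwXor(as.integer(solution),
                                  as.integer(corrected))),
                   nrow = nrow(solution))
  em <- error_matrix(nrow(solution), cs)
  for (r in rows) {
    nz <- bdelta[r, ] != as.raw(0)
    em$states[r, !nz] <- 0L
    em$states[r, nz] <- 1L
    em$suggestions[r, nz] <- as.integer(corrected[r, nz])
  }
  histogram <- lapply(seq_len(cs), function(j) {
    v <- as.integer(bdelta[rows, j])
    v <- v[v != 0]
    if (length(v) == 0) return(integer(0))
    sort(table(v), decreasing = TRUE)
  })
  list(error_matrix = em, histogram = histogram, bdelta = bdelta,
       corrected = corrected, rows = rows)
}

#' Pick the columns whose dominant delta exceeds a threshold
#' @param te result of [text_error_histogram()]
#' @param threshold minimum occurrence count of the dominant delta
#' @return integer vector of column indices, most affected first
#' @export
text_suspect_columns <- function(te, threshold) {
  tops <- vapply(te$histogram, function(h)
    if (length(h) == 0) 0L else as.integer(h[1]), integer(1))
  ord <- order(-tops)
  ord[tops[ord] >= threshold]
}

#' Tag rows from the dominant delta of one column
#'
#' Rows whose delta at `column` equals the dominant delta are tagged
#' incorrect.  In strict mode only rows with a zero delta at that column
#' are tagged correct; lenient mode tags all other rows correct.
#'
#' @param te result of [text_error_histogram()]
#' @param column column to use
#' @param threshold minimum count for the dominant delta
#' @param mode `"strict"` or `"lenient"`
#' @return list with `tags` (a [tag_set()]) and `delta` (dominant delta
#'   byte as raw)
#' @export
text_tag_rows <- function(te, column, threshold,
                          mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  h <- te$histogram[[column]]
  if (length(h) == 0 || h[1] < threshold)
    stop("below threshold: no dominant delta in this column")
  dom <- as.integer(names(h)[1])
  col_deltas <- as.integer(te$bdelta[te$rows, column])
  incorrect <- te$rows[col_deltas == dom]
  correct <- if (mode == "strict") te$rows[col_deltas == 0L]
             else setdiff(te$rows, incorrect)
  list(tags = tag_set(correct = correct, incorrect = incorrect),
       delta = as.raw(dom))
}

#' Localize a corrupted packet from a text column analysis
#'
#' Tags rows via [text_tag_rows()] and intersects their contribution sets.
#' Rows the corrector silently failed to fix carry a zero delta and can be
#' falsely tagged correct; when the strict tag set yields an empty
#' candidate set, the correct tags are therefore dropped and localization
#' retried on the incorrect tags alone.
#'
#' @param dr a `decode_result`
#' @param te result of [text_error_histogram()]
#' @param column suspect column (see [text_suspect_columns()])
#' @param threshold dominant-delta threshold
#' @return list with `candidates`, `delta` (full chunk-size delta) and
#'   `tags`
#' @export
text_localize <- function(dr, te, column, threshold) {
  tg <- text_tag_rows(te, column, threshold, mode = "strict")
  cand <- localize_from_tags(dr$system, tg$tags)
  if (length(cand) == 0) {
    tg$tags <- tag_set(incorrect = tg$tags$incorrect)
    cand <- localize_from_tags(dr$system, tg$tags)
  }
  delta <- raw(ncol(dr$solution))
  delta[column] <- tg$delta
  list(candidates = cand, delta = delta, tags = tg$tags)
}

#' Tag rows by comparing the decode against an uploaded partial repair
#'
#' Any file type: a user (or an external forensic tool) repairs parts of
#' the decoded file out-of-band and uploads the result; rows that differ
#' yield per-row deltas that the localization and propagation machinery can
#' exploit, repairing all remaining affected rows.
#'
#' @param dr a `decode_result`
#' @param uploaded raw vector, same length as the decoded file
#' @param partial when `TRUE` rows identical to the upload stay untagged
#'   (the upload is known to be incompletely repaired)
#' @return list with `tags` (a [tag_set()], data-chunk row indices) and
#'   `deltas` (list of `list(row, delta)` for differing rows)
#' @export
upload_diff <- function(dr, uploaded, partial = FALSE) {
  stopifnot(inherits(dr, "decode_result"), is.raw(uploaded))
  if (is.null(dr$file)) stop("decode result carries no assembled file")
  if (length(uploaded) != length(dr$file))
    stop("uploaded length differs from the decoded file length")
  cs <- ncol(dr$solution)
  n_data <- dr$n_chunks - 1L
  up_pad <- c(uploaded, raw(n_data * cs - length(uploaded)))
  up_chunks <- matrix(up_pad, nrow = n_data, ncol = cs, byrow = TRUE)
  incorrect <- integer(0)
  correct <- integer(0)
  deltas <- list()
  for (j in seq_len(n_data)) {
    row <- 1L + j
    cur <- dr$solution[row, ]
    d <- xor_raw(cur, up_chunks[j, ])
    if (any(d != as.raw(0))) {
      incorrect <- c(incorrect, row)
      deltas[[length(deltas) + 1]] <- list(row = row, delta = d)
    } else if (!partial) {
      correct <- c(correct, row)
    }
  }
  list(tags = tag_set(correct = correct, incorrect = incorrect),
       deltas = deltas)
}
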