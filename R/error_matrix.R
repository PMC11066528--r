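# Byte-granular error matrix shared by the content plugins.
#
# Cell states: -1 unknown, 0 valid, 1 invalid.  An invalid cell may carry a
# suggested corrected byte (0..255) in the parallel suggestion matrix; -1
# means no suggestion.

#' Create an all-unknown error matrix
#'
#' @param n_rows,row_len dimensions (decoded chunk rows x chunk size)
#' @return object of class `error_matrix` with `states` and `suggestions`
#' @export
error_matrix <- function(n_rows, row_len) {
  structure(list(
    states = matrix(-1L, nrow = n_rows, ncol = row_len),
    suggestions = matrix(-1L, nrow = n_rows, ncol = row_len)
  ), class = "error_matrix")
}

em_mark <- function(em, row, cols, state, suggest = NULL) {
  em$states[row, cols] <- state
  if (!is.null(suggest)) em$suggestions[row, cols] <- as.integer(suggest)
  em
}

# mark a run of FILE byte positions (1-based within the decoded file, i.e.
# after the header chunk) in the solution coordinate system
em_mark_file_bytes <- function(em, byte_pos, state, suggest = NULL,
                               chunk_size, header_rows = 1L) {
  rows <- header_rows + ((byte_pos - 1L) %/% chunk_size) + 1L
  cols <- ((byte_pos - 1L) %% chunk_size) + 1L
  for (i in seq_along(byte_pos)) {
    em$states[rows[i], cols[i]] <- state
    if (!is.null(suggest))
      em$suggestions[rows[i], cols[i]] <- as.integer(suggest[i])
  }
  em
}

#' @export
print.error_matrix <- function(x, ...) {
  n_inv <- sum(x$states == 1L)
  n_val <- sum(x$states == 0L)
  cat(sprintf("Error matrix %d x %d: %d invalid, %d valid, %d unknown\n",
              nrow(x$states), ncol(x$states), n_inv, n_val,
              sum(x$states == -1L)))
  invisible(x)
}

#' Derive row tags from an error matrix restricted to given columns
#'
#' A row is tagged correct if every inspected cell is valid, incorrect if
#' any inspected cell is invalid; rows with only unknown cells stay
#' untagged.
#'
#' @param em an [error_matrix()]
#' @param columns columns to inspect
#' @param rows rows to consider (default all)
#' @return a [tag_set()]
#' @export
error_matrix_tags <- function(em, columns, rows = seq_len(nrow(em$states))) {
  if (length(columns) == 0) stop("no columns to inspect")
  st <- em$states[rows, columns, drop = FALSE]
  incorrect <- rows[apply(st == 1L, 1, any)]
  correct <- rows[apply(st == 0L, 1, all)]
  tag_set(correct = setdiff(correct, incorrect), incorrect = incorrect)
}
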