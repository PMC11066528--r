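#' @useDynLib dnarescue, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif median quantile
#' @importFrom utils head read.delim write.table
NULL

# ---- bit-exact linear algebra over GF(2) with contribution tracking ----
#
# A "bit matrix" is a plain 0/1 integer matrix; "byte rows" are a raw matrix
# with one packet/chunk payload per row.  All indices at the R level are
# 1-based, following R convention.

#' XOR two equal-length raw vectors
#' @param a,b raw vectors of identical length
#' @return raw vector `a` XOR `b`
#' @export
xor_raw <- function(a, b) {
  stopifnot(is.raw(a), is.raw(b), length(a) == length(b))
  as.raw(bitwXor(as.integer(a), as.integer(b)))
}

as_bit_matrix <- function(A) {
  if (!is.matrix(A)) stop("expected a matrix")
  storage.mode(A) <- "integer"
  if (any(A != 0L & A != 1L)) stop("bit matrix entries must be 0 or 1")
  A
}

as_byte_rows <- function(b, n_rows = NULL) {
  if (is.list(b)) {
    lens <- lengths(b)
    if (length(unique(lens)) > 1L) stop("all byte rows must have equal length")
    b <- matrix(unlist(b, use.names = FALSE), nrow = length(b), byrow = TRUE)
    b <- matrix(as.raw(b), nrow = nrow(b))
  }
  if (!is.matrix(b) || !is.raw(b)) stop("expected a raw matrix or list of raw vectors")
  if (!is.null(n_rows) && nrow(b) != n_rows) stop("byte row count mismatch")
  b
}

#' GF(2) rank of a bit matrix, optionally augmented with byte rows
#'
#' Computes the rank of `A` over GF(2).  When `b` is supplied, the bytes of
#' each row are appended as bit columns and the rank of the augmented matrix
#' `[A | b]` is returned, which is how system consistency is assessed
#' (Rouche-Capelli: a system is consistent iff the augmentation does not
#' raise the rank).
#'
#' @param A 0/1 integer matrix (packets x chunks)
#' @param b optional raw matrix of payloads, one row per row of `A`
#' @return integer rank
#' @export
gf2_rank <- function(A, b = NULL) {
  A <- as_bit_matrix(A)
  if (nrow(A) == 0L || ncol(A) == 0L) stop("empty matrix has no defined rank here")
  if (is.null(b)) return(.gf2_rank_cpp(A))
  b <- as_byte_rows(b, nrow(A))
  .gf2_ranks_cpp(A, b)[2L]
}

#' Is the packet system consistent?
#'
#' `TRUE` iff `rank(A) == rank([A|b])`.  A corrupted non-critical packet
#' raises the augmented rank and renders the system inconsistent, which is
#' the signal the automatic repair methods exploit.
#'
#' @inheritParams gf2_rank
#' @return logical scalar
#' @export
is_consistent <- function(A, b) {
  A <- as_bit_matrix(A)
  b <- as_byte_rows(b, nrow(A))
  r <- .gf2_ranks_cpp(A, b)
  r[1L] == r[2L]
}

new_tracked_system <- function(A, b, res, row_order, mode) {
  structure(
    list(
      A = A, b = b,
      reduced_A = res$reduced_A,
      reduced_b = res$reduced_b,
      tracker = res$tracker,
      solved_mask = as.logical(res$solved_mask),
      row_order = row_order,
      mode = mode
    ),
    class = "tracked_system"
  )
}

#' Tracked Gaussian elimination of a packet system
#'
#' Reduces `[A | I | b]` to reduced row echelon form over the chunk columns
#' of `A`, carrying an identity block (the accumulated left-inverse of `A`)
#' so that each output row records exactly which original packets were
#' XOR-combined to produce it.  For an inconsistent system the result
#' depends on `row_order`; the permutation-ensemble repair exploits exactly
#' this.
#'
#' @param A 0/1 integer matrix (M packets x N chunks)
#' @param b raw matrix of payloads (M x chunk_size)
#' @param row_order permutation of `1:nrow(A)` applied before elimination
#' @return object of class `tracked_system` with elements `reduced_A`,
#'   `reduced_b` (chunk row i in output row i; residual rows follow),
#'   `tracker` (rows x original packets), `solved_mask` (length N) and the
#'   inputs
#' @export
eliminate_tracked <- function(A, b, row_order = seq_len(nrow(A))) {
  A <- as_bit_matrix(A)
  b <- as_byte_rows(b, nrow(A))
  row_order <- as.integer(row_order)
  if (length(row_order) != nrow(A) ||
      !identical(sort(row_order), seq_len(nrow(A))))
    stop("row_order must be a permutation of 1:nrow(A)")
  res <- .gf2_eliminate_cpp(A, b, row_order - 1L, 0L)
  new_tracked_system(A, b, res, row_order, "full")
}

#' Partially solve an under-determined packet system
#'
#' Reduces only the solvable rows: columns for which no pivot exists are
#' skipped, and a chunk row counts as solved only if it ends with exactly
#' one 1, on the diagonal — which happens exactly for the chunks whose
#' value is derivable from the received rows.  Unsolved chunk rows are
#' returned as all-zero bytes so a partial file can still be assembled.
#'
#' @inheritParams eliminate_tracked
#' @return `tracked_system` (see [eliminate_tracked()])
#' @export
partial_eliminate <- function(A, b) {
  A <- as_bit_matrix(A)
  b <- as_byte_rows(b, nrow(A))
  res <- .gf2_eliminate_cpp(A, b, seq_len(nrow(A)) - 1L, 1L)
  new_tracked_system(A, b, res, seq_len(nrow(A)), "partial")
}

#' Contribution sets of solved chunk rows
#'
#' For each solved chunk row r, the set of original packet indices whose
#' XOR combination produced the decoded row (read off the tracked
#' left-inverse of `A`).  These sets drive corrupted-packet localization:
#' tagging decoded rows as correct/incorrect constrains which packets can be
#' at fault.
#'
#' @param t a `tracked_system`
#' @param rows chunk rows to query (default: all solved rows)
#' @return named list; element `"r"` is the sorted integer vector of packet
#'   indices contributing to chunk row r
#' @export
contribution_sets <- function(t, rows = which(t$solved_mask)) {
  stopifnot(inherits(t, "tracked_system"))
  rows <- as.integer(rows)
  if (any(!t$solved_mask[rows]))
    stop("unsolved row queried: contribution sets exist only for solved rows")
  out <- lapply(rows, function(r) which(t$tracker[r, ] == 1L))
  names(out) <- as.character(rows)
  out
}

#' @export
print.tracked_system <- function(x, ...) {
  n <- ncol(x$A)
  cat(sprintf(
    "Tracked GF(2) system: %d packets x %d chunks (%s elimination)\n",
    nrow(x$A), n, x$mode))
  cat(sprintf("  solved chunk rows: %d / %d\n", sum(x$solved_mask), n))
  resid <- nrow(x$reduced_b) - n
  if (resid > 0) {
    nz <- sum(vapply(seq_len(resid), function(i) {
      any(x$reduced_b[n + i, ] != as.raw(0))
    }, logical(1)))
    cat(sprintf("  residual rows: %d (%d with non-zero payload%s)\n",
                resid, nz,
                if (nz > 0) " -> system inconsistent" else ""))
  }
  invisible(x)
}

# residual rows with zero A-part but non-zero payload witness inconsistency
has_inconsistent_residual <- function(t) {
  n <- ncol(t$A)
  total <- nrow(t$reduced_b)
  if (total <= n) return(FALSE)
  for (i in (n + 1L):total) {
    if (all(t$reduced_A[i, ] == 0L) && any(t$reduced_b[i, ] != as.raw(0)))
      return(TRUE)
  }
  FALSE
}
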