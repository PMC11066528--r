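# Independent oracles and fixture builders.  The oracles deliberately use
# plain-R algorithms separate from the package's compiled kernels.

# GF(2) rank by naive R row reduction over a 0/1 matrix
brute_rank <- function(A) {
  A <- as.matrix(A) %% 2
  r <- 0
  for (col in seq_len(ncol(A))) {
    piv <- which(A[, col] == 1 & seq_len(nrow(A)) > r)
    if (length(piv) == 0) next
    r <- r + 1
    A[c(r, piv[1]), ] <- A[c(piv[1], r), ]
    for (i in seq_len(nrow(A))) {
      if (i != r && A[i, col] == 1) A[i, ] <- (A[i, ] + A[r, ]) %% 2
    }
  }
  r
}

# append byte rows as bit columns (LSB-first; any consistent order works
# for rank purposes)
augment_bits <- function(A, b) {
  bits <- t(apply(b, 1, function(row) {
    as.integer(rawToBits(row))
  }))
  cbind(A, bits)
}

# delete-one-row criticality oracle: row i non-critical iff the rank is
# unchanged after removing it
criticality_oracle <- function(A) {
  r <- brute_rank(A)
  vapply(seq_len(nrow(A)), function(i) {
    brute_rank(A[-i, , drop = FALSE]) == r
  }, logical(1))
}

# random sparse 0/1 system with full column rank and byte payloads derived
# from a random ground-truth solution
random_system <- function(M, N, L, density = 0.35, seed = 1) {
  set.seed(seed)
  repeat {
    A <- matrix(rbinom(M * N, 1, density), M, N)
    empty <- rowSums(A) == 0
    A[empty, sample(N, sum(empty), replace = TRUE)] <- 1
    if (brute_rank(A) == N) break
  }
  storage.mode(A) <- "integer"
  truth <- matrix(as.raw(sample(0:255, N * L, replace = TRUE)), N, L)
  b <- matrix(as.raw(0), M, L)
  for (i in seq_len(M)) {
    acc <- raw(L)
    for (j in which(A[i, ] == 1)) acc <- xor_raw(acc, truth[j, ])
    b[i, ] <- acc
  }
  list(A = A, b = b, truth = truth)
}

# encode a file and keep resampling seeds until the packet set decodes
encode_solved <- function(data, cfg, filename = "data.bin", first_seed = 1) {
  pk <- encode(data, cfg, filename = filename, first_seed = first_seed,
               ensure_decodable = TRUE)
  dr <- decode(pk)
  stopifnot(dr$status == "solved")
  list(pk = pk, dr = dr)
}

# corrupt packet `victim` of a solved decode by `delta`; returns the
# re-decoded (inconsistent/partial) result
inject_error <- function(dr, victim, delta) {
  b2 <- dr$b
  b2[victim, ] <- xor_raw(b2[victim, ], delta)
  dnarescue:::decode_system(dr$A, b2, dr$n_chunks, dr$n_padding, dr$config)
}

random_delta <- function(len, nnz = NULL) {
  d <- raw(len)
  if (is.null(nnz)) {
    d <- as.raw(sample(0:255, len, replace = TRUE))
    if (all(d == 0)) d[1] <- as.raw(1)
  } else {
    d[sample(len, nnz)] <- as.raw(sample(1:255, nnz, replace = TRUE))
  }
  d
}

# encode `data` and delete every packet covering `chunk`, retrying seed
# ranges until exactly that chunk is left unsolved (a clean knockout)
make_missing_chunk_case <- function(data, cfg, chunk = 2,
                                    filename = "tale.txt", tries = 25) {
  for (t in seq_len(tries)) {
    pk <- encode(data, cfg, filename = filename, first_seed = t * 5501,
                 ensure_decodable = TRUE)
    dr0 <- decode(pk)
    covering <- which(dr0$A[, chunk] == 1)
    if (length(covering) == 0 || length(covering) >= nrow(dr0$A)) next
    dru <- dnarescue:::decode_system(
      dr0$A[-covering, , drop = FALSE], dr0$b[-covering, , drop = FALSE],
      dr0$n_chunks, 0, cfg)
    unsolved <- which(!dru$system$solved_mask[seq_len(dr0$n_chunks)])
    if (identical(unsolved, as.integer(chunk))) {
      return(list(dr0 = dr0, dru = dru))
    }
  }
  stop("no clean knockout found")
}

# bit-string helpers for the worked 4x3 example
bits_row <- function(s) as.raw(as.integer(strsplit(s, "")[[1]]))
row_string <- function(r) paste(as.integer(r), collapse = "")

example1 <- function() {
  A <- rbind(c(1L, 0L, 0L), c(0L, 1L, 1L), c(0L, 0L, 1L), c(0L, 1L, 0L))
  b <- rbind(bits_row("110001"), bits_row("011110"),
             bits_row("001011"), bits_row("010110"))
  list(A = A, b = b)
}
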