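# Seed -> chunk-selection machinery.
#
# The packet seed drives a small, versioned linear congruential generator
# (Numerical Recipes 32-bit constants) so that encoder and decoder agree
# bit-exactly across runs and platforms; the platform RNG is never used
# here.  The same stream first draws the packet degree from the configured
# distribution, then draws distinct chunk indices uniformly.

lcg_next <- function(state) {
  # exact in doubles: 1664525 * 2^32 < 2^53
  (1664525 * state + 1013904223) %% 4294967296
}

# (a * b) mod 2^32, exact in doubles via 16-bit split
mul32 <- function(a, b) {
  hi <- a %/% 65536
  lo <- a %% 65536
  (((hi * b) %% 65536) * 65536 + lo * b) %% 4294967296
}

xor32 <- function(a, b) {
  # bitwXor is limited to signed 32-bit; split into 16-bit halves
  hi <- bitwXor(a %/% 65536, b %/% 65536)
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi * 65536 + lo
}

# murmur3 finalizer: decorrelates streams seeded with sequential seeds
mix32 <- function(h) {
  h <- h %% 4294967296
  h <- xor32(h, h %/% 65536)
  h <- mul32(h, 2246822507)   # 0x85ebca6b
  h <- xor32(h, h %/% 8192)
  h <- mul32(h, 3266489909)   # 0xc2b2ae35
  xor32(h, h %/% 65536)
}

#' Degree distributions for the fountain code
#'
#' Two named options are shipped:
#' * `"raptor"`: the RFC 5053 Raptor degree table (degrees 1, 2, 3, 4, 10,
#'   11, 40), the distribution family the reference DNA-storage encoders
#'   use;
#' * `"robust_soliton"`: the classic LT robust soliton with parameters `c`
#'   and `delta`.
#'
#' @param name `"raptor"` or `"robust_soliton"`
#' @param c,delta robust soliton parameters (ignored for `"raptor"`)
#' @return object of class `degree_distribution` holding the degree table
#'   and its probabilities
#' @export
degree_distribution <- function(name = c("raptor", "robust_soliton"),
                                c = 0.1, delta = 0.05) {
  name <- match.arg(name)
  if (name == "raptor") {
    degrees <- c(1L, 2L, 3L, 4L, 10L, 11L, 40L)
    f <- c(10241, 491582, 712794, 831695, 948446, 1032189, 1048576)
    probs <- diff(c(0, f)) / 1048576
    params <- list()
  } else {
    params <- list(c = c, delta = delta)
    degrees <- NULL  # depends on n_chunks; resolved in degree_table()
    probs <- NULL
  }
  structure(list(name = name, degrees = degrees, probs = probs,
                 params = params),
            class = "degree_distribution")
}

# resolve the (degree, prob) table for a given chunk count
degree_table <- function(dist, n_chunks) {
  stopifnot(inherits(dist, "degree_distribution"))
  if (dist$name == "raptor") {
    keep <- dist$degrees <= n_chunks
    if (!any(keep)) keep[1] <- TRUE
    degrees <- pmin(dist$degrees[keep], n_chunks)
    probs <- dist$probs[keep]
    # mass of truncated tail goes to the largest retained degree
    probs[length(probs)] <- probs[length(probs)] + sum(dist$probs[!keep])
  } else {
    k <- n_chunks
    cc <- dist$params$c
    delta <- dist$params$delta
    R <- cc * log(k / delta) * sqrt(k)
    rho <- c(1 / k, 1 / ((2:k) * (1:(k - 1))))
    tau <- numeric(k)
    kr <- max(1L, min(k, floor(k / R)))
    if (kr > 1) tau[1:(kr - 1)] <- R / ((1:(kr - 1)) * k)
    tau[kr] <- R * log(R / delta) / k
    probs <- (rho + tau) / sum(rho + tau)
    degrees <- seq_len(k)
    keep <- probs > 0
    degrees <- degrees[keep]
    probs <- probs[keep]
  }
  list(degrees = as.integer(degrees), probs = probs, cdf = cumsum(probs))
}

#' Chunk-index set selected by a packet seed
#'
#' Deterministically expands a packet seed into the set of chunk indices
#' XORed into that packet.  Encoder and decoder call this with the same
#' distribution and chunk count, so the seed alone carries the packet's
#' structure.
#'
#' @param seed non-negative integer (interpreted modulo 2^32)
#' @param n_chunks number of chunks (columns of the system)
#' @param dist a [degree_distribution()]
#' @return sorted integer vector of chunk indices (1-based)
#' @export
chunks_from_seed <- function(seed, n_chunks, dist) {
  tab <- degree_table(dist, n_chunks)
  .seed_chunks_cpp(seed %% 4294967296, as.integer(n_chunks),
                   tab$cdf, tab$degrees) + 1L
}

# pure-R reference used as an independent oracle in the tests
chunks_from_seed_ref <- function(seed, n_chunks, dist) {
  tab <- degree_table(dist, n_chunks)
  s <- lcg_next(mix32(seed %% 4294967296))
  u <- s / 4294967296
  deg <- tab$degrees[length(tab$degrees)]
  for (k in seq_along(tab$cdf)) {
    if (u < tab$cdf[k]) { deg <- tab$degrees[k]; break }
  }
  deg <- max(1L, min(deg, n_chunks))
  picked <- integer(0)
  while (length(picked) < deg) {
    s <- lcg_next(s)
    idx <- floor((s / 4294967296) * n_chunks) + 1
    idx <- min(idx, n_chunks)
    if (!(idx %in% picked)) picked <- c(picked, idx)
  }
  sort(as.integer(picked))
}
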