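# Reed-Solomon over GF(256), primitive polynomial 0x11D, generator alpha=2,
# first consecutive root alpha^0.  Classic syndrome decoding
# (Berlekamp-Massey + Chien search + Forney) correcting up to n_sym/2 byte
# errors per block.  No pre-installed R package provides an RS codec, so
# this is implemented here; it follows the textbook construction used by
# the common Python codecs.

gf256_tables <- local({
  exp <- integer(512)
  log <- integer(256)
  x <- 1L
  for (i in 0:254) {
    exp[i + 1] <- x
    log[x + 1] <- i
    x <- bitwShiftL(x, 1L)
    if (x >= 256L) x <- bitwAnd(bitwXor(x, 0x11DL), 255L)
  }
  for (i in 255:511) exp[i + 1] <- exp[i - 255 + 1]
  list(exp = exp, log = log)
})

gf_mul <- function(a, b) {
  if (a == 0L || b == 0L) return(0L)
  t <- gf256_tables
  t$exp[((t$log[a + 1] + t$log[b + 1]) %% 255) + 1]
}

gf_div <- function(a, b) {
  if (b == 0L) stop("division by zero in GF(256)")
  if (a == 0L) return(0L)
  t <- gf256_tables
  t$exp[((t$log[a + 1] - t$log[b + 1] + 255) %% 255) + 1]
}

gf_pow <- function(a, p) {
  t <- gf256_tables
  if (a == 0L) return(if (p == 0) 1L else 0L)
  t$exp[(((t$log[a + 1] * p) %% 255 + 255) %% 255) + 1]
}

gf_inverse <- function(a) gf_div(1L, a)

# polynomial helpers; coefficients highest-order first, integer 0..255
gf_poly_mul <- function(p, q) {
  out <- integer(length(p) + length(q) - 1)
  for (i in seq_along(p)) {
    if (p[i] == 0L) next
    for (j in seq_along(q)) {
      if (q[j] == 0L) next
      out[i + j - 1] <- bitwXor(out[i + j - 1], gf_mul(p[i], q[j]))
    }
  }
  out
}

gf_poly_eval <- function(p, x) {
  y <- p[1]
  for (i in seq_along(p)[-1]) y <- bitwXor(gf_mul(y, x), p[i])
  y
}

rs_generator_poly <- function(n_sym) {
  g <- 1L
  for (i in 0:(n_sym - 1)) g <- gf_poly_mul(g, c(1L, gf_pow(2L, i)))
  g
}

#' Append Reed-Solomon parity symbols to a payload
#'
#' @param payload raw vector (message), length + `n_sym` must be <= 255
#' @param n_sym number of parity bytes; the code corrects up to
#'   `floor(n_sym/2)` byte errors
#' @return raw vector `payload` followed by `n_sym` parity bytes
#' @export
rs_encode <- function(payload, n_sym) {
  stopifnot(is.raw(payload), n_sym >= 0)
  if (n_sym == 0) return(payload)
  if (length(payload) + n_sym > 255)
    stop("payload too long for a single RS(255) block")
  gen <- rs_generator_poly(n_sym)
  msg <- c(as.integer(payload), integer(n_sym))
  for (i in seq_len(length(payload))) {
    coef <- msg[i]
    if (coef != 0L) {
      for (j in seq_along(gen)[-1]) {
        msg[i + j - 1] <- bitwXor(msg[i + j - 1], gf_mul(gen[j], coef))
      }
    }
  }
  c(payload, as.raw(msg[(length(payload) + 1):length(msg)]))
}

rs_syndromes <- function(block, n_sym) {
  vapply(0:(n_sym - 1), function(i) gf_poly_eval(block, gf_pow(2L, i)),
         integer(1))
}

#' Check and correct a Reed-Solomon block
#'
#' @param block raw vector: payload followed by `n_sym` parity bytes
#' @param n_sym number of parity bytes used at encoding time
#' @return list with `payload` (raw, parity stripped), `status` one of
#'   `"ok"` (no errors), `"repaired"` (errors corrected), `"failed"`
#'   (uncorrectable; treat the packet as an erasure), and `n_corrected`
#' @export
rs_decode <- function(block, n_sym) {
  stopifnot(is.raw(block), n_sym >= 0)
  if (n_sym == 0)
    return(list(payload = block, status = "ok", n_corrected = 0L))
  if (length(block) > 255) stop("block too long for RS(255)")
  msg <- as.integer(block)
  synd <- rs_syndromes(msg, n_sym)
  strip <- function(m) as.raw(m[seq_len(length(m) - n_sym)])
  if (all(synd == 0L))
    return(list(payload = strip(msg), status = "ok", n_corrected = 0L))

  # Berlekamp-Massey for the error locator polynomial
  err_loc <- 1L
  old_loc <- 1L
  for (i in seq_len(n_sym)) {
    delta <- synd[i]
    if (length(err_loc) > 1) {
      for (j in 1:(length(err_loc) - 1)) {
        delta <- bitwXor(delta,
                         gf_mul(err_loc[length(err_loc) - j], synd[i - j]))
      }
    }
    old_loc <- c(old_loc, 0L)
    if (delta != 0L) {
      if (length(old_loc) > length(err_loc)) {
        new_loc <- vapply(old_loc, gf_mul, integer(1), b = delta)
        old_loc <- vapply(err_loc, gf_div, integer(1), b = delta)
        err_loc <- new_loc
      }
      pad <- length(err_loc) - length(old_loc)
      add <- c(integer(pad), vapply(old_loc, gf_mul, integer(1), b = delta))
      err_loc <- bitwXor(err_loc, add)
    }
  }
  while (length(err_loc) > 1 && err_loc[1] == 0L) err_loc <- err_loc[-1]
  n_errors <- length(err_loc) - 1
  if (n_errors * 2 > n_sym || n_errors == 0)
    return(list(payload = strip(msg), status = "failed", n_corrected = 0L))

  # Chien search for error positions (0-based positions in the block)
  n <- length(msg)
  pos <- integer(0)
  rev_loc <- rev(err_loc)  # roots of the reversed locator are the X_k
  for (i in 0:(n - 1)) {
    if (gf_poly_eval(rev_loc, gf_pow(2L, i)) == 0L) pos <- c(pos, n - 1 - i)
  }
  pos <- pos[pos >= 0 & pos < n]
  if (length(pos) != n_errors)
    return(list(payload = strip(msg), status = "failed", n_corrected = 0L))

  # Forney (first consecutive root alpha^0): with X_k = alpha^(n-1-pos_k),
  # Lambda(x) = prod_k (1 + X_k x) and Omega = S * Lambda mod x^nsym
  # (low-order first), the magnitude is
  # e_k = Omega(X_k^-1) / prod_{j != k} (1 + X_j X_k^-1).
  X <- vapply(n - 1 - pos, function(cp) gf_pow(2L, cp), integer(1))
  lam_low <- 1L
  for (xk in X) lam_low <- gf_poly_mul(lam_low, c(1L, xk))
  omega_low <- gf_poly_mul(synd, lam_low)[seq_len(n_sym)]
  for (k in seq_along(pos)) {
    xi_inv <- gf_inverse(X[k])
    loc_prime <- 1L
    for (j in seq_along(X)) {
      if (j != k)
        loc_prime <- gf_mul(loc_prime,
                            bitwXor(1L, gf_mul(xi_inv, X[j])))
    }
    if (loc_prime == 0L)
      return(list(payload = strip(msg), status = "failed", n_corrected = 0L))
    magnitude <- gf_div(gf_poly_eval(rev(omega_low), xi_inv), loc_prime)
    msg[pos[k] + 1] <- bitwXor(msg[pos[k] + 1], magnitude)
  }
  if (any(rs_syndromes(msg, n_sym) != 0L))
    return(list(payload = strip(msg), status = "failed", n_corrected = 0L))
  list(payload = strip(msg), status = "repaired",
       n_corrected = length(pos))
}
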