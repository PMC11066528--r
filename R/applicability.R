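# Applicability analyses: information density, criticality vs. overhead,
# and tagging requirements.

#' Per-strand information density
#'
#' Fraction of a DNA strand of `strand_len_nt` nucleotides that carries
#' payload, after subtracting the seed and optional error-correction
#' symbols: `(n - (s + e)) / n`.
#'
#' @param strand_len_nt strand length n in nt
#' @param seed_len_nt seed length s in nt (4 nt per seed byte)
#' @param ecc_len_nt error-correction length e in nt
#' @return fraction in (0, 1]
#' @export
per_strand_density <- function(strand_len_nt, seed_len_nt = 16,
                               ecc_len_nt = 0) {
  if (seed_len_nt + ecc_len_nt >= strand_len_nt)
    stop("seed + ECC cannot fill the whole strand")
  (strand_len_nt - (seed_len_nt + ecc_len_nt)) / strand_len_nt
}

#' Effective information density of an encoded file
#'
#' Accounts for the fixed packet overhead on top of the per-strand
#' density: with payload bytes `(n - s - e)/4` per strand and
#' `ceiling(file_size / payload)` chunks, the density is
#' `n_chunks * (n - s - e) / ((n_chunks + overhead) * n)`.
#' File sizes use decimal units (1 kB = 1000 bytes).
#'
#' @param file_size_bytes file size in bytes
#' @param strand_len_nt strand length in nt
#' @param seed_len_nt seed length in nt
#' @param ecc_len_nt error-correction length in nt
#' @param overhead_packets fixed packet overhead
#' @return fraction in (0, 1]
#' @export
effective_density <- function(file_size_bytes, strand_len_nt = 300,
                              seed_len_nt = 16, ecc_len_nt = 0,
                              overhead_packets = 16) {
  payload_nt <- strand_len_nt - seed_len_nt - ecc_len_nt
  if (payload_nt <= 0) stop("seed + ECC cannot fill the whole strand")
  if (payload_nt %% 4 != 0)
    stop("payload must be a whole number of bytes (multiple of 4 nt)")
  payload_bytes <- payload_nt / 4
  n_chunks <- ceiling(file_size_bytes / payload_bytes)
  n_chunks * payload_nt / ((n_chunks + overhead_packets) * strand_len_nt)
}

#' Non-critical packet counts across overheads
#'
#' For each overhead and repeat: encode the file with a fresh seed range,
#' then count the packets whose removal still leaves the file decodable
#' (equivalently, packets participating in a linear dependency of the
#' received system).  Rank-deficient ("degenerate") encodings contribute
#' zero non-critical packets unless excluded.
#'
#' @param data raw vector (the file)
#' @param n_chunks_target total chunk count (header + data); the chunk
#'   size is derived from it
#' @param overheads integer vector of packet overheads to sweep
#' @param repeats encodings per overhead
#' @param rng_seed seed controlling the per-repeat encoder seed ranges
#' @param distribution a [degree_distribution()]
#' @param exclude_degenerate resample rank-deficient encodings
#' @return data.frame with one row per (overhead, repeat): `n_packets`,
#'   `n_noncritical`, `frac`, `decodable`
#' @export
noncritical_curve <- function(data, n_chunks_target, overheads,
                              repeats = 20, rng_seed = 1,
                              distribution = degree_distribution("raptor"),
                              exclude_degenerate = FALSE) {
  stopifnot(repeats >= 1)
  chunk_size <- ceiling(length(data) / (n_chunks_target - 1L))
  cfg0 <- encoder_config(chunk_size = chunk_size,
                         distribution = distribution, with_crc = FALSE)
  first_seeds <- with_local_seed(rng_seed, {
    matrix(sample.int(2^30, length(overheads) * repeats),
           nrow = length(overheads))
  })
  out <- list()
  for (oi in seq_along(overheads)) {
    ov <- overheads[oi]
    for (r in seq_len(repeats)) {
      cfg <- cfg0
      cfg$overhead <- ov
      pk <- encode(data, cfg, first_seed = first_seeds[oi, r],
                   ensure_decodable = exclude_degenerate)
      sys <- packets_to_system(pk$packets, pk$n_chunks, 0L, cfg)
      decodable <- gf2_rank(sys$A) == ncol(sys$A)
      n_nc <- if (decodable) sum(classify_criticality(sys$A)) else 0L
      out[[length(out) + 1]] <- data.frame(
        overhead = ov, rep = r, n_packets = nrow(sys$A),
        n_noncritical = n_nc, frac = n_nc / nrow(sys$A),
        decodable = decodable)
    }
  }
  do.call(rbind, out)
}

#' Candidate-set sizes under randomized row tagging
#'
#' For each designated corrupted packet and each (valid, invalid)
#' tag-count combination, samples truthful tags from the ground truth and
#' records the size of the candidate set returned by
#' [localize_from_tags()].
#'
#' @param dr a solved `decode_result` (the system to tag)
#' @param valid_counts,invalid_counts tag-count grids
#' @param repeats random tag draws per combination
#' @param rng_seed seed
#' @param packets packets to designate as corrupted (default: all)
#' @return data.frame: `packet`, `n_valid`, `n_invalid`, `rep`,
#'   `n_candidates`, `contains_truth`
#' @export
tagging_curve <- function(dr, valid_counts = 0:5, invalid_counts = 0:5,
                          repeats = 10, rng_seed = 1,
                          packets = seq_len(nrow(dr$A))) {
  stopifnot(inherits(dr, "decode_result"))
  N <- dr$n_chunks
  tracker <- dr$system$tracker[seq_len(N), , drop = FALSE]
  solved <- which(dr$system$solved_mask[seq_len(N)])
  out <- vector("list", 0)
  with_local_seed(rng_seed, {
    for (p in packets) {
      affected <- intersect(which(tracker[, p] == 1L), solved)
      clean <- setdiff(solved, affected)
      for (v in valid_counts) for (iv in invalid_counts) {
        for (r in seq_len(repeats)) {
          inc <- if (iv > 0) sample(affected, min(iv, length(affected)))
                 else integer(0)
          cor <- if (v > 0) sample(clean, min(v, length(clean)))
                 else integer(0)
          if (length(inc) == 0) {
            # no invalid tags: candidate set cannot be formed (single mode)
            out[[length(out) + 1]] <- data.frame(
              packet = p, n_valid = v, n_invalid = iv, rep = r,
              n_candidates = NA_integer_, contains_truth = NA)
            next
          }
          cand <- localize_from_tags(
            dr$system, tag_set(correct = cor, incorrect = inc))
          out[[length(out) + 1]] <- data.frame(
            packet = p, n_valid = v, n_invalid = iv, rep = r,
            n_candidates = length(cand), contains_truth = p %in% cand)
        }
      }
    }
  })
  do.call(rbind, out)
}

#' Minimal combined tag count isolating each corrupted packet
#'
#' For each designated packet, draws truthful tags one at a time —
#' alternating at random between the pool of affected rows (tagged
#' invalid) and unaffected rows (tagged valid) — until the candidate set
#' returned by the tag localization is a singleton, and records the
#' combined number of tags needed.  Packets that contributed to no solved
#' row (pure redundancy rows) are skipped: an error in them never reaches
#' the decoded data, and no row tag can refer to them.
#'
#' @param dr a solved `decode_result`
#' @param repeats random tag orders per packet
#' @param rng_seed seed
#' @param packets packets to designate as corrupted (default: all packets
#'   used in at least one solved row)
#' @param max_tags cap per run (`NA` recorded when reached)
#' @return data.frame: `packet`, `rep`, `n_tags`
#' @export
min_tags_to_singleton <- function(dr, repeats = 5, rng_seed = 1,
                                  packets = NULL, max_tags = 100) {
  stopifnot(inherits(dr, "decode_result"))
  N <- dr$n_chunks
  M <- nrow(dr$A)
  tracker <- dr$system$tracker[seq_len(N), , drop = FALSE]
  solved <- which(dr$system$solved_mask[seq_len(N)])
  used <- which(colSums(tracker[solved, , drop = FALSE]) > 0)
  if (is.null(packets)) packets <- used else packets <- intersect(packets,
                                                                  used)
  cap <- max_tags
  out <- vector("list", 0)
  with_local_seed(rng_seed, {
    for (p in packets) {
      affected <- intersect(which(tracker[, p] == 1L), solved)
      clean <- setdiff(solved, affected)
      for (r in seq_len(repeats)) {
        pool_inv <- sample(affected)[seq_len(min(cap, length(affected)))]
        pool_val <- sample(clean)[seq_len(min(cap, length(clean)))]
        # prefix cumulative masks: inc[i] = intersection over the first i
        # invalid tags; cor[v] = union over the first v valid tags
        inc <- matrix(TRUE, nrow = length(pool_inv) + 1, ncol = M)
        for (i in seq_along(pool_inv))
          inc[i + 1, ] <- inc[i, ] & (tracker[pool_inv[i], ] == 1L)
        cor <- matrix(FALSE, nrow = length(pool_val) + 1, ncol = M)
        for (v in seq_along(pool_val))
          cor[v + 1, ] <- cor[v, ] | (tracker[pool_val[v], ] == 1L)
        best <- NA_integer_
        for (i in seq_along(pool_inv)) {
          m <- inc[i + 1, ]
          cnt <- sum(m) - as.vector(cor %*% m)  # candidates per valid count
          hit <- which(cnt == 1L)
          if (length(hit) > 0) {
            cand <- i + (hit[1] - 1L)
            if (is.na(best) || cand < best) best <- cand
          }
          if (!is.na(best) && best <= i + 1) break
        }
        out[[length(out) + 1]] <- data.frame(packet = p, rep = r,
                                             n_tags = best)
      }
    }
  })
  do.call(rbind, out)
}
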