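# DNA rendition of packets, synthesis-constraint screening, and a
# parametric substitution/dropout channel.

BASES <- c("A", "C", "G", "T")

# 256-entry lookup: byte value -> 4-base string, MSB pair first
byte_to_quad <- local({
  vapply(0:255, function(v) {
    paste0(BASES[c(v %/% 64, (v %/% 16) %% 4, (v %/% 4) %% 4, v %% 4) + 1],
           collapse = "")
  }, character(1))
})

#' Render bytes as DNA (2 bits per base)
#'
#' Plain mapping A=00, C=01, G=10, T=11, most-significant bits first, so one
#' byte becomes four bases.
#'
#' @param bytes raw vector
#' @return single DNA string
#' @export
to_dna <- function(bytes) {
  stopifnot(is.raw(bytes))
  paste0(byte_to_quad[as.integer(bytes) + 1], collapse = "")
}

#' Decode a DNA string back to bytes
#' @param seq DNA string over ACGT (lowercase accepted), length divisible by 4
#' @return raw vector
#' @export
from_dna <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 4 != 0) stop("DNA length must be divisible by 4 bases per byte")
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1]], BASES) - 1L
  if (anyNA(codes)) stop("non-ACGT symbol in sequence")
  q <- matrix(codes, nrow = 4)
  as.raw(q[1, ] * 64L + q[2, ] * 16L + q[3, ] * 4L + q[4, ])
}

#' DNA synthesis constraint set
#'
#' @param max_homopolymer longest allowed run of identical bases
#' @param gc_min,gc_max global GC-content bounds (fractions)
#' @param window_len sliding-window length in nt for windowed GC (stride 1);
#'   windows shorter than this at the tail are skipped
#' @param window_gc_min,window_gc_max per-window GC bounds
#' @param blacklist_motifs character vector of forbidden motifs; reverse
#'   complements are rejected too
#' @return object of class `constraint_set`
#' @export
constraint_set <- function(max_homopolymer = 3,
                           gc_min = 0.4, gc_max = 0.6,
                           window_len = 50,
                           window_gc_min = 0.3, window_gc_max = 0.7,
                           blacklist_motifs = character(0)) {
  stopifnot(gc_min >= 0, gc_max <= 1, window_gc_min >= 0, window_gc_max <= 1)
  structure(list(max_homopolymer = max_homopolymer, gc_min = gc_min,
                 gc_max = gc_max, window_len = window_len,
                 window_gc_min = window_gc_min, window_gc_max = window_gc_max,
                 blacklist_motifs = toupper(blacklist_motifs)),
            class = "constraint_set")
}

reverse_complement <- function(seq) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(toupper(seq), "", fixed = TRUE)[[1]]),
               collapse = ""))
}

#' Screen a DNA sequence against synthesis constraints
#'
#' @param seq DNA string
#' @param c a [constraint_set()]
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   violated rules, empty on pass)
#' @export
check_constraints <- function(seq, c) {
  stopifnot(inherits(c, "constraint_set"))
  seq <- toupper(seq)
  reasons <- character(0)
  if (grepl(sprintf("A{%d}|C{%d}|G{%d}|T{%d}",
                    c$max_homopolymer + 1, c$max_homopolymer + 1,
                    c$max_homopolymer + 1, c$max_homopolymer + 1), seq))
    reasons <- c(reasons, "homopolymer")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  is_gc <- ch == "G" | ch == "C"
  gc <- mean(is_gc)
  if (gc < c$gc_min || gc > c$gc_max)
    reasons <- c(reasons, "gc_global")
  if (length(ch) >= c$window_len) {
    cs <- c(0, cumsum(is_gc))
    w <- c$window_len
    win_gc <- (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
    if (any(win_gc < c$window_gc_min | win_gc > c$window_gc_max))
      reasons <- c(reasons, "gc_window")
  }
  for (m in c$blacklist_motifs) {
    if (grepl(m, seq, fixed = TRUE) ||
        grepl(reverse_complement(m), seq, fixed = TRUE)) {
      reasons <- c(reasons, "motif")
      break
    }
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Synthetic corruption channel configuration
#'
#' A parametric stand-in for the DNA storage channel: per-base
#' substitutions and whole-strand dropouts.  Indels are modeled as strand
#' drops only, because wrong-length strands are discarded before decoding
#' and surviving errors therefore reduce to substitutions.
#'
#' @param substitution_rate per-base probability of substitution to a
#'   uniformly chosen different base
#' @param drop_rate per-strand probability of loss
#' @param rng_seed integer seed; the channel is deterministic given it
#' @return object of class `channel_config`
#' @export
channel_config <- function(substitution_rate = 0, drop_rate = 0,
                           rng_seed = 1) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            drop_rate >= 0, drop_rate <= 1)
  structure(list(substitution_rate = substitution_rate,
                 drop_rate = drop_rate, rng_seed = rng_seed),
            class = "channel_config")
}

# evaluate expr with a locally seeded RNG, restoring global RNG state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Pass DNA strands through the substitution/dropout channel
#'
#' @param seqs character vector of DNA strands
#' @param config a [channel_config()]
#' @return character vector of surviving (possibly substituted) strands
#' @export
corrupt <- function(seqs, config) {
  stopifnot(inherits(config, "channel_config"))
  with_local_seed(config$rng_seed, {
    keep <- runif(length(seqs)) >= config$drop_rate
    seqs <- seqs[keep]
    if (config$substitution_rate > 0) {
      seqs <- vapply(seqs, function(s) {
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        hit <- which(runif(length(ch)) < config$substitution_rate)
        for (i in hit) {
          ch[i] <- sample(setdiff(BASES, ch[i]), 1)
        }
        paste0(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    seqs
  })
}

#' Discard strands of unexpected length
#'
#' Fountain packets have a fixed strand length, so insertions/deletions are
#' detected directly and such strands removed (they become erasures the
#' fountain overhead absorbs).
#'
#' @param seqs character vector of strands
#' @param expected_nt expected strand length
#' @return list with `kept` and `discarded`
#' @export
length_filter <- function(seqs, expected_nt) {
  ok <- nchar(seqs) == expected_nt
  list(kept = seqs[ok], discarded = seqs[!ok])
}

#' Render a packet set as DNA strands
#' @param pk a `packet_set`
#' @return character vector, one strand per packet (seed + payload + ECC)
#' @export
packets_to_dna <- function(pk) {
  stopifnot(inherits(pk, "packet_set"))
  vapply(pk$packets, function(p) {
    to_dna(c(seed_to_bytes(p$seed, pk$config$seed_len), p$payload, p$ecc))
  }, character(1))
}

#' Parse DNA strands back into packets
#'
#' Inverts [packets_to_dna()]: splits each strand into seed, payload and
#' optional RS parity, runs the RS check when `config$ecc_sym > 0`, and
#' drops uncorrectable strands (they are counted as erasures).
#'
#' @param seqs character vector of strands (equal length)
#' @param config the [encoder_config()] used at encoding time
#' @return list with `packets`, `n_repaired`, `n_failed`
#' @export
dna_to_packets <- function(seqs, config) {
  packets <- list()
  n_repaired <- 0L
  n_failed <- 0L
  for (s in seqs) {
    bytes <- from_dna(s)
    if (config$ecc_sym > 0) {
      res <- rs_decode(bytes, config$ecc_sym)
      if (res$status == "failed") { n_failed <- n_failed + 1L; next }
      if (res$status == "repaired") n_repaired <- n_repaired + 1L
      bytes <- res$payload
    }
    seed <- bytes_to_seed(bytes[seq_len(config$seed_len)])
    payload <- bytes[(config$seed_len + 1):length(bytes)]
    packets[[length(packets) + 1]] <-
      list(seed = seed, payload = payload, ecc = raw(0))
  }
  list(packets = packets, n_repaired = n_repaired, n_failed = n_failed)
}

#' Write strands to a FASTA file
#'
#' One record per strand; record ids are a running index (strand order
#' carries no meaning downstream).
#'
#' @param seqs character vector of DNA strands
#' @param path output file
#' @export
write_packets_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- sprintf("strand_%06d", seq_along(seqs))
  Biostrings::writeXStringSet(x, filepath = path, width = 20000L)
  invisible(path)
}

#' Read strands from a FASTA file
#'
#' Lowercase bases are upcased; records containing symbols outside ACGT are
#' rejected (with a message) and counted.
#'
#' @param path FASTA file
#' @return list with `seqs` (character) and `n_rejected`
#' @export
read_packets_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  ok <- !grepl("[^ACGT]", seqs)
  if (any(!ok))
    message(sum(!ok), " record(s) rejected (non-ACGT symbols)")
  if (length(seqs) == 0) warning("empty FASTA file")
  list(seqs = unname(seqs[ok]), n_rejected = sum(!ok))
}
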