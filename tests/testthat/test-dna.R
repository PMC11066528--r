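# DNA rendition, constraint screening, channel, strand-level ECC, FASTA.

test_that("byte/base mapping is the fixed 2-bit code and bijective", {
  expect_equal(to_dna(as.raw(0x00)), "AAAA")
  expect_equal(to_dna(as.raw(0x1B)), "ACGT")
  all_bytes <- as.raw(0:255)
  expect_identical(from_dna(to_dna(all_bytes)), all_bytes)
  expect_identical(from_dna("acgt"), as.raw(0x1B))  # lowercase accepted
  expect_error(from_dna("ACGTN..."), "non-ACGT")
  expect_error(from_dna("ACG"), "divisible")
})

test_that("constraint screening matches an independent rule-by-rule check", {
  cs <- constraint_set()
  expect_true(check_constraints("ACGT", cs)$pass)  # GC exactly 50%
  r <- check_constraints("AAAACGCG", cs)
  expect_false(r$pass)
  expect_true("homopolymer" %in% r$reasons)

  ref_check <- function(seq, c) {
    ch <- strsplit(seq, "")[[1]]
    runs <- rle(ch)
    if (max(runs$lengths) > c$max_homopolymer) return(FALSE)
    gc <- mean(ch %in% c("G", "C"))
    if (gc < c$gc_min || gc > c$gc_max) return(FALSE)
    if (length(ch) >= c$window_len) {
      for (s in 1:(length(ch) - c$window_len + 1)) {
        wgc <- mean(ch[s:(s + c$window_len - 1)] %in% c("G", "C"))
        if (wgc < c$window_gc_min || wgc > c$window_gc_max) return(FALSE)
      }
    }
    TRUE
  }
  set.seed(6)
  for (i in 1:100) {
    seq <- paste0(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                  collapse = "")
    expect_equal(check_constraints(seq, cs)$pass, ref_check(seq, cs),
                 info = seq)
  }

  # motifs are rejected together with their reverse complements
  cm <- constraint_set(blacklist_motifs = "GAATTC")
  expect_false(check_constraints("ACGAATTCGT", cm)$pass)
  expect_false(check_constraints(dnarescue:::reverse_complement("ACGAATTCGT"),
                                 cm)$pass)
})

test_that("substitution channel is seeded, rate-faithful, length-preserving", {
  seqs <- vapply(1:50, function(i) to_dna(random_file(20, i)), character(1))
  cc0 <- channel_config(substitution_rate = 0, drop_rate = 0, rng_seed = 1)
  expect_identical(corrupt(seqs, cc0), seqs)

  cc1 <- channel_config(substitution_rate = 1, drop_rate = 0, rng_seed = 2)
  out1 <- corrupt("A", cc1)
  expect_false(out1 == "A")

  cc <- channel_config(substitution_rate = 0.01, drop_rate = 0,
                       rng_seed = 3)
  long <- paste0(rep("A", 10000), collapse = "")
  hit <- sum(strsplit(corrupt(long, cc), "")[[1]] != "A")
  sigma <- sqrt(10000 * 0.01 * 0.99)
  expect_lt(abs(hit - 100), 3.5 * sigma)
  # substitutions never change strand length
  expect_equal(nchar(corrupt(seqs, cc)), nchar(seqs))
  # determinism given the seed
  expect_identical(corrupt(seqs, cc), corrupt(seqs, cc))

  ccd <- channel_config(drop_rate = 0.5, rng_seed = 4)
  kept <- corrupt(rep("ACGT", 1000), ccd)
  expect_lt(abs(length(kept) - 500), 3.5 * sqrt(250) + 1)
})

test_that("length filter separates indel-bearing strands", {
  seqs <- c("ACGTACGT", "ACGTACG", "ACGTACGT", "ACGTACGTA")
  lf <- length_filter(seqs, 8)
  expect_equal(length(lf$kept), 2)
  expect_equal(length(lf$discarded), 2)
  expect_true(all(nchar(lf$kept) == 8))
})

test_that("strand ECC corrects within capacity and reports failures", {
  payload <- random_file(30, rng_seed = 5)
  blk <- rs_encode(payload, 2)
  expect_equal(length(blk), 32)
  expect_equal(rs_decode(blk, 2)$status, "ok")

  # every single-byte corruption is repaired (t = 1 for two parity bytes)
  for (pos in seq_along(blk)) {
    bad <- blk
    bad[pos] <- xor_raw(bad[pos], as.raw(0x35))
    r <- rs_decode(bad, 2)
    expect_equal(r$status, "repaired")
    expect_identical(r$payload, payload)
  }

  # two byte errors exceed t and must not silently pass
  bad2 <- blk
  bad2[3] <- xor_raw(bad2[3], as.raw(1))
  bad2[9] <- xor_raw(bad2[9], as.raw(2))
  expect_equal(rs_decode(bad2, 2)$status, "failed")

  # four parity bytes correct two errors
  blk4 <- rs_encode(payload, 4)
  bad4 <- blk4
  bad4[c(2, 20)] <- xor_raw(bad4[c(2, 20)], as.raw(c(7, 200)))
  r4 <- rs_decode(bad4, 4)
  expect_equal(r4$status, "repaired")
  expect_identical(r4$payload, payload)

  expect_error(rs_encode(random_file(254, 1), 4), "too long")
})

test_that("DNA round trip through the ECC-wrapped strand set", {
  data <- random_file(300, rng_seed = 12)
  cfg <- encoder_config(chunk_size = 20, overhead = 4, ecc_sym = 2)
  pk <- encode(data, cfg, ensure_decodable = TRUE)
  strands <- packets_to_dna(pk)
  # strand length: (seed 4 + payload 20 + ecc 2) bytes * 4 bases
  expect_true(all(nchar(strands) == 26 * 4))

  # one substituted base per strand is absorbed by the RS code
  cc <- channel_config(substitution_rate = 0.005, rng_seed = 6)
  noisy <- corrupt(strands, cc)
  parsed <- dna_to_packets(noisy, cfg)
  dr <- decode(parsed$packets, n_chunks = pk$n_chunks, config = cfg)
  expect_equal(dr$status, "solved")
  expect_identical(dr$file, data)
})

test_that("constraint-screened packets all satisfy the constraints", {
  cons <- constraint_set(max_homopolymer = 3, gc_min = 0.4, gc_max = 0.6,
                         window_len = 50)
  data <- random_file(200, rng_seed = 13)
  cfg <- encoder_config(chunk_size = 20, overhead = 4)
  # low seeds render as leading A-homopolymers (zero bytes); start the
  # seed counter in a region whose upper bytes carry mixed bits
  pk <- encode(data, cfg, constraints = cons, first_seed = 456787000)
  for (s in packets_to_dna(pk))
    expect_true(check_constraints(s, cons)$pass)
})

test_that("FASTA write/read round trip with per-record rejection", {
  strands <- vapply(1:50, function(i) to_dna(random_file(15, i)),
                    character(1))
  path <- tempfile(fileext = ".fasta")
  write_packets_fasta(strands, path)
  back <- read_packets_fasta(path)
  expect_identical(back$seqs, strands)
  expect_equal(back$n_rejected, 0)

  # a record with N is rejected, the rest survive
  lines <- readLines(path)
  writeLines(c(lines, ">bad", "ACGTNACGT"), path)
  expect_message(back2 <- read_packets_fasta(path), "rejected")
  expect_equal(back2$n_rejected, 1)
  expect_identical(back2$seqs, strands)

  # empty file warns and returns nothing
  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_warning(r <- read_packets_fasta(empty), "empty")
  expect_equal(length(r$seqs), 0)
})
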