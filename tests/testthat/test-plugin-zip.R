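# ZIP content plugin: signature scan, cross-checks, localization,
# brute-force reparse repair.

make_zip <- function(n_files = 4, rng_seed = 60) {
  set.seed(rng_seed)
  files <- list()
  for (i in seq_len(n_files)) {
    body <- paste(sample(c("import os", "x = 1", "print(x)", "def f():",
                           "    return 2", "# comment"),
                         sample(20:40, 1), replace = TRUE), collapse = "\n")
    files[[sprintf("module_%02d.py", i)]] <- charToRaw(body)
  }
  zip_build(files)
}

make_zip_case <- function(rng_seed, n_files = 4, chunk_size = 30,
                          overhead = 8) {
  z <- make_zip(n_files, rng_seed)
  cfg <- encoder_config(chunk_size = chunk_size, overhead = overhead)
  dr0 <- encode_solved(z, cfg, filename = "arc.zip",
                       first_seed = rng_seed * 127)$dr
  list(z = z, dr0 = dr0, cfg = cfg, chunk_size = chunk_size)
}

# corrupt the packet covering a given file-byte position (avoiding the
# header chunk), returning the corrupted decode and ground truth
corrupt_at_byte <- function(cs, byte_pos, delta_byte = 0x15) {
  dr0 <- cs$dr0
  ch <- cs$chunk_size
  row_hit <- 1 + ((byte_pos - 1) %/% ch) + 1
  col_hit <- ((byte_pos - 1) %% ch) + 1
  tracker <- dr0$system$tracker[seq_len(dr0$n_chunks), , drop = FALSE]
  nc <- which(classify_criticality(dr0$A))
  nc <- nc[tracker[1, nc] == 0L]
  victim <- intersect(which(tracker[row_hit, ] == 1L), nc)[1]
  delta <- raw(ch)
  delta[col_hit] <- as.raw(delta_byte)
  list(dr = inject_error(dr0, victim, delta), victim = victim,
       delta = delta, row = row_hit, col = col_hit)
}

test_that("a pristine stored archive has no invalid cells or pairs", {
  cs <- make_zip_case(61, n_files = 2)
  za <- zip_analyze(cs$dr0)
  expect_equal(za$n_local, 2)
  expect_equal(za$n_central, 2)
  expect_true(za$eocd_ok)
  expect_equal(sum(za$error_matrix$states == 1L), 0)
  expect_equal(length(za$pairs), 0)
  expect_true(zip_validate(cs$z))
})

test_that("non-ZIP input raises the not-a-ZIP signal", {
  data <- charToRaw(strrep("plain text only, nothing binary here. ", 20))
  cfg <- encoder_config(chunk_size = 30, overhead = 4)
  dr <- encode_solved(data, cfg, filename = "t.txt")$dr
  expect_error(zip_analyze(dr), "not a ZIP")
})

test_that("a corrupted filename surfaces as an alternating pair", {
  cs <- make_zip_case(62)
  za0 <- zip_analyze(cs$dr0)
  fn_pos <- za0$entries[[2]]$offset + 30 + 2  # 2nd filename byte, entry 2
  cc <- corrupt_at_byte(cs, fn_pos)
  za <- zip_analyze(cc$dr)
  fields <- vapply(za$pairs, function(p) p$field, character(1))
  expect_true("filename" %in% fields)
  # the corrupted byte shows up in some filename pair (the same column of
  # other affected rows may produce further pairs)
  hit <- vapply(za$pairs[fields == "filename"], function(p) {
    fn_pos %in% p$local_bytes || fn_pos %in% p$central_bytes
  }, logical(1))
  expect_true(any(hit))
})

test_that("a corrupted length field does not hide the following header", {
  cs <- make_zip_case(63)
  za0 <- zip_analyze(cs$dr0)
  # corrupt the compressed-size field of entry 1's local header
  size_pos <- za0$entries[[1]]$offset + 18 + 1
  cc <- corrupt_at_byte(cs, size_pos, delta_byte = 0x40)
  za <- zip_analyze(cc$dr)
  # all local headers are still located despite the bad length
  expect_equal(za$n_local, 4)
  fields <- vapply(za$pairs, function(p) p$field, character(1))
  expect_true("csize" %in% fields)
})

test_that("column-restricted localization narrows to the true packet", {
  done <- 0
  for (s in c(64, 65, 66)) {
    cs <- make_zip_case(s, n_files = 5, overhead = 10)
    za0 <- zip_analyze(cs$dr0)
    fn_pos <- za0$entries[[2]]$offset + 30 + 1
    cc <- corrupt_at_byte(cs, fn_pos)
    za <- zip_analyze(cc$dr)
    zl <- zip_column_localize(cc$dr, za)
    if (length(zl$candidates) == 0) next
    expect_true(cc$victim %in% zl$candidates)
    # brute-force reparse repair resolves any remaining ambiguity
    br <- zip_bruteforce_repair(cc$dr, zl$candidates, cc$delta)
    expect_true(br$unique)
    expect_identical(br$files[[1]], cs$z)
    done <- done + 1
  }
  expect_gte(done, 2)
})

test_that("brute-force repair over 18 candidates validates exactly one file", {
  cs <- make_zip_case(67, n_files = 3, overhead = 8)
  dr0 <- cs$dr0
  tracker <- dr0$system$tracker[seq_len(dr0$n_chunks), , drop = FALSE]
  nc <- which(classify_criticality(dr0$A))
  nc <- nc[tracker[1, nc] == 0L]
  victim <- nc[1]
  delta <- random_delta(cs$chunk_size, nnz = 2)
  dr <- inject_error(dr0, victim, delta)
  # an 18-strong candidate set containing the truth
  set.seed(68)
  beta <- head(unique(c(victim, sample(nrow(dr$A)))), 18)
  br <- zip_bruteforce_repair(dr, beta, delta)
  expect_true(br$unique)
  expect_identical(br$files[[1]], cs$z)
  expect_equal(br$packets, victim)

  # singleton candidate set reproduces the original archive directly
  br1 <- zip_bruteforce_repair(dr, victim, delta)
  expect_true(br1$unique)
  expect_identical(br1$files[[1]], cs$z)

  # zero delta is a flagged no-op
  br0 <- zip_bruteforce_repair(dr0, beta, raw(cs$chunk_size))
  expect_true(br0$noop)
  expect_identical(br0$files[[1]], cs$z)
})

test_that("reparse validation rejects single-byte CRC-field corruptions", {
  z <- make_zip(2, rng_seed = 69)
  expect_true(zip_validate(z))
  loc <- dnarescue:::find_signature(z, dnarescue:::SIG_LOCAL)
  for (p in loc) {
    for (off in 14:17) {  # CRC-32 field of the local header
      bad <- z
      bad[p + off] <- xor_raw(bad[p + off], as.raw(0x01))
      expect_false(zip_validate(bad))
    }
  }
})

test_that("plugin discovery picks analyzers from filename and magic bytes", {
  cs <- make_zip_case(70, n_files = 2)
  expect_equal(detect_plugin(cs$dr0)$name, "zip")
  txt <- synthetic_text(800, rng_seed = 71)
  drt <- encode_solved(txt, encoder_config(chunk_size = 20, overhead = 4),
                       filename = "story.txt")$dr
  expect_equal(detect_plugin(drt)$name, "text")
  expect_equal(detect_plugin(cs$dr0, override = "bmp")$name, "bmp")
  expect_error(detect_plugin(cs$dr0, override = "nope"), "unknown plugin")
  # magic-byte fallback: strip the filename hint
  dr_anon <- cs$dr0
  dr_anon$header$filename <- "blob.bin"
  expect_equal(detect_plugin(dr_anon)$name, "zip")
})
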