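# Text content plugin: corrector, column-delta histogram, tagging, upload.

make_text_case <- function(rng_seed, n_bytes = 3200, chunk_size = 40,
                           col = 7, delta_byte = 0x08, min_rows = 25) {
  txt <- synthetic_text(n_bytes, rng_seed = rng_seed)
  cfg <- encoder_config(chunk_size = chunk_size, overhead = 8)
  dr0 <- encode_solved(txt, cfg, filename = "story.txt",
                       first_seed = rng_seed * 509)$dr
  tracker <- dr0$system$tracker[seq_len(dr0$n_chunks), , drop = FALSE]
  nc <- which(classify_criticality(dr0$A))
  # pick a non-critical packet whose error will touch many rows
  loads <- colSums(tracker)
  cand <- nc[order(-loads[nc])]
  victim <- cand[loads[cand] >= min_rows][1]
  if (is.na(victim)) victim <- cand[1]
  delta <- raw(chunk_size)
  delta[col] <- as.raw(delta_byte)
  dr <- inject_error(dr0, victim, delta)
  list(txt = txt, dr0 = dr0, dr = dr, victim = victim, delta = delta,
       col = col, affected = which(tracker[, victim] == 1L))
}

test_that("dictionary corrector preserves length and fixes 1-char errors", {
  corr <- dictionary_corrector(reference_lexicon())
  expect_equal(corr$correct("the kixg was asleep"), "the king was asleep")
  expect_equal(nchar(corr$correct("zzzz qqqq")), 9)
  # unknown words with no close match are left alone
  expect_equal(corr$correct("xyzzy"), "xyzzy")
})

test_that("clean text yields an all-zero column histogram", {
  txt <- synthetic_text(1500, rng_seed = 40)
  cfg <- encoder_config(chunk_size = 30, overhead = 4)
  dr0 <- encode_solved(txt, cfg, filename = "t.txt")$dr
  corr <- dictionary_corrector(reference_lexicon())
  rows <- setdiff(which(dr0$system$solved_mask[seq_len(dr0$n_chunks)]), 1)
  te <- text_error_histogram(dr0$solution, corr, rows = rows)
  tops <- vapply(te$histogram, function(h)
    if (length(h) == 0) 0L else as.integer(h[1]), integer(1))
  # stray false-positive corrections stay below any acting threshold
  expect_true(all(tops < 8))
  clean_col <- which(tops == 0)[1]
  expect_error(text_tag_rows(te, clean_col, threshold = 8),
               "below threshold")
})

test_that("a corrupted column dominates the histogram and tags true rows", {
  cs <- make_text_case(rng_seed = 41)
  expect_gte(length(cs$affected), 25)
  corr <- dictionary_corrector(reference_lexicon())
  rows <- setdiff(which(cs$dr$system$solved_mask[seq_len(cs$dr$n_chunks)]),
                  1)
  te <- text_error_histogram(cs$dr$solution, corr, rows = rows)
  sus <- text_suspect_columns(te, threshold = 8)
  expect_equal(sus[1], cs$col)
  tg <- text_tag_rows(te, cs$col, threshold = 8, mode = "strict")
  expect_identical(tg$delta, as.raw(0x08))
  # tagged-incorrect rows are all truly affected
  expect_true(all(tg$tags$incorrect %in% cs$affected))
  # strict and lenient modes differ only on rows with non-dominant deltas
  tl <- text_tag_rows(te, cs$col, threshold = 8, mode = "lenient")
  extra <- setdiff(tl$tags$correct, tg$tags$correct)
  col_deltas <- as.integer(te$bdelta[extra, cs$col])
  expect_true(all(col_deltas != 0 & col_deltas != 8))
})

test_that("text localization and repair recover the original file", {
  ok <- 0
  for (s in c(42, 43, 44)) {
    cs <- make_text_case(rng_seed = s)
    corr <- dictionary_corrector(reference_lexicon())
    rows <- setdiff(
      which(cs$dr$system$solved_mask[seq_len(cs$dr$n_chunks)]), 1)
    te <- text_error_histogram(cs$dr$solution, corr, rows = rows)
    sus <- text_suspect_columns(te, threshold = 8)
    if (length(sus) == 0) next
    tl <- text_localize(cs$dr, te, sus[1], threshold = 8)
    if (!(cs$victim %in% tl$candidates)) next
    en <- enumerate_candidate_files(cs$dr, tl$candidates, list(tl$delta))
    if (en$unique && identical(en$files[[1]], cs$txt)) ok <- ok + 1
  }
  expect_gte(ok, 2)
})

test_that("two corrupted columns are handled iteratively", {
  cs1 <- make_text_case(rng_seed = 45, col = 5)
  # second corruption in a different column via a different packet
  tracker <- cs1$dr0$system$tracker[seq_len(cs1$dr0$n_chunks), ,
                                    drop = FALSE]
  nc <- which(classify_criticality(cs1$dr0$A))
  second <- setdiff(nc[order(-colSums(tracker)[nc])], cs1$victim)[1]
  d2 <- raw(40); d2[12] <- as.raw(0x04)
  b2 <- cs1$dr$b
  b2[second, ] <- xor_raw(b2[second, ], d2)
  dr <- dnarescue:::decode_system(cs1$dr$A, b2, cs1$dr$n_chunks, 0,
                                  cs1$dr$config)
  corr <- dictionary_corrector(reference_lexicon())
  rows <- setdiff(which(dr$system$solved_mask[seq_len(dr$n_chunks)]), 1)
  te <- text_error_histogram(dr$solution, corr, rows = rows)
  sus <- text_suspect_columns(te, threshold = 8)
  expect_true(all(c(5, 12) %in% sus))

  # repair the first column, re-run the analysis, repair the second
  tl1 <- text_localize(dr, te, 5, threshold = 8)
  if (cs1$victim %in% tl1$candidates) {
    en1 <- enumerate_candidate_files(dr, tl1$candidates,
                                     list(tl1$delta),
                                     validator = function(f) TRUE)
    # apply the first fix directly and iterate
    dr_1 <- dnarescue:::redecode_with_fix(dr, cs1$victim, tl1$delta)
    te2 <- text_error_histogram(dr_1$solution, corr, rows = rows)
    sus2 <- text_suspect_columns(te2, threshold = 8)
    expect_false(5 %in% sus2)
    expect_true(12 %in% sus2)
  }
})

test_that("upload diff recovers deltas and enables full repair", {
  data <- random_file(900, rng_seed = 48)
  cfg <- encoder_config(chunk_size = 30, overhead = 6)
  dr0 <- encode_solved(data, cfg)$dr
  nc <- which(classify_criticality(dr0$A))
  tracker0 <- dr0$system$tracker[seq_len(dr0$n_chunks), , drop = FALSE]
  # keep the header chunk intact so the corrupted decode still assembles
  nc <- nc[tracker0[1, nc] == 0L]
  victim <- nc[1]
  delta <- random_delta(30, nnz = 4)
  dr <- inject_error(dr0, victim, delta)

  # identical upload: nothing tagged incorrect
  up0 <- upload_diff(dr0, data)
  expect_equal(length(up0$tags$incorrect), 0)
  expect_gt(length(up0$tags$correct), 0)

  # a partially repaired upload: take the corrupted decode and fix the
  # bytes of three affected rows out-of-band
  affected <- which(dr$system$tracker[seq_len(dr$n_chunks), victim] == 1L)
  fixed_rows <- setdiff(affected, 1)[1:3]
  uploaded <- as.vector(t(dr$solution[1 + seq_len(dr$n_chunks - 1), ]))
  uploaded <- uploaded[seq_len(length(data))]
  for (r in fixed_rows) {
    lo <- (r - 2) * 30 + 1
    hi <- min(lo + 29, length(uploaded))
    uploaded[lo:hi] <- data[lo:hi]
  }
  # the decode result being diffed is the corrupted one
  up <- upload_diff(dr, as.raw(uploaded), partial = TRUE)
  expect_equal(sort(vapply(up$deltas, function(d) d$row, numeric(1))),
               sort(fixed_rows))
  for (d in up$deltas) expect_identical(d$delta, delta)

  # localization from the upload tags + propagation restores the file
  cand <- localize_from_tags(dr$system,
                             tag_set(incorrect = up$tags$incorrect))
  expect_true(victim %in% cand)
  sol <- propagate_delta(dr$system, victim, up$deltas[[1]]$delta)
  out <- reassemble_file(sol[seq_len(dr$n_chunks), ])
  expect_identical(out$file, data)

  expect_error(upload_diff(dr, as.raw(c(uploaded, 0))), "length")
})
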