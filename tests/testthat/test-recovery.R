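# Corrupted-packet localization, permutation repair, delta machinery.

test_that("tag localization narrows to the corrupted packet", {
  # one incorrect row whose contribution set is a singleton
  b <- matrix(as.raw(1:8), 4, 2)
  t <- eliminate_tracked(diag(4L), b)
  expect_equal(localize_from_tags(t, tag_set(incorrect = 3)), 3L)

  # randomized systems with an injected corruption and truthful tags
  set.seed(14)
  for (i in 1:25) {
    data <- random_file(250, rng_seed = i)
    cfg <- encoder_config(chunk_size = 25, overhead = 4)
    dr0 <- encode_solved(data, cfg, first_seed = i * 977)$dr
    nc <- which(classify_criticality(dr0$A))
    tracker <- dr0$system$tracker[seq_len(dr0$n_chunks), , drop = FALSE]
    # only packets used in at least one solved row can be tagged at all
    nc <- nc[colSums(tracker[, nc, drop = FALSE]) > 0]
    victim <- sample(nc, 1)
    affected <- which(tracker[, victim] == 1L)
    clean <- setdiff(seq_len(dr0$n_chunks), affected)
    tags <- tag_set(correct = clean, incorrect = affected)
    cand <- localize_from_tags(dr0$system, tags)
    expect_true(victim %in% cand)
    # full truthful tagging isolates the packet when its footprint is
    # unique among packets
    same_col <- sum(apply(tracker, 2, identical, y = tracker[, victim]))
    if (same_col == 1) expect_equal(cand, victim)
    # adding truthful tags never grows the candidate set
    part <- tag_set(correct = clean[seq_len(length(clean) %/% 2)],
                    incorrect = affected[1])
    expect_gte(length(localize_from_tags(dr0$system, part)), length(cand))
  }
})

test_that("correct-only tags cannot isolate and raise a signal", {
  b <- matrix(as.raw(1:8), 4, 2)
  t <- eliminate_tracked(diag(4L), b)
  expect_error(localize_from_tags(t, tag_set(correct = c(1, 2))),
               "insufficient")
  # multi mode returns an empty set instead
  expect_equal(length(localize_from_tags(t, tag_set(correct = 1:2),
                                         multi = TRUE)), 0)
})

test_that("permutation ensemble exposes the worked example's two solutions", {
  ex <- example1()
  pv <- permutation_variants(ex$A, ex$b, n_perms = 12, rng_seed = 3)
  v2 <- unique(vapply(pv$solutions, function(s) row_string(s[2, ]),
                      character(1)))
  expect_true("010101" %in% v2 || "010110" %in% v2)
  # the two printed versions differ by delta 000011
  t1 <- eliminate_tracked(ex$A, ex$b)
  t2 <- eliminate_tracked(ex$A, ex$b, c(1, 4, 3, 2))
  delta <- xor_raw(t1$reduced_b[2, ], t2$reduced_b[2, ])
  expect_equal(row_string(delta), "000011")

  # consistent systems: every permutation yields identical solutions
  sys <- random_system(9, 6, 3, seed = 8)
  pvc <- permutation_variants(sys$A, sys$b, n_perms = 8, rng_seed = 1)
  for (s in pvc$solutions) expect_identical(s, pvc$solutions[[1]])
})

test_that("single-error auto repair restores files and never fabricates", {
  set.seed(15)
  n_rep <- 0
  for (i in 1:25) {
    data <- random_file(sample(300:2500, 1), rng_seed = i + 50)
    cfg <- encoder_config(chunk_size = 30, overhead = sample(2:8, 1))
    dr0 <- encode_solved(data, cfg, first_seed = i * 1331)$dr
    nc <- which(classify_criticality(dr0$A))
    victim <- sample(nc, 1)
    dr <- inject_error(dr0, victim, random_delta(30))
    rep <- auto_repair_single(dr, rng_seed = i)
    expect_equal(rep$status, "repaired")
    expect_identical(rep$repaired_file, data)
    n_rep <- n_rep + 1
  }
  expect_equal(n_rep, 25)
})

test_that("clean decode reports no_error; critical corruption not localizable", {
  data <- random_file(200, rng_seed = 60)
  cfg <- encoder_config(chunk_size = 20, overhead = 3)
  dr0 <- encode_solved(data, cfg)$dr
  expect_equal(auto_repair_single(dr0)$status, "no_error")

  # square full-rank system: every packet is critical, an error keeps the
  # system consistent and cannot be seen by the decoder alone
  sys <- random_system(6, 6, 4, seed = 77)
  expect_true(all(!classify_criticality(sys$A)))
  b2 <- sys$b
  b2[2, ] <- xor_raw(b2[2, ], random_delta(4))
  expect_true(is_consistent(sys$A, b2))
})

test_that("multi-error repair fixes independent deltas, flags dependent ones", {
  set.seed(16)
  for (i in 1:5) {
    data <- random_file(1200, rng_seed = i + 90)
    cfg <- encoder_config(chunk_size = 30, overhead = 10)
    dr0 <- encode_solved(data, cfg, first_seed = i * 4099)$dr
    nc <- which(classify_criticality(dr0$A))
    v <- sample(nc, 2)
    d1 <- random_delta(30, nnz = 2)
    d2 <- random_delta(30, nnz = 2)
    if (identical(d1, d2)) d2[1] <- xor_raw(d2[1], as.raw(3))
    b2 <- dr0$b
    b2[v[1], ] <- xor_raw(b2[v[1], ], d1)
    b2[v[2], ] <- xor_raw(b2[v[2], ], d2)
    dr <- dnarescue:::decode_system(dr0$A, b2, dr0$n_chunks, 0, cfg)
    rep <- auto_repair_multi(dr, rng_seed = i)
    expect_equal(rep$status, "repaired")
    expect_identical(rep$repaired_file, data)
  }

  # single corruption: multi-error route agrees with the single route
  data <- random_file(800, rng_seed = 91)
  cfg <- encoder_config(chunk_size = 25, overhead = 6)
  dr0 <- encode_solved(data, cfg)$dr
  nc <- which(classify_criticality(dr0$A))
  dr <- inject_error(dr0, nc[2], random_delta(25, nnz = 1))
  r1 <- auto_repair_single(dr, rng_seed = 4)
  r2 <- auto_repair_multi(dr, rng_seed = 4)
  expect_equal(r1$status, "repaired")
  expect_equal(r2$status, "repaired")
  expect_identical(r1$repaired_file, r2$repaired_file)

  # identical (linearly dependent) deltas: flagged, never silently wrong
  v2 <- sample(nc, 2)
  d <- random_delta(25, nnz = 2)
  b3 <- dr0$b
  b3[v2[1], ] <- xor_raw(b3[v2[1], ], d)
  b3[v2[2], ] <- xor_raw(b3[v2[2], ], d)
  dr3 <- dnarescue:::decode_system(dr0$A, b3, dr0$n_chunks, 0, cfg)
  r3 <- auto_repair_multi(dr3, rng_seed = 4)
  if (r3$status == "repaired")
    expect_identical(r3$repaired_file, data)
  else
    expect_true(r3$status %in% c("candidates_remain", "not_localizable"))
})

test_that("delta propagation is exact, involutive, equals a re-decode", {
  set.seed(17)
  for (i in 1:20) {
    data <- random_file(400, rng_seed = i + 150)
    cfg <- encoder_config(chunk_size = 20, overhead = 4)
    dr0 <- encode_solved(data, cfg, first_seed = i * 211)$dr
    victim <- sample(nrow(dr0$A), 1)
    delta <- random_delta(20)
    dr <- inject_error(dr0, victim, delta)
    # propagating the delta onto the corrupted decode restores the truth
    fixed <- propagate_delta(dr$system, victim, delta)
    truth <- dr0$solution
    expect_identical(fixed, truth)
    # involution: XORing the delta into the affected rows again restores
    # the corrupted solution
    affected <- which(dr$system$tracker[seq_len(dr$n_chunks), victim] == 1L)
    twice <- fixed
    for (k in affected) twice[k, ] <- xor_raw(twice[k, ], delta)
    expect_identical(twice, dr$solution[seq_len(dr$n_chunks), ])
  }
  # zero delta leaves the solution unchanged
  dr0 <- encode_solved(random_file(200, 1),
                       encoder_config(chunk_size = 20, overhead = 3))$dr
  expect_identical(propagate_delta(dr0$system, 1, raw(20)), dr0$solution)
})

test_that("a corrected row yields the delta and its candidate packets", {
  data <- random_file(500, rng_seed = 19)
  cfg <- encoder_config(chunk_size = 25, overhead = 5)
  dr0 <- encode_solved(data, cfg)$dr
  nc <- which(classify_criticality(dr0$A))
  victim <- nc[1]
  delta <- random_delta(25, nnz = 3)
  dr <- inject_error(dr0, victim, delta)
  affected <- which(dr$system$tracker[seq_len(dr$n_chunks), victim] == 1L)
  row <- affected[1]
  fix <- delta_from_row_fix(dr$system, row, dr0$solution[row, ])
  expect_identical(fix$delta, delta)
  expect_true(victim %in% fix$candidates)
  expect_false(fix$zero)
  # propagate the recovered delta through the true packet: file restored
  sol <- propagate_delta(dr$system, victim, fix$delta)
  out <- reassemble_file(sol[seq_len(dr$n_chunks), ])
  expect_identical(out$file, data)
  expect_true(out$crc_ok)

  expect_message(z <- delta_from_row_fix(dr$system, row, dr$solution[row, ]),
                 "zero delta")
  expect_true(z$zero)
})

test_that("criticality flags match the delete-and-decode oracle", {
  # square full-rank: all critical; duplicated row: both copies non-critical
  sys <- random_system(5, 5, 2, seed = 23)
  expect_true(all(!classify_criticality(sys$A)))
  A2 <- rbind(sys$A, sys$A[1, ])
  flags <- classify_criticality(A2)
  expect_true(flags[1])
  expect_true(flags[6])
  expect_true(all(!flags[2:5]))

  set.seed(24)
  for (i in 1:15) {
    M <- sample(6:10, 1)
    N <- sample(4:8, 1)
    A <- matrix(rbinom(M * N, 1, 0.4), M, N)
    A[rowSums(A) == 0, 1] <- 1
    storage.mode(A) <- "integer"
    expect_identical(classify_criticality(A), criticality_oracle(A))
  }
})

test_that("manual row insertion completes an under-determined decode", {
  # craft a text whose second chunk is the known missing line
  chunk_size <- 20
  known <- charToRaw("re lived a king and ")
  expect_equal(length(known), chunk_size)
  rest <- synthetic_text(7 * chunk_size, rng_seed = 30)
  data <- c(known, rest)
  cfg <- encoder_config(chunk_size = chunk_size, overhead = 3)
  # remove every packet covering chunk 2 (the first data chunk)
  mc <- make_missing_chunk_case(data, cfg, chunk = 2)
  dr0 <- mc$dr0
  dru <- mc$dru
  expect_equal(dru$status, "partial")
  expect_false(dru$system$solved_mask[2])

  # inserting the known content completes the decode
  fixed <- insert_manual_row(dru, 2, known)
  expect_equal(fixed$status, "solved")
  expect_identical(fixed$file, data)

  # inserting an all-zero header row exposes remaining rows (with errors)
  drh <- dnarescue:::decode_system(dr0$A[-which(dr0$A[, 1] == 1), ,
                                         drop = FALSE],
                                   dr0$b[-which(dr0$A[, 1] == 1), ,
                                         drop = FALSE],
                                   dr0$n_chunks, 0, cfg)
  if (drh$status == "partial" && !drh$system$solved_mask[1]) {
    drh2 <- insert_manual_row(drh, 1, raw(chunk_size))
    expect_gte(sum(drh2$system$solved_mask),
               sum(drh$system$solved_mask))
  }

  # wrong content: the inserted packet becomes a known corrupted packet
  wrong <- known
  wrong[3] <- xor_raw(wrong[3], as.raw(0x20))
  fixed_wrong <- insert_manual_row(dru, 2, wrong)
  inserted <- nrow(fixed_wrong$A)  # the appended degree-1 row
  if (fixed_wrong$status == "solved") {
    aff <- which(fixed_wrong$system$tracker[seq_len(dr0$n_chunks),
                                            inserted] == 1L)
    row <- aff[1]
    fx <- delta_from_row_fix(fixed_wrong$system, row, dr0$solution[row, ])
    sol <- propagate_delta(fixed_wrong$system, inserted, fx$delta)
    out <- reassemble_file(sol[seq_len(dr0$n_chunks), ])
    expect_identical(out$file, data)
  }

  expect_error(insert_manual_row(dru, 99, known), "out of range")
  expect_warning(insert_manual_row(dru, 2, known[1:5]), "zero-padded")
})

test_that("padding rows surface the injected delta", {
  data <- random_file(400, rng_seed = 33)
  cfg <- encoder_config(chunk_size = 20, overhead = 6,
                        n_padding_chunks = 2)
  dr0 <- encode_solved(data, cfg)$dr
  expect_equal(length(check_padding_rows(dr0)), 0)

  delta <- random_delta(20, nnz = 2)
  nc <- which(classify_criticality(dr0$A))
  dr <- inject_error(dr0, nc[1], delta)
  # the corrupted packet can propagate into several padding rows; at
  # least one must expose the injected delta verbatim
  flags <- check_padding_rows(dr)
  expect_gte(length(flags), 1)
  expect_true(any(vapply(flags, function(f) identical(f$delta, delta),
                         logical(1))))

  # two corruptions cancelling on the same padding row go unseen by this
  # check alone (documented limitation)
  pad_col <- dr0$n_chunks + 1
  on_pad <- which(dr0$A[, pad_col] == 1)
  if (length(on_pad) >= 2) {
    b3 <- dr0$b
    b3[on_pad[1], ] <- xor_raw(b3[on_pad[1], ], delta)
    b3[on_pad[2], ] <- xor_raw(b3[on_pad[2], ], delta)
    dr3 <- dnarescue:::decode_system(dr0$A, b3, dr0$n_chunks,
                                     dr0$n_padding, cfg)
    rows <- vapply(check_padding_rows(dr3), function(f) f$row, numeric(1))
    expect_false(pad_col %in% rows)
  }
})

test_that("candidate enumeration returns exactly the validating file", {
  data <- random_file(600, rng_seed = 35)
  cfg <- encoder_config(chunk_size = 30, overhead = 5)
  dr0 <- encode_solved(data, cfg)$dr
  nc <- which(classify_criticality(dr0$A))
  victim <- nc[1]
  delta <- random_delta(30, nnz = 2)
  dr <- inject_error(dr0, victim, delta)

  beta <- sort(unique(c(victim, sample(nrow(dr$A), 10))))
  en <- enumerate_candidate_files(dr, beta, list(delta))
  expect_true(en$unique)
  expect_identical(en$files[[1]], data)
  expect_equal(en$combos[[1]]$index, victim)

  expect_equal(length(enumerate_candidate_files(dr, integer(0),
                                                list(delta))$files), 0)
  expect_error(enumerate_candidate_files(dr, 1:100,
                                         rep(list(delta), 100), cap = 50),
               "cap")
})
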