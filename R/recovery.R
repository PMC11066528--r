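# Detection, localization and repair of corrupted packets via
# equation-system inconsistencies, row tags, permutation ensembles, delta
# propagation and candidate enumeration.

#' Row tags: decoded chunk rows annotated as correct / incorrect
#'
#' @param correct,incorrect integer vectors of chunk-row indices (disjoint)
#' @return object of class `tag_set`
#' @export
tag_set <- function(correct = integer(0), incorrect = integer(0)) {
  correct <- sort(unique(as.integer(correct)))
  incorrect <- sort(unique(as.integer(incorrect)))
  if (length(intersect(correct, incorrect)) > 0)
    stop("a row cannot be tagged both correct and incorrect")
  structure(list(correct = correct, incorrect = incorrect),
            class = "tag_set")
}

#' Localize corrupted packets from row tags
#'
#' Single-error mode: the candidate set is the intersection of the
#' contribution sets of rows tagged incorrect, minus the union over rows
#' tagged correct.  Multi-error mode replaces the intersection with a
#' union.  Under truthful tags the result always contains the truly
#' corrupted packet(s).
#'
#' @param t a `tracked_system` (or a list of contribution sets indexed by
#'   chunk row, as returned by [contribution_sets()] over all solved rows)
#' @param tags a [tag_set()]
#' @param multi use the multi-error (union) form?
#' @return sorted integer vector of candidate packet indices
#' @export
localize_from_tags <- function(t, tags, multi = FALSE) {
  stopifnot(inherits(tags, "tag_set"))
  sets <- if (inherits(t, "tracked_system")) {
    contribution_sets(t, rows = c(tags$incorrect, tags$correct))
  } else {
    t[as.character(c(tags$incorrect, tags$correct))]
  }
  if (length(tags$incorrect) == 0) {
    if (!multi)
      stop("insufficient tags: at least one row must be tagged incorrect")
    return(integer(0))
  }
  inc_sets <- sets[as.character(tags$incorrect)]
  cand <- if (multi) {
    sort(unique(unlist(inc_sets)))
  } else {
    Reduce(intersect, inc_sets)
  }
  if (length(tags$correct) > 0) {
    cor_union <- unique(unlist(sets[as.character(tags$correct)]))
    cand <- setdiff(cand, cor_union)
  }
  sort(cand)
}

#' Solve the system under several row permutations
#'
#' Computes the tracked elimination of `[A|b]` under the natural row order
#' plus `n_perms - 1` sampled shuffles.  For a consistent system every
#' permutation yields the same solution; for an inconsistent one the
#' reduction path (and hence the decoded rows touched by the corrupted
#' packet) differs, which exposes the error.
#'
#' @param A,b the packet system
#' @param n_perms total number of permutations (>= 2); default
#'   `min(64, 8 * ceiling(log2(M))) + 1`
#' @param rng_seed seed for the permutation sampling
#' @return object of class `permutation_ensemble`: lists `permutations`,
#'   `solutions` (chunk-row raw matrices) and `trackers`
#' @export
permutation_variants <- function(A, b, n_perms = NULL, rng_seed = 1) {
  A <- as_bit_matrix(A)
  b <- as_byte_rows(b, nrow(A))
  M <- nrow(A)
  N <- ncol(A)
  if (is.null(n_perms)) n_perms <- min(24, 8 * ceiling(log2(max(M, 2)))) + 1
  if (n_perms < 2) stop("n_perms must be >= 2")
  perms <- with_local_seed(rng_seed, {
    c(list(seq_len(M)),
      lapply(seq_len(n_perms - 1), function(i) sample.int(M)))
  })
  systems <- lapply(perms, function(p) {
    res <- .gf2_eliminate_cpp(A, b, p - 1L, 0L)
    new_tracked_system(A, b, res, p, "full")
  })
  structure(list(
    permutations = perms,
    solutions = lapply(systems, function(t)
      t$reduced_b[seq_len(N), , drop = FALSE]),
    trackers = lapply(systems, function(t)
      t$tracker[seq_len(N), , drop = FALSE]),
    systems = systems,
    rng_seed = rng_seed
  ), class = "permutation_ensemble")
}

delta_key <- function(delta) paste(as.integer(delta), collapse = ",")
key_to_delta <- function(key) as.raw(as.integer(strsplit(key, ",")[[1]]))

# GF(2) linear-independence filter over byte-vector deltas, preserving
# input order (greedy: keep a delta iff independent of those kept before)
independent_deltas <- function(deltas) {
  basis <- list()  # keyed by leading-bit position (as character)
  keep <- logical(length(deltas))
  for (i in seq_along(deltas)) {
    red <- reduce_against_basis(as.integer(deltas[[i]]), basis)
    if (any(red != 0L)) {
      basis[[as.character(leading_bit(red))]] <- red
      keep[i] <- TRUE
    }
  }
  keep
}

# standard GF(2) XOR-basis reduction: repeatedly cancel the leading bit of v
# against the basis vector stored under that position
reduce_against_basis <- function(v, basis) {
  repeat {
    if (all(v == 0L)) return(v)
    lead <- as.character(leading_bit(v))
    bvec <- basis[[lead]]
    if (is.null(bvec)) return(v)
    v <- bitwXor(v, bvec)
  }
}
leading_bit <- function(v) {
  # (byte index, bit index) flattened: first set bit scanning bytes, MSB first
  for (i in seq_along(v)) {
    if (v[i] != 0L) {
      for (t in 7:0) if (bitwAnd(v[i], bitwShiftL(1L, t)) != 0L)
        return((i - 1L) * 8L + (7L - t))
    }
  }
  -1L
}

# decompose delta v as a GF(2) combination of the (independent) gamma'
# vectors; returns the integer vector of gamma' indices used, or NULL when
# v is not in their span.  Builds an echelon basis that remembers which
# gamma' members each echelon vector combines.
decompose_in_basis <- function(v, gamma_prime) {
  ech <- list()      # leading bit -> vector
  members <- list()  # leading bit -> indices of gamma' combined into it
  for (i in seq_along(gamma_prime)) {
    w <- as.integer(gamma_prime[[i]])
    mem <- i
    repeat {
      if (all(w == 0L)) break  # dependent (cannot happen for gamma')
      lead <- as.character(leading_bit(w))
      if (is.null(ech[[lead]])) {
        ech[[lead]] <- w
        members[[lead]] <- mem
        break
      }
      w <- bitwXor(w, ech[[lead]])
      mem <- sort(c(setdiff(mem, members[[lead]]),
                    setdiff(members[[lead]], mem)))
    }
  }
  v <- as.integer(v)
  used <- integer(0)
  repeat {
    if (all(v == 0L)) return(sort(used))
    lead <- as.character(leading_bit(v))
    if (is.null(ech[[lead]])) return(NULL)
    v <- bitwXor(v, ech[[lead]])
    used <- c(setdiff(used, members[[lead]]),
              setdiff(members[[lead]], used))
  }
}

new_repair_report <- function(status, corrupted_packets = list(),
                              repaired_file = NULL, candidate_files = list(),
                              beta = integer(0), deltas = list(),
                              rng_seed = NA, n_perms = NA, detail = "") {
  structure(list(status = status, corrupted_packets = corrupted_packets,
                 repaired_file = repaired_file,
                 candidate_files = candidate_files, beta = beta,
                 deltas = deltas, rng_seed = rng_seed, n_perms = n_perms,
                 detail = detail),
            class = "repair_report")
}

#' @export
print.repair_report <- function(x, ...) {
  cat("Repair report: status", x$status, "\n")
  if (length(x$corrupted_packets) > 0) {
    for (cp in x$corrupted_packets) {
      cat(sprintf("  packet %d, delta %s\n", cp$index,
                  paste(format(cp$delta[seq_len(min(8, length(cp$delta)))]),
                        collapse = " ")))
    }
  }
  if (length(x$beta) > 0 && x$status != "repaired")
    cat("  candidate packets:", paste(x$beta, collapse = ", "), "\n")
  if (!is.null(x$repaired_file))
    cat(sprintf("  repaired file: %d bytes\n", length(x$repaired_file)))
  if (x$detail != "") cat(" ", x$detail, "\n")
  cat(sprintf("  permutations: %s, rng seed: %s\n", x$n_perms, x$rng_seed))
  invisible(x)
}

# re-decode the system with packet `idx` repaired by `delta`; returns the
# decode_result
redecode_with_fix <- function(dr, idx, delta) {
  b2 <- dr$b
  b2[idx, ] <- xor_raw(b2[idx, ], delta)
  decode_system(dr$A, b2, dr$n_chunks, dr$n_padding, dr$config)
}

# validate a repaired decode: header CRC when present, else consistency;
# an explicit validator(file) overrides
repaired_ok <- function(dr2, validator = NULL) {
  if (dr2$status != "solved") return(FALSE)
  if (dr2$config$use_header && is.null(dr2$file))
    return(FALSE)  # header unparseable: not a valid repair
  if (!is.null(validator)) {
    if (is.null(dr2$file)) return(FALSE)
    return(isTRUE(validator(dr2$file)))
  }
  if (dr2$config$use_header && dr2$config$with_crc)
    return(isTRUE(dr2$crc_ok))
  TRUE
}

# pairwise analysis of a permutation ensemble.
# Returns alpha mask, beta mask, and the per-delta bookkeeping needed by
# both the single- and the multi-error repair.
ensemble_analysis <- function(pv, M) {
  n <- length(pv$solutions)
  N <- nrow(pv$solutions[[1]])
  # deduplicate identical solution outcomes to cut pairwise work
  uniq <- rep(TRUE, n)
  for (i in seq_len(n)[-1]) {
    for (j in which(uniq[seq_len(i - 1)])) {
      if (identical(pv$solutions[[i]], pv$solutions[[j]]) &&
          identical(pv$trackers[[i]], pv$trackers[[j]])) {
        uniq[i] <- FALSE
        break
      }
    }
  }
  sols <- pv$solutions[uniq]
  # raw-typed trackers: byte-wise comparison is far cheaper than integer
  trks <- lapply(pv$trackers[uniq], function(t)
    matrix(as.raw(t), nrow(t), ncol(t)))
  u <- length(sols)

  alpha0 <- logical(M)       # from agreeing rows: packets whose usage
                             # differs yet the row agrees must be correct
  beta_mask <- rep(TRUE, M)  # global p_diff intersection (single error)
  any_diff <- FALSE
  # per-delta bookkeeping: occurrence count, intersection of p_diff masks,
  # union of p_eq masks over the rows that produced it
  dcount <- new.env(parent = emptyenv())
  dmask <- new.env(parent = emptyenv())
  dmask_eq <- new.env(parent = emptyenv())

  if (u >= 2) {
    L <- ncol(sols[[1]])
    for (i in 1:(u - 1)) {
      for (j in (i + 1):u) {
        # vectorized per-pair delta matrix and row keys
        Dx <- matrix(as.raw(bitwXor(as.integer(sols[[i]]),
                                    as.integer(sols[[j]]))), N, L)
        diff_rows <- which(rowSums(Dx != as.raw(0)) > 0)
        agree_rows <- setdiff(seq_len(N), diff_rows)
        T_ne <- trks[[i]] != trks[[j]]
        if (length(agree_rows) > 0) {
          moved <- colSums(T_ne[agree_rows, , drop = FALSE]) > 0
          alpha0 <- alpha0 | moved
        }
        if (length(diff_rows) > 0) {
          any_diff <- TRUE
          T_and <- (trks[[i]] == as.raw(1)) & (trks[[j]] == as.raw(1))
          all_diff <- colMeans(T_ne[diff_rows, , drop = FALSE]) == 1
          beta_mask <- beta_mask & all_diff
          dm <- matrix(as.integer(Dx[diff_rows, , drop = FALSE]),
                       nrow = length(diff_rows))
          keys <- do.call(paste, c(lapply(seq_len(ncol(dm)),
                                          function(cc) dm[, cc]),
                                   list(sep = ",")))
          for (key in unique(keys)) {
            rows_k <- diff_rows[keys == key]
            dcount[[key]] <- (if (is.null(dcount[[key]])) 0L
                              else dcount[[key]]) + length(rows_k)
            m <- colMeans(T_ne[rows_k, , drop = FALSE]) == 1
            dmask[[key]] <- if (is.null(dmask[[key]])) m
                            else dmask[[key]] & m
            me <- colSums(T_and[rows_k, , drop = FALSE]) > 0
            dmask_eq[[key]] <- if (is.null(dmask_eq[[key]])) me
                               else dmask_eq[[key]] | me
          }
        }
      }
    }
  }
  keys <- ls(dcount)
  list(alpha0 = alpha0, beta_mask = beta_mask, any_diff = any_diff,
       delta_keys = keys,
       delta_counts = vapply(keys, function(k) dcount[[k]], integer(1)),
       delta_masks = lapply(keys, function(k) dmask[[k]]),
       delta_eq_masks = lapply(keys, function(k) dmask_eq[[k]]))
}

#' Automatic single-error repair via permutation ensembles
#'
#' Detects an inconsistent system, solves it under several row
#' permutations, derives the set of known-correct packets (alpha) and the
#' candidate corrupted packets (beta) from the pairwise solution
#' differences, and — when the candidate narrows to one packet with one
#' error delta — repairs the original packet, re-decodes and validates
#' (header checksum or a supplied validator).  If several candidates
#' remain and a checksum/validator exists, the remaining combinations are
#' enumerated and the uniquely validating file is accepted.
#'
#' @param dr a `decode_result` (typically with status `"inconsistent"`)
#' @param n_perms number of permutations (see [permutation_variants()])
#' @param rng_seed seed for permutation sampling
#' @param validator optional `function(file) -> logical`
#' @param enumerate_cap cap on candidate (packet, delta) combinations tried
#'   in the enumeration fallback
#' @return a `repair_report`
#' @export
auto_repair_single <- function(dr, n_perms = NULL, rng_seed = 1,
                               validator = NULL, enumerate_cap = 512) {
  stopifnot(inherits(dr, "decode_result"))
  M <- nrow(dr$A)
  if (dr$status == "solved") {
    return(new_repair_report("no_error", repaired_file = dr$file,
                             rng_seed = rng_seed, n_perms = n_perms))
  }
  # fast path for large systems: a small ensemble usually already narrows
  # beta to a singleton; escalate to the full ensemble only when it fails
  if (is.null(n_perms) && M > 64) {
    quick <- auto_repair_single(dr, n_perms = 9, rng_seed = rng_seed,
                                validator = validator,
                                enumerate_cap = min(enumerate_cap, 32))
    if (quick$status %in% c("repaired", "no_error")) return(quick)
  }
  pv <- permutation_variants(dr$A, dr$b, n_perms, rng_seed)
  an <- ensemble_analysis(pv, M)
  if (!an$any_diff) {
    return(new_repair_report("not_localizable", rng_seed = rng_seed,
                             n_perms = length(pv$permutations),
                             detail = paste("no differing solutions across",
                                            "permutations: corrupted packet",
                                            "critical or error consistent")))
  }
  # single-error alpha: agreeing-row evidence plus packets used on both
  # sides of any differing row (valid because there is one corruption)
  alpha <- an$alpha0 | Reduce(`|`, an$delta_eq_masks, logical(M))
  beta <- which(an$beta_mask & !alpha)
  deltas <- lapply(an$delta_keys, key_to_delta)
  np <- length(pv$permutations)

  try_fix <- function(idx, delta) {
    dr2 <- redecode_with_fix(dr, idx, delta)
    if (repaired_ok(dr2, validator)) dr2 else NULL
  }

  if (length(beta) == 1 && length(deltas) == 1) {
    dr2 <- try_fix(beta, deltas[[1]])
    if (!is.null(dr2)) {
      return(new_repair_report(
        "repaired",
        corrupted_packets = list(list(index = beta, delta = deltas[[1]])),
        repaired_file = dr2$file, beta = beta, deltas = deltas,
        rng_seed = rng_seed, n_perms = np))
    }
  }
  # enumeration fallback: only safe when a checksum or validator can vouch
  has_check <- !is.null(validator) ||
    (dr$config$use_header && dr$config$with_crc)
  if (has_check && length(beta) >= 1 &&
      length(beta) * length(deltas) <= enumerate_cap) {
    hits <- list()
    for (idx in beta) {
      for (d in deltas) {
        dr2 <- try_fix(idx, d)
        if (!is.null(dr2))
          hits[[length(hits) + 1]] <- list(index = idx, delta = d,
                                           file = dr2$file)
      }
    }
    files <- unique(lapply(hits, `[[`, "file"))
    if (length(files) == 1) {
      return(new_repair_report(
        "repaired",
        corrupted_packets = list(list(index = hits[[1]]$index,
                                      delta = hits[[1]]$delta)),
        repaired_file = files[[1]], beta = beta, deltas = deltas,
        rng_seed = rng_seed, n_perms = np,
        detail = "validated by checksum enumeration"))
    }
    if (length(files) > 1) {
      return(new_repair_report("candidates_remain", beta = beta,
                               deltas = deltas,
                               candidate_files = files,
                               rng_seed = rng_seed, n_perms = np,
                               detail = "multiple validating candidates"))
    }
  }
  new_repair_report("candidates_remain", beta = beta, deltas = deltas,
                    rng_seed = rng_seed, n_perms = np)
}

#' Automatic multi-error repair
#'
#' Generalizes [auto_repair_single()]: collects the set of all unique
#' solution differences (gamma), orders them by occurrence count
#' (descending) then number of differing bytes (ascending, ties broken
#' lexicographically), greedily keeps a linearly independent subset
#' (gamma'), and for each retained delta computes its own candidate packet
#' set — pairs whose difference is a GF(2) combination of gamma' members
#' containing the target delta also count.  Each (packet, delta) pair is
#' repaired independently, then the result is re-decoded and validated.
#' Errors with linearly dependent deltas are reported unrecoverable rather
#' than silently mis-repaired.
#'
#' @inheritParams auto_repair_single
#' @return a `repair_report`
#' @export
auto_repair_multi <- function(dr, n_perms = NULL, rng_seed = 1,
                              validator = NULL) {
  rep <- repair_multi_once(dr, n_perms, rng_seed, validator,
                           weight_first = FALSE)
  if (rep$status == "repaired") return(rep)
  # the count-based ranking can promote a composite (linearly dependent)
  # delta over a real one; when a checksum can vouch for the outcome, retry
  # with the differing-byte count as the primary sort key
  has_check <- !is.null(validator) ||
    (dr$config$use_header && dr$config$with_crc)
  if (has_check) {
    rep2 <- repair_multi_once(dr, n_perms, rng_seed, validator,
                              weight_first = TRUE)
    if (rep2$status == "repaired") return(rep2)
  }
  rep
}

repair_multi_once <- function(dr, n_perms = NULL, rng_seed = 1,
                              validator = NULL, weight_first = FALSE,
                              .depth = 1) {
  stopifnot(inherits(dr, "decode_result"))
  M <- nrow(dr$A)
  if (dr$status == "solved")
    return(new_repair_report("no_error", repaired_file = dr$file,
                             rng_seed = rng_seed, n_perms = n_perms))
  pv <- permutation_variants(dr$A, dr$b, n_perms, rng_seed)
  an <- ensemble_analysis(pv, M)
  np <- length(pv$permutations)
  if (!an$any_diff)
    return(new_repair_report("not_localizable", rng_seed = rng_seed,
                             n_perms = np))

  deltas <- lapply(an$delta_keys, key_to_delta)
  counts <- an$delta_counts
  nnz <- vapply(deltas, function(d) sum(d != as.raw(0)), integer(1))
  ord <- if (weight_first) order(nnz, -counts, an$delta_keys)
         else order(-counts, nnz, an$delta_keys)
  deltas <- deltas[ord]
  masks <- an$delta_masks[ord]
  counts <- counts[ord]

  keep <- independent_deltas(deltas)
  gamma_prime <- deltas[keep]

  # per-delta alpha: agreeing-row evidence plus p_eq restricted to pairs
  # whose difference is exactly this delta; per-delta beta additionally
  # intersects the p_diff masks of pairs whose difference is a GF(2)
  # combination of gamma' members containing this delta
  eq_masks <- an$delta_eq_masks[ord]
  alpha_l <- vector("list", length(gamma_prime))
  beta_l <- vector("list", length(gamma_prime))
  for (l in seq_along(gamma_prime)) {
    alpha_l[[l]] <- an$alpha0
    beta_l[[l]] <- rep(TRUE, M)
  }
  gk <- which(keep)
  for (d_i in seq_along(deltas)) {
    comp <- decompose_in_basis(deltas[[d_i]], gamma_prime)
    if (is.null(comp)) next
    for (l_idx in comp) {
      beta_l[[l_idx]] <- beta_l[[l_idx]] & masks[[d_i]]
      if (length(comp) == 1 && d_i == gk[l_idx])
        alpha_l[[l_idx]] <- alpha_l[[l_idx]] | eq_masks[[d_i]]
    }
  }
  fixes <- list()
  leftover <- list()
  for (l in seq_along(gamma_prime)) {
    cand <- which(beta_l[[l]] & !alpha_l[[l]])
    if (length(cand) == 1) {
      fixes[[length(fixes) + 1]] <-
        list(index = cand, delta = gamma_prime[[l]])
    } else {
      leftover[[length(leftover) + 1]] <-
        list(beta = cand, delta = gamma_prime[[l]])
    }
  }
  has_check <- !is.null(validator) ||
    (dr$config$use_header && dr$config$with_crc)
  if (length(fixes) > 0) {
    b2 <- dr$b
    for (f in fixes) b2[f$index, ] <- xor_raw(b2[f$index, ], f$delta)
    dr2 <- decode_system(dr$A, b2, dr$n_chunks, dr$n_padding, dr$config)
    if (repaired_ok(dr2, validator)) {
      return(new_repair_report("repaired", corrupted_packets = fixes,
                               repaired_file = dr2$file,
                               deltas = gamma_prime,
                               rng_seed = rng_seed, n_perms = np))
    }
    # confident fixes applied but errors remain: iterate on the partially
    # repaired system (each iteration removes at least one error)
    if (dr2$status == "inconsistent" && .depth < 4) {
      rep2 <- repair_multi_once(dr2, n_perms, rng_seed + .depth, validator,
                                weight_first, .depth = .depth + 1)
      if (rep2$status == "repaired") {
        return(new_repair_report(
          "repaired", corrupted_packets = c(fixes, rep2$corrupted_packets),
          repaired_file = rep2$repaired_file, deltas = gamma_prime,
          rng_seed = rng_seed, n_perms = np))
      }
    }
    fallback <- new_repair_report(
      "candidates_remain", corrupted_packets = fixes,
      beta = sort(unique(unlist(lapply(leftover, `[[`, "beta")))),
      deltas = gamma_prime, rng_seed = rng_seed, n_perms = np,
      detail = paste("partial repair did not validate: remaining errors",
                     "may have linearly dependent deltas"))
  } else {
    fallback <- NULL
  }
  # unresolved candidate sets remain: with a checksum, enumerate the
  # cartesian product of per-delta candidate assignments
  pairs <- c(lapply(fixes, function(f)
               list(beta = f$index, delta = f$delta)),
             leftover)
  sizes <- vapply(pairs, function(p) length(p$beta), integer(1))
  if (has_check && length(pairs) > 0 && all(sizes >= 1) &&
      prod(sizes) <= 512) {
    grid <- as.matrix(expand.grid(lapply(pairs, function(p) p$beta)))
    hits <- list()
    for (g in seq_len(nrow(grid))) {
      b2 <- dr$b
      idxs <- grid[g, ]
      if (anyDuplicated(idxs)) next
      for (q in seq_along(pairs))
        b2[idxs[q], ] <- xor_raw(b2[idxs[q], ], pairs[[q]]$delta)
      dr2 <- decode_system(dr$A, b2, dr$n_chunks, dr$n_padding, dr$config)
      if (repaired_ok(dr2, validator))
        hits[[length(hits) + 1]] <- list(idxs = idxs, file = dr2$file)
    }
    files <- unique(lapply(hits, `[[`, "file"))
    if (length(files) == 1) {
      cps <- lapply(seq_along(pairs), function(q)
        list(index = unname(hits[[1]]$idxs[q]), delta = pairs[[q]]$delta))
      return(new_repair_report(
        "repaired", corrupted_packets = cps,
        repaired_file = files[[1]], deltas = gamma_prime,
        rng_seed = rng_seed, n_perms = np,
        detail = "validated by checksum enumeration"))
    }
  }
  if (!is.null(fallback)) return(fallback)
  new_repair_report(
    if (length(leftover) > 0) "candidates_remain" else "not_localizable",
    beta = sort(unique(unlist(lapply(leftover, `[[`, "beta")))),
    deltas = gamma_prime, rng_seed = rng_seed, n_perms = np,
    detail = if (length(leftover) > 0)
      "no delta narrowed to a single packet" else "")
}

#' Propagate an error delta to every affected decoded row
#'
#' XORs `delta` into exactly the chunk rows whose contribution set contains
#' `packet_index`.  Applying the correct delta of a corrupted packet
#' equals a full re-decode with that packet repaired; applying it twice
#' restores the input (XOR involution).
#'
#' @param t a `tracked_system`
#' @param packet_index original packet (row of `A`)
#' @param delta raw vector of `chunk_size` bytes
#' @return raw matrix: the updated chunk rows
#' @export
propagate_delta <- function(t, packet_index, delta) {
  stopifnot(inherits(t, "tracked_system"))
  N <- ncol(t$A)
  sol <- t$reduced_b[seq_len(N), , drop = FALSE]
  if (length(delta) != ncol(sol)) stop("delta length must equal chunk size")
  affected <- which(t$tracker[seq_len(N), packet_index] == 1L)
  unsolved_hit <- affected[!t$solved_mask[affected]]
  if (length(unsolved_hit) > 0)
    warning("partial propagation: affected rows ",
            paste(unsolved_hit, collapse = ", "), " are unsolved")
  for (k in setdiff(affected, unsolved_hit))
    sol[k, ] <- xor_raw(sol[k, ], delta)
  sol
}

#' Derive the error delta from one manually corrected row
#'
#' The delta is the XOR of the decoded row and its corrected version; the
#' candidate corrupted packets are that row's contribution set (to be
#' narrowed further with tags).
#'
#' @param t a `tracked_system`
#' @param row_index solved chunk row
#' @param corrected_row raw vector of the same length
#' @return list with `candidates` (packet indices) and `delta`; a zero
#'   delta (row already correct) is flagged via `zero = TRUE`
#' @export
delta_from_row_fix <- function(t, row_index, corrected_row) {
  stopifnot(inherits(t, "tracked_system"))
  if (!t$solved_mask[row_index]) stop("row is not solved")
  current <- t$reduced_b[row_index, ]
  if (length(corrected_row) != length(current))
    stop("corrected row length mismatch")
  delta <- xor_raw(current, corrected_row)
  zero <- all(delta == as.raw(0))
  if (zero) message("corrected row equals decoded row: zero delta")
  list(candidates = which(t$tracker[row_index, ] == 1L), delta = delta,
       zero = zero)
}

#' Classify packets as critical / non-critical
#'
#' A packet is non-critical when removing its row from the system does not
#' reduce `rank(A)`; equivalently it participates in a linear dependency
#' among the received packets.  Errors in non-critical packets make the
#' system inconsistent and are therefore automatically detectable.
#'
#' @param A packet bit matrix
#' @return logical vector, `TRUE` = non-critical
#' @export
classify_criticality <- function(A) {
  A <- as_bit_matrix(A)
  as.logical(.gf2_noncritical_cpp(A))
}

#' Insert a manually reconstructed degree-1 row and re-solve
#'
#' Adds a packet mapping directly to `chunk_index` with the supplied
#' content and re-runs decoding.  In an under-determined system this can
#' unlock previously unsolved rows; if the content is wrong the inserted
#' packet becomes a known corrupted packet whose delta can be obtained via
#' [delta_from_row_fix()] on any affected row.
#'
#' @param dr a `decode_result`
#' @param chunk_index chunk the new row maps to
#' @param content raw vector; shorter content is zero-padded with a warning
#' @return a new `decode_result`
#' @export
insert_manual_row <- function(dr, chunk_index, content) {
  stopifnot(inherits(dr, "decode_result"))
  N <- ncol(dr$A)
  if (chunk_index < 1 || chunk_index > N) stop("chunk_index out of range")
  cs <- ncol(dr$b)
  if (length(content) > cs) stop("content longer than chunk size")
  if (length(content) < cs) {
    warning("content shorter than chunk size: zero-padded")
    content <- c(content, raw(cs - length(content)))
  }
  row <- integer(N)
  row[chunk_index] <- 1L
  A2 <- rbind(dr$A, row)
  rownames(A2) <- NULL
  b2 <- rbind(dr$b, matrix(content, nrow = 1))
  decode_system(A2, b2, dr$n_chunks, dr$n_padding, dr$config)
}

#' Inspect padding rows for error deltas
#'
#' With the zero-byte-padding scheme every packet XORs exactly one
#' artificial all-zero chunk.  After decoding, any padding row with
#' non-zero content directly exposes the delta of a corrupted packet
#' (unless several corruptions cancel on the same row).
#'
#' @param dr a `decode_result` from an encoding with padding chunks
#' @return list of `list(row, delta)`, empty when clean
#' @export
check_padding_rows <- function(dr) {
  stopifnot(inherits(dr, "decode_result"))
  if (dr$n_padding == 0) return(list())
  out <- list()
  for (i in seq_len(dr$n_padding)) {
    row <- dr$n_chunks + i
    val <- dr$solution[row, ]
    if (any(val != as.raw(0)))
      out[[length(out) + 1]] <- list(row = row, delta = val)
  }
  out
}

#' Enumerate candidate repaired files over (packet, delta) combinations
#'
#' Applies each candidate repair, re-decodes and keeps the files the
#' validator accepts (header checksum by default).  Exactly one surviving
#' file is flagged `unique`.
#'
#' @param dr a `decode_result`
#' @param beta candidate packet indices
#' @param deltas list of raw candidate deltas
#' @param validator optional `function(file) -> logical`
#' @param cap maximum combinations tried
#' @return list with `files`, `combos` (packet/delta per surviving file)
#'   and `unique`
#' @export
enumerate_candidate_files <- function(dr, beta, deltas, validator = NULL,
                                      cap = 512) {
  stopifnot(inherits(dr, "decode_result"))
  if (length(beta) * length(deltas) > cap)
    stop(sprintf("combination cap exceeded: %d candidates",
                 length(beta) * length(deltas)))
  files <- list()
  combos <- list()
  for (idx in beta) {
    for (d in deltas) {
      dr2 <- redecode_with_fix(dr, idx, d)
      if (repaired_ok(dr2, validator)) {
        is_new <- !any(vapply(files, identical, logical(1), y = dr2$file))
        if (is_new) {
          files[[length(files) + 1]] <- dr2$file
          combos[[length(combos) + 1]] <- list(index = idx, delta = d)
        }
      }
    }
  }
  list(files = files, combos = combos, unique = length(files) == 1)
}
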