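---
title: "Decoder-based and content-based data recovery for fountain-coded DNA storage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoder-based and content-based data recovery for fountain-coded DNA storage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnarescue)
```

## The model

A file is split into $N$ fixed-size chunks (plus a small header chunk
carrying the last-chunk length, the filename and an optional file-wide
CRC-32). Each stored DNA strand carries one *packet*: a seed plus the XOR
of a seed-determined subset of chunks. Collecting $M \ge N$ strands gives
a linear system over GF(2),

$$ A\,x = b, \qquad A \in \mathbb{F}_2^{M \times N}, $$

where row $i$ of $A$ is the indicator vector of the chunks XORed into
packet $i$ and $b_i$ is its payload. Decoding is Gaussian elimination of
$[A \mid b]$. The package's central observation (and the reason the whole
toolkit exists) is what the *redundant* rows buy you beyond erasure
tolerance:

* **Detection.** If one packet's payload is corrupted by a byte delta
  $\delta \ne 0$ and that packet is *non-critical* — removing its row does
  not reduce $\operatorname{rank}(A)$ — then
  $\operatorname{rank}([A \mid b]) = \operatorname{rank}(A) + 1$ and the
  system is inconsistent (Rouché–Capelli). `is_consistent()` tests exactly
  this.
* **Localization.** Eliminating $[A \mid I_M \mid b]$ carries a left
  inverse of $A$: the *contribution set* $S_r$ of decoded row $r$ is the
  set of original packets XOR-combined into it. Tagging decoded rows as
  correct/incorrect constrains the corrupted packet to
  $\bigcap_{r \in \text{bad}} S_r \setminus \bigcup_{r \in \text{good}}
  S_r$ (`localize_from_tags()`), with the intersection replaced by a union
  when several packets may be corrupt.
* **Repair.** For an inconsistent system the reduction result depends on
  the row order. Solving under several row permutations
  (`permutation_variants()`) yields differing versions of affected rows;
  the XOR of two versions of the same row *is* the error delta, and
  comparing which packets the two reduction paths used separates
  known-correct packets ($\alpha$, used on both sides of a differing row,
  or used differently on an agreeing row) from candidates ($\beta$, used
  differently on every differing row). With $\beta$ a singleton and a
  unique delta, `auto_repair_single()` XORs the delta into the packet,
  re-decodes and validates against the stored checksum. Corrections
  propagate: XORing $\delta$ into every row whose contribution set
  contains the repaired packet (`propagate_delta()`) equals a full
  re-decode.

Multiple corruptions are handled by `auto_repair_multi()`: the set of all
observed row differences is ranked by occurrence count (descending) and
number of differing bytes (ascending; ties broken lexicographically), a
linearly independent subset is kept greedily, and each retained delta gets
its own candidate set, counting also row pairs whose difference is a GF(2)
combination of retained deltas. Errors whose deltas are linearly dependent
(e.g. two packets corrupted identically) are structurally invisible to
this ranking; the implementation never applies an unvalidated repair, so
such cases surface as `candidates_remain` rather than a silently wrong
file.

## What is deliberately layered on top of the core

The permutation algebra above is exact but can leave more than one
candidate. Three pragmatic extensions, all checksum-gated, close the gap:

* when $\beta$ is small and a checksum or validator exists, all
  (packet, delta) combinations are enumerated and a repair is accepted
  only if exactly one distinct file validates;
* `auto_repair_multi()` iterates: confidently attributed deltas are
  applied, the smaller problem is re-analyzed (up to three rounds);
* because the count-based ranking can promote a composite delta
  ($\delta_1 \oplus \delta_2$ can outnumber $\delta_1$ when many rows were
  reduced using both corrupted packets), a second pass re-ranks by byte
  weight first. Both passes only ever return a result the checksum
  accepts.

Without a checksum and without a singleton candidate, no repair is applied
— the report carries the candidates and deltas for a user to resolve.

## Content plugins

When the decoder-based route fails (consistent-but-wrong systems, critical
packets), file structure supplies the tags instead. All plugins emit a
byte-granular *error matrix* (valid / unknown / invalid, with suggested
bytes where the format forces a value):

* **Text** (`text_error_histogram()`): a pluggable corrector proposes an
  equal-length corrected version of each decoded row; the reference
  implementation replaces words by the closest equal-length dictionary
  word by Hamming distance, keeping ties unchanged. Because a corrupted
  packet hits the same column of every affected row with the same delta,
  the per-column histogram of decode-vs-corrected deltas separates the
  systematic error from scattered false corrections. Rows the corrector
  silently failed to fix would be falsely tagged correct, so localization
  drops the correct tags and retries on the incorrect tags alone whenever
  the strict tag set annihilates the candidate set.
* **BMP** (`bmp_analyze()`): signature, stored file size, pixel-array
  offset, plane count and the width/height/bits-per-pixel geometry
  (bottom-up rows padded to 4 bytes) are cross-checked against the decoded
  length. `bmp_pixel_to_cells()` translates visually wrong pixels into
  decoded cells for manual tagging. Only uncompressed BI_RGB bitmaps with
  the 40-byte info header or the OS/2 core header are supported.
* **ZIP** (`zip_analyze()`): every duplicated field between a local file
  header and its central-directory twin (CRC-32, sizes, flags, method,
  timestamps, filename) is compared; entry payloads are checked against
  their CRC-32. Headers are found by scanning the whole stream for the
  three signatures, so a corrupted length field cannot truncate a
  following header, and central-directory offsets recover locals the scan
  missed. A field mismatch yields an *alternating pair* (either copy may
  be corrupt); assignments are resolved by the consistency of the implied
  correct/incorrect row partition plus a column-consistency filter (a
  corrupted packet strikes the same columns of all its rows), with
  remaining ties reported as ambiguous and passed to the reparse-validated
  brute force (`zip_bruteforce_repair()`).
* **Upload diff** (`upload_diff()`): any file type; rows differing from a
  partially repaired upload yield per-row deltas directly.

Two further recovery modes need no content at all: degree-1 rows for
missing chunks can be inserted manually (`insert_manual_row()`; wrong
insertions become ordinary corrupted packets repairable by
`delta_from_row_fix()`), and all-zero padding chunks — each packet XORs
exactly one — turn any corruption into a visible non-zero padding row
whose value *is* the delta (`check_padding_rows()`; two corruptions
cancelling on the same padding row evade this check, a documented
limitation).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `chunk_size` | — | payload bytes per packet; with a 300 nt strand and 4-byte seed, 71 bytes |
| `overhead` | 2 | packets beyond the chunk count; drives both erasure tolerance and repairability |
| `distribution` | `"raptor"` | RFC 5053 degree table; `"robust_soliton"` (c = 0.1, δ = 0.05) for chunk counts in the hundreds and beyond |
| `ecc_sym` | 0 | Reed–Solomon parity bytes per strand (2 bytes correct 1 byte error) |
| `n_perms` | `min(24, 8⌈log₂M⌉)+1` (a 9-permutation fast path runs first on large systems) | permutations sampled by the repair ensemble |
| `max_homopolymer`, `gc_min/max`, `window_len` | 3, 0.40–0.60, 50 nt | synthesis constraint screening |
| text threshold | caller-set (tests use 8) | dominant-delta count required to act on a column |

The degree table deserves a note: the shipped `"raptor"` option is the
plain RFC 5053 degree distribution *without* a systematic precode
(precodes are out of scope). Without a precode the table leaves a few
chunks uncovered once the chunk count reaches the hundreds, so encodes at
that scale should either use `"robust_soliton"` or rely on
`ensure_decodable = TRUE`, which resamples seed ranges until the packet
set has full rank. Every experiment below states the distribution it used.

## The seed machinery

Packet seeds feed a fixed 32-bit linear congruential generator
(Numerical Recipes constants) whose state is first passed through a
murmur3-style avalanche mix — sequential seeds must yield decorrelated
chunk selections, which a bare affine generator cannot provide. The same
code runs compiled and as a pure-R reference, and the two are tested for
bit-exact agreement; the platform RNG is never involved, so encoder and
decoder agree across machines and sessions. Host-RNG randomness
(permutation sampling, the corruption channel, experiment repeats) is
always drawn under a locally seeded, restored RNG scope.

## What the synthetic data emulates — and what it does not

The corruption channel substitutes bases independently and drops whole
strands; indels appear only as drops because wrong-length strands are
discarded before decoding (surviving errors are therefore substitutions in
the payload, possibly in the seed — a corrupted seed is treated as a
payload error on the reinterpreted packet). The generated "text" draws
words from a ~100-word lexicon with punctuation: enough to give the
dictionary corrector realistic hit rates, but real prose has richer
vocabulary (more correction false negatives) and real channels have
position-dependent, strand-correlated error profiles. Passing tests
demonstrate the algebra and the plugin logic, not channel realism.

## Numerical and design choices

* Rank and consistency checks append payload bytes as bit columns; payload
  XOR is bytewise. Elimination, tracking and rank live in compiled code;
  pivoting takes the first row in the current order with a 1 in the pivot
  column, so results are deterministic given the row order.
* Information density uses decimal file-size units (1 kB = 1000 B):
  `effective_density(1e5)` with a 300 nt strand, 4-byte seed and overhead
  16 gives 0.9360374269005848, approaching the per-strand bound 284/300
  as the file grows.
* The criticality experiment (19 chunks, overhead 1, 100 repeats) reports
  the mean fraction of packets whose removal leaves the file decodable,
  over decodable encodings: rank-deficient packet sets cannot decode even
  untouched, so the remove-one protocol presupposes a decodable base —
  they are resampled, mirroring an encoder that checks decodability before
  synthesis. With the shipped degree table this lands a little above 40%,
  a few points below the reference value of one half; the gap tracks the
  unknown original degree distribution, which is why the quantity carries
  a wide tolerance.
* The tagging experiment (166 chunks / 170 packets) draws truthful tags
  from the affected/unaffected row pools, capped at 20 valid + 20 invalid
  per run as in the reference design, and records the smallest combined
  count at which localization returns a singleton; runs that do not
  isolate within the cap (about a tenth — packets sharing their exact
  row footprint with another packet can never be isolated by row tags)
  are censored. The average lands around 8–10 tags, comfortably under the
  16 the bound allows. Packets that contributed to no solved row are
  skipped outright: no row tag can refer to them and an error in them
  never reaches the decoded data.
* Test and experiment sizes are desk-scale by design: repair properties
  run on files up to 50 kB and a couple hundred randomized trials;
  `noncritical_curve()` and `min_tags_to_singleton()` expose `repeats`
  for larger runs.

## Known limitations

* A corrupted *critical* packet leaves the system consistent; the decoder
  route cannot see it (`not_localizable`) and recovery must come from the
  content plugins.
* Linearly dependent error deltas defeat the multi-error separation by
  construction; they are flagged, not repaired.
* Repair without any checksum or validator only auto-applies in the
  unambiguous singleton case.
* ZIP64, encrypted entries, compressed BMP variants and quality-score
  (FASTQ) handling are out of scope; the plugin registry is the extension
  point.
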