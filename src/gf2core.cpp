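// Bit-packed GF(2) linear algebra kernels.
//
// Rows of [A | tracker | b] are packed into 64-bit words so that the
// permutation-ensemble repair and the criticality sweeps stay cheap even for
// systems with a few thousand packets.  All indices at this level are 0-based.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct PackedRows {
  int n_rows;
  int n_bits;   // bits per row
  int n_words;  // 64-bit words per row
  std::vector<uint64_t> w;

  PackedRows(int rows, int bits)
      : n_rows(rows), n_bits(bits), n_words((bits + 63) / 64),
        w(static_cast<size_t>(rows) * n_words, 0ULL) {}

  inline uint64_t* row(int r) { return &w[static_cast<size_t>(r) * n_words]; }
  inline bool get(int r, int c) const {
    return (w[static_cast<size_t>(r) * n_words + (c >> 6)] >> (c & 63)) & 1ULL;
  }
  inline void set(int r, int c) {
    w[static_cast<size_t>(r) * n_words + (c >> 6)] |= (1ULL << (c & 63));
  }
  inline void xor_rows(int dst, int src) {
    uint64_t* d = row(dst);
    uint64_t* s = row(src);
    for (int k = 0; k < n_words; ++k) d[k] ^= s[k];
  }
  inline void swap_rows(int a, int b) {
    if (a == b) return;
    uint64_t* pa = row(a);
    uint64_t* pb = row(b);
    for (int k = 0; k < n_words; ++k) std::swap(pa[k], pb[k]);
  }
  inline bool row_zero(int r, int from_bit, int to_bit) const {
    for (int c = from_bit; c < to_bit; ++c)
      if (get(r, c)) return false;
    return true;
  }
};

PackedRows pack_A(const IntegerMatrix& A) {
  PackedRows p(A.nrow(), A.ncol());
  for (int i = 0; i < A.nrow(); ++i)
    for (int j = 0; j < A.ncol(); ++j)
      if (A(i, j)) p.set(i, j);
  return p;
}

// bytes of b appended as bits (MSB of byte 0 first is irrelevant for rank;
// use LSB-first consistently)
PackedRows pack_Ab(const IntegerMatrix& A, const RawMatrix& b) {
  int nb = b.ncol() * 8;
  PackedRows p(A.nrow(), A.ncol() + nb);
  for (int i = 0; i < A.nrow(); ++i) {
    for (int j = 0; j < A.ncol(); ++j)
      if (A(i, j)) p.set(i, j);
    for (int j = 0; j < b.ncol(); ++j) {
      unsigned char byte = b(i, j);
      for (int t = 0; t < 8; ++t)
        if ((byte >> t) & 1) p.set(i, A.ncol() + 8 * j + t);
    }
  }
  return p;
}

int rank_of(PackedRows& p, int n_cols) {
  int pivot_row = 0;
  for (int col = 0; col < n_cols && pivot_row < p.n_rows; ++col) {
    int r = -1;
    for (int i = pivot_row; i < p.n_rows; ++i)
      if (p.get(i, col)) { r = i; break; }
    if (r < 0) continue;
    p.swap_rows(r, pivot_row);
    for (int i = 0; i < p.n_rows; ++i)
      if (i != pivot_row && p.get(i, col)) p.xor_rows(i, pivot_row);
    ++pivot_row;
  }
  return pivot_row;
}

}  // namespace

// [[Rcpp::export(name = ".gf2_rank_cpp")]]
int gf2_rank_cpp(IntegerMatrix A) {
  PackedRows p = pack_A(A);
  return rank_of(p, A.ncol());
}

// rank(A) and rank([A|b]) in one call
// [[Rcpp::export(name = ".gf2_ranks_cpp")]]
IntegerVector gf2_ranks_cpp(IntegerMatrix A, RawMatrix b) {
  PackedRows pa = pack_A(A);
  PackedRows pab = pack_Ab(A, b);
  return IntegerVector::create(rank_of(pa, A.ncol()),
                               rank_of(pab, pab.n_bits));
}

// Tracked Gaussian elimination of [A | I_M | b].
//
// mode = 0: full reduced row echelon form over A's columns; pivot for each
//           column is the first row (in row_order) carrying a 1 there.
// mode = 1: partially solved system: initial diagonal pivoting places (where
//           possible) a row with A[i,i] = 1 at position i; positions that
//           cannot be pivoted are inactivated and their columns skipped.
//
// Output rows are aligned to chunk indices: row i (i < N) is the row whose
// pivot sits in column i (all-zero if that chunk has no pivot); residual
// rows follow after N.  The tracker column space indexes the ORIGINAL rows
// of the input (before row_order is applied).
// [[Rcpp::export(name = ".gf2_eliminate_cpp")]]
List gf2_eliminate_cpp(IntegerMatrix A, RawMatrix b, IntegerVector row_order,
                       int mode) {
  const int M = A.nrow();
  const int N = A.ncol();
  const int L = b.ncol();
  if (b.nrow() != M) stop("A and b row counts differ");
  if (row_order.size() != M) stop("row_order length must equal nrow(A)");

  const int bits_A = N;
  const int bits_T = M;
  const int bits_b = 8 * L;
  PackedRows p(M, bits_A + bits_T + bits_b);

  // apply permutation while packing; tracker identity in original index space
  for (int i = 0; i < M; ++i) {
    int src = row_order[i];
    if (src < 0 || src >= M) stop("row_order out of range");
    for (int j = 0; j < N; ++j)
      if (A(src, j)) p.set(i, j);
    p.set(i, bits_A + src);
    for (int j = 0; j < L; ++j) {
      unsigned char byte = b(src, j);
      for (int t = 0; t < 8; ++t)
        if ((byte >> t) & 1) p.set(i, bits_A + bits_T + 8 * j + t);
    }
  }

  // Full reduced row echelon form over A's columns.  Columns without a
  // pivot are skipped (their chunks are unsolvable from the received
  // rows); a chunk row counts as solved only when it ends with exactly
  // one 1, so the same pass serves both the fully-determined and the
  // partially-solvable case (`mode` is kept for interface stability).
  (void)mode;
  std::vector<int> pivot_of_col(N, -1);  // row position holding pivot of col
  int pivot_row = 0;
  for (int col = 0; col < N && pivot_row < M; ++col) {
    int r = -1;
    for (int i = pivot_row; i < M; ++i)
      if (p.get(i, col)) { r = i; break; }
    if (r < 0) continue;
    p.swap_rows(r, pivot_row);
    for (int i = 0; i < M; ++i)
      if (i != pivot_row && p.get(i, col)) p.xor_rows(i, pivot_row);
    pivot_of_col[col] = pivot_row;
    ++pivot_row;
  }

  // scatter: chunk row i <- row with pivot in column i; rows without a
  // pivot become residual rows after position N-1.  Output has
  // N + (M - n_pivots) rows so every input row keeps a slot even when the
  // system is under-determined.
  int n_pivots = 0;
  for (int col = 0; col < N; ++col)
    if (pivot_of_col[col] >= 0) ++n_pivots;
  const int R_out = N + (M - n_pivots);

  IntegerMatrix RA(R_out, N);
  IntegerMatrix TR(R_out, M);
  RawMatrix RB(R_out, L);
  LogicalVector solved(N);
  std::vector<int> dest(M, -1);
  for (int col = 0; col < N; ++col)
    if (pivot_of_col[col] >= 0) dest[pivot_of_col[col]] = col;
  int tail = N;
  for (int i = 0; i < M; ++i)
    if (dest[i] < 0) dest[i] = tail++;

  for (int i = 0; i < M; ++i) {
    int d = dest[i];
    for (int j = 0; j < N; ++j)
      if (p.get(i, j)) RA(d, j) = 1;
    for (int j = 0; j < M; ++j)
      if (p.get(i, bits_A + j)) TR(d, j) = 1;
    for (int j = 0; j < L; ++j) {
      unsigned char byte = 0;
      for (int t = 0; t < 8; ++t)
        if (p.get(i, bits_A + bits_T + 8 * j + t)) byte |= (1 << t);
      RB(d, j) = byte;
    }
  }

  for (int i = 0; i < N; ++i) {
    bool ok = (RA(i, i) == 1);
    if (ok) {
      for (int j = 0; j < N && ok; ++j)
        if (j != i && RA(i, j)) ok = false;
    }
    solved[i] = ok;
    if (!ok) {
      // unsolved chunk rows carry no trusted content: zero payload
      for (int j = 0; j < L; ++j) RB(i, j) = 0;
    }
  }
  return List::create(_["reduced_A"] = RA, _["tracker"] = TR,
                      _["reduced_b"] = RB, _["solved_mask"] = solved);
}

// Supports of a basis of the left null space of A (row dependencies).
// Returns an M-length logical: true if the row participates in some
// dependency, i.e. the packet is non-critical.
// [[Rcpp::export(name = ".gf2_noncritical_cpp")]]
LogicalVector gf2_noncritical_cpp(IntegerMatrix A) {
  const int M = A.nrow();
  const int N = A.ncol();
  // eliminate [A | I] ; rows whose A-part becomes zero carry null vectors
  PackedRows p(M, N + M);
  for (int i = 0; i < M; ++i) {
    for (int j = 0; j < N; ++j)
      if (A(i, j)) p.set(i, j);
    p.set(i, N + i);
  }
  int pivot_row = 0;
  for (int col = 0; col < N && pivot_row < M; ++col) {
    int r = -1;
    for (int i = pivot_row; i < M; ++i)
      if (p.get(i, col)) { r = i; break; }
    if (r < 0) continue;
    p.swap_rows(r, pivot_row);
    for (int i = 0; i < M; ++i)
      if (i != pivot_row && p.get(i, col)) p.xor_rows(i, pivot_row);
    ++pivot_row;
  }
  LogicalVector out(M);
  for (int i = pivot_row; i < M; ++i) {
    for (int j = 0; j < M; ++j)
      if (p.get(i, N + j)) out[j] = true;
  }
  return out;
}

// CRC-32 (reflected polynomial 0xEDB88320), table-driven
// [[Rcpp::export(name = ".crc32_cpp")]]
double crc32_cpp(RawVector data) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? (0xEDB88320U ^ (c >> 1)) : (c >> 1);
      table[i] = c;
    }
    init = true;
  }
  uint32_t crc = 0xFFFFFFFFU;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFU] ^ (crc >> 8);
  return static_cast<double>(crc ^ 0xFFFFFFFFU);
}

// Deterministic 32-bit linear congruential generator shared by encoder and
// decoder (Numerical Recipes constants).  Returns the updated state.
static inline uint64_t lcg_next(uint64_t s) {
  return (1664525ULL * s + 1013904223ULL) & 0xFFFFFFFFULL;
}

// 32-bit avalanche mix (murmur3 finalizer): sequential packet seeds must
// produce decorrelated streams, which a bare affine generator cannot do.
static inline uint32_t mix32(uint32_t h) {
  h ^= h >> 16; h *= 0x85ebca6bU;
  h ^= h >> 13; h *= 0xc2b2ae35U;
  h ^= h >> 16;
  return h;
}

// Chunk-index selection for one packet seed: draw the degree from the
// cumulative distribution cdf (length = n_chunks-capped degree table), then
// draw distinct chunk indices uniformly.  degrees[k] is the degree that
// cdf[k] corresponds to.
// [[Rcpp::export(name = ".seed_chunks_cpp")]]
IntegerVector seed_chunks_cpp(double seed, int n_chunks,
                              NumericVector cdf, IntegerVector degrees) {
  if (n_chunks < 1) stop("n_chunks must be >= 1");
  uint64_t s = mix32(static_cast<uint32_t>(
      static_cast<uint64_t>(seed) & 0xFFFFFFFFULL));
  s = lcg_next(s);
  double u = static_cast<double>(s) / 4294967296.0;
  int deg = degrees[degrees.size() - 1];
  for (int k = 0; k < cdf.size(); ++k)
    if (u < cdf[k]) { deg = degrees[k]; break; }
  if (deg > n_chunks) deg = n_chunks;
  if (deg < 1) deg = 1;
  std::vector<bool> used(n_chunks, false);
  IntegerVector out(deg);
  int got = 0;
  while (got < deg) {
    s = lcg_next(s);
    int idx = static_cast<int>(
        (static_cast<double>(s) / 4294967296.0) * n_chunks);
    if (idx >= n_chunks) idx = n_chunks - 1;
    if (!used[idx]) {
      used[idx] = true;
      out[got++] = idx;
    }
  }
  std::sort(out.begin(), out.end());
  return out;
}
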