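#include <Rcpp.h>
#include <cstring>
#include <cstdint>
using namespace Rcpp;

// Alphabet: A=0 C=1 G=2 T=3, anything else (incl. N) = 4.  Code 4 never
// matches, not even itself.
static inline int enc_base(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

// Scoring (fixed; recorded in the package config): match +1, mismatch -2,
// gap -4 for the first gapped column and -1 for each additional column of
// the same gap.  End gaps on either sequence are free and never scored.
static const int S_MATCH = 1;
static const int S_MISMATCH = -2;
static const int S_GAP_OPEN = -4;   // cost of the first gap column
static const int S_GAP_EXT = -1;    // cost of each further gap column
static const int NEG_INF = INT32_MIN / 4;

// Affine-gap pairwise alignment of a vs b.
//
// mode fit (global = false): semi-global alignment in which the shorter
// sequence is aligned over its whole length and the longer sequence has
// free, unscored end gaps.  identity = 100 * matches / columns where
// columns counts every column of that alignment (internal gaps included,
// terminal overhangs of the longer sequence excluded), so columns >=
// min(length a, length b).  A short sequence exactly contained in a
// longer one scores 100; unrelated full-length pairs score near the
// random-background identity because the shorter sequence cannot escape
// into a tiny local overlap.
//
// mode global (global = true): both sequences consumed end to end, end
// gaps charged.  Used internally for the chimera two-segment profiles,
// where a prefix-anchored match profile along the whole query is needed
// (an overlap alignment of a half-matching pair collapses instead of
// covering the matching half).  Terminal gap runs at the very ends are
// not counted into columns.
//
// If want_prefix, additionally returns an integer vector pm of length
// nchar(a)+1 with pm[i+1] = number of match columns whose a-position is
// < i (0-based; pm[1] = 0 and pm[nchar(a)+1] = matches).
// [[Rcpp::export]]
List cpp_align_overlap(std::string a, std::string b, bool want_prefix = false,
                       bool global = false) {
  if (a.size() == 0 || b.size() == 0) stop("sequences must be non-empty");
  // fit mode: a is the fully aligned (shorter) sequence
  if (!global && a.size() > b.size()) std::swap(a, b);
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int8_t> ea(n), eb(m);
  for (int i = 0; i < n; ++i) ea[i] = enc_base(a[i]);
  for (int j = 0; j < m; ++j) eb[j] = enc_base(b[j]);

  const size_t W = (size_t)m + 1;
  // rolling score rows for the three states:
  // M diag, X gap-in-b (consumes a), Y gap-in-a (consumes b)
  std::vector<int> Mp(W, NEG_INF), Xp(W, NEG_INF), Yp(W, NEG_INF);
  std::vector<int> Mc(W, NEG_INF), Xc(W, NEG_INF), Yc(W, NEG_INF);
  // packed traceback byte per cell: bits 0-1 = M predecessor
  // (0 start, 1 M, 2 X, 3 Y); bit 2 = X extends X; bit 3 = Y extends Y
  std::vector<uint8_t> tb((size_t)(n + 1) * W, 0);
  std::vector<int> lastcolM((size_t)n + 1, NEG_INF); // M score at column m

  if (global) {
    Mp[0] = 0;                                   // the (0,0) start
    for (int j = 1; j <= m; ++j) Yp[j] = S_GAP_OPEN + (j - 1) * S_GAP_EXT;
  }
  for (int i = 1; i <= n; ++i) {
    std::fill(Mc.begin(), Mc.end(), NEG_INF);
    Xc[0] = global ? S_GAP_OPEN + (i - 1) * S_GAP_EXT : NEG_INF;
    Yc[0] = NEG_INF;
    uint8_t *trow = &tb[(size_t)i * W];
    const int8_t ai = ea[i - 1];
    const bool edge_i = (i == 1);
    for (int j = 1; j <= m; ++j) {
      // M: diagonal move
      int best, t;
      // fit mode: a fresh start (leading free gap in b) only on a's
      // first base; global mode: only at (1,1)
      const bool fresh = global ? (edge_i && j == 1) : edge_i;
      if (fresh) { best = 0; t = 0; } else { best = NEG_INF; t = 0; }
      int v = Mp[j - 1]; if (v > best) { best = v; t = 1; }
      v = Xp[j - 1];     if (v > best) { best = v; t = 2; }
      v = Yp[j - 1];     if (v > best) { best = v; t = 3; }
      const bool is_match = ai == eb[j - 1] && ai != 4;
      Mc[j] = best + (is_match ? S_MATCH : S_MISMATCH);
      // X: gap column in b (a[i-1] vs '-')
      int fromM = Mp[j] + S_GAP_OPEN;
      int fromX = Xp[j] + S_GAP_EXT;
      if (fromM >= fromX) Xc[j] = fromM;
      else { Xc[j] = fromX; t |= 4; }
      // Y: gap column in a ('-' vs b[j-1])
      fromM = Mc[j - 1] + S_GAP_OPEN;
      int fromY = Yc[j - 1] + S_GAP_EXT;
      if (fromM >= fromY) Yc[j] = fromM;
      else { Yc[j] = fromY; t |= 8; }
      trow[j] = (uint8_t)t;
    }
    lastcolM[i] = Mc[m];
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  // after the loop Mp/Xp/Yp hold row n

  int bestScore = NEG_INF, bi = -1, bj = -1;
  uint8_t state = 1;
  if (global) {
    bi = n; bj = m;
    bestScore = Mp[m]; state = 1;
    if (Xp[m] > bestScore) { bestScore = Xp[m]; state = 2; }
    if (Yp[m] > bestScore) { bestScore = Yp[m]; state = 3; }
  } else {
    // fit mode: a fully consumed; end anywhere on the last row, in state
    // M (the trailing gap in b is free and unscored)
    for (int j = 1; j <= m; ++j) {
      if (Mp[j] > bestScore) { bestScore = Mp[j]; bi = n; bj = j; }
    }
  }

  // traceback over the packed byte matrix
  int matches = 0, columns = 0;
  std::vector<int> matchAt;           // 0-based a positions of match columns
  int i = bi, j = bj;
  int a_end = bi, b_end = bj, a_start = bi, b_start = bj;
  while (i > 0 && j > 0) {
    const uint8_t t = tb[(size_t)i * W + j];
    if (state == 1) {
      ++columns;
      if (ea[i - 1] == eb[j - 1] && ea[i - 1] != 4) {
        ++matches;
        if (want_prefix) matchAt.push_back(i - 1);
      }
      uint8_t pred = t & 3;
      --i; --j;
      a_start = i; b_start = j;
      if (pred == 0) break;
      state = pred;
    } else if (state == 2) { // X: gap in b
      ++columns;
      state = (t & 4) ? 2 : 1;
      --i;
    } else { // Y: gap in a
      ++columns;
      state = (t & 8) ? 3 : 1;
      --j;
    }
  }

  double identity = columns > 0 ? 100.0 * (double)matches / (double)columns
                                : 0.0;
  List out = List::create(
    _["identity"] = identity,
    _["matches"] = matches,
    _["columns"] = columns,
    _["score"] = bestScore,
    _["a_start"] = a_start, _["a_end"] = a_end,
    _["b_start"] = b_start, _["b_end"] = b_end);
  if (want_prefix) {
    IntegerVector pm(n + 1);
    std::vector<int> cnt(n, 0);
    for (size_t p = 0; p < matchAt.size(); ++p) cnt[matchAt[p]] = 1;
    int acc = 0;
    pm[0] = 0;
    for (int p = 0; p < n; ++p) { acc += cnt[p]; pm[p + 1] = acc; }
    out["prefix_matches"] = pm;
  }
  return out;
}

// Ungapped sliding-window scan of `oligo` along `query` (single strand).
// Returns a matrix with one row per occurrence with <= max_mm mismatches:
// columns start (0-based), mismatches.  A query shorter than the oligo
// yields zero rows.
// [[Rcpp::export]]
IntegerMatrix cpp_oligo_scan(std::string query, std::string oligo, int max_mm) {
  const int n = (int)query.size(), k = (int)oligo.size();
  std::vector<int8_t> eq(n), eo(k);
  for (int i = 0; i < n; ++i) eq[i] = enc_base(query[i]);
  for (int i = 0; i < k; ++i) eo[i] = enc_base(oligo[i]);
  std::vector<int> starts, mms;
  for (int s = 0; s + k <= n; ++s) {
    int mm = 0;
    for (int t = 0; t < k; ++t) {
      if (eq[s + t] != eo[t] || eo[t] == 4) {
        if (++mm > max_mm) break;
      }
    }
    if (mm <= max_mm) { starts.push_back(s); mms.push_back(mm); }
  }
  IntegerMatrix out((int)starts.size(), 2);
  for (int r = 0; r < (int)starts.size(); ++r) {
    out(r, 0) = starts[r];
    out(r, 1) = mms[r];
  }
  colnames(out) = CharacterVector::create("start", "mismatches");
  return out;
}

static inline int kmer_code(const int8_t *e, int k) {
  int code = 0;
  for (int t = 0; t < k; ++t) {
    if (e[t] == 4) return -1;
    code = (code << 2) | e[t];
  }
  return code;
}

// Presence bitsets of all k-mers of each sequence; one column per sequence,
// 4^k / 8 bytes per column.  k <= 10.
// [[Rcpp::export]]
RawMatrix cpp_kmer_index(CharacterVector seqs, int k) {
  if (k < 4 || k > 10) stop("k must be in [4, 10]");
  const int nbits = 1 << (2 * k);
  const int nbytes = nbits / 8;
  RawMatrix idx(nbytes, seqs.size());
  for (int s = 0; s < seqs.size(); ++s) {
    std::string sq = as<std::string>(seqs[s]);
    const int n = (int)sq.size();
    std::vector<int8_t> e(n);
    for (int i = 0; i < n; ++i) e[i] = enc_base(sq[i]);
    for (int p = 0; p + k <= n; ++p) {
      int code = kmer_code(&e[p], k);
      if (code >= 0) idx(code >> 3, s) |= (Rbyte)(1 << (code & 7));
    }
  }
  return idx;
}

// Number of distinct k-mers of `query` present in each indexed sequence.
// [[Rcpp::export]]
IntegerVector cpp_kmer_shared(std::string query, RawMatrix idx, int k) {
  const int nbits = 1 << (2 * k);
  if (idx.nrow() != nbits / 8) stop("index does not match k");
  const int n = (int)query.size();
  std::vector<int8_t> e(n);
  for (int i = 0; i < n; ++i) e[i] = enc_base(query[i]);
  std::vector<uint8_t> qbits(nbits / 8, 0);
  for (int p = 0; p + k <= n; ++p) {
    int code = kmer_code(&e[p], k);
    if (code >= 0) qbits[code >> 3] |= (uint8_t)(1 << (code & 7));
  }
  IntegerVector out(idx.ncol());
  static const int8_t popc[256] = {
#define B2(x) x, x + 1, x + 1, x + 2
#define B4(x) B2(x), B2(x + 1), B2(x + 1), B2(x + 2)
#define B6(x) B4(x), B4(x + 1), B4(x + 1), B4(x + 2)
    B6(0), B6(1), B6(1), B6(2)
#undef B2
#undef B4
#undef B6
  };
  for (int s = 0; s < idx.ncol(); ++s) {
    int cnt = 0;
    for (int b = 0; b < nbits / 8; ++b)
      cnt += popc[(uint8_t)(idx(b, s) & qbits[b])];
    out[s] = cnt;
  }
  return out;
}

// Shared distinct k-mers between two indexed sequences (1-based columns).
// [[Rcpp::export]]
int cpp_kmer_shared_cols(RawMatrix idx, int i, int j) {
  if (i < 1 || j < 1 || i > idx.ncol() || j > idx.ncol()) {
    stop("column index out of range");
  }
  static const int8_t popc[256] = {
#define B2(x) x, x + 1, x + 1, x + 2
#define B4(x) B2(x), B2(x + 1), B2(x + 1), B2(x + 2)
#define B6(x) B4(x), B4(x + 1), B4(x + 1), B4(x + 2)
    B6(0), B6(1), B6(1), B6(2)
#undef B2
#undef B4
#undef B6
  };
  int cnt = 0;
  for (int b = 0; b < idx.nrow(); ++b) {
    cnt += popc[(uint8_t)(idx(b, i - 1) & idx(b, j - 1))];
  }
  return cnt;
}

// Number of distinct k-mers per indexed sequence (popcount per column).
// [[Rcpp::export]]
IntegerVector cpp_kmer_card(RawMatrix idx) {
  static const int8_t popc[256] = {
#define B2(x) x, x + 1, x + 1, x + 2
#define B4(x) B2(x), B2(x + 1), B2(x + 1), B2(x + 2)
#define B6(x) B4(x), B4(x + 1), B4(x + 1), B4(x + 2)
    B6(0), B6(1), B6(1), B6(2)
#undef B2
#undef B4
#undef B6
  };
  IntegerVector out(idx.ncol());
  for (int s = 0; s < idx.ncol(); ++s) {
    int cnt = 0;
    for (int b = 0; b < idx.nrow(); ++b) cnt += popc[(uint8_t)idx(b, s)];
    out[s] = cnt;
  }
  return out;
}

// Number of distinct k-mers of a single sequence.
// [[Rcpp::export]]
int cpp_kmer_count(std::string seq, int k) {
  const int n = (int)seq.size();
  std::vector<int8_t> e(n);
  for (int i = 0; i < n; ++i) e[i] = enc_base(seq[i]);
  std::vector<uint8_t> bits((size_t)1 << (2 * k - 3), 0);
  int cnt = 0;
  for (int p = 0; p + k <= n; ++p) {
    int code = kmer_code(&e[p], k);
    if (code >= 0) {
      uint8_t m = (uint8_t)(1 << (code & 7));
      if (!(bits[code >> 3] & m)) { bits[code >> 3] |= m; ++cnt; }
    }
  }
  return cnt;
}
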