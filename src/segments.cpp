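#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Shared haplotype segments are maximal runs of marker-wise allele identity
// between two haplotypes within a chromosome. A run qualifies if it contains
// at least `min_markers` markers and spans at least `min_len_bp` base pairs
// (first to last marker of the run). Chromosome blocks come in as 0-based
// inclusive [chr_start, chr_end] index pairs.
//
// Haplotypes are bit-packed into 64-bit words so that identity runs between
// two haplotypes can be scanned word-wise (XOR + count-trailing-zeros),
// which makes the all-pairs scans cheap even for large panels.

struct Run { int start; int end; };

static std::vector<uint64_t> pack_columns(const IntegerMatrix &H, int &W) {
  const int m = H.nrow(), nh = H.ncol();
  W = (m + 63) / 64;
  std::vector<uint64_t> P((size_t)nh * W, 0ULL);
  for (int j = 0; j < nh; ++j) {
    const int *h = &H(0, j);
    uint64_t *p = &P[(size_t)j * W];
    for (int i = 0; i < m; ++i)
      if (h[i]) p[i >> 6] |= 1ULL << (i & 63);
  }
  return P;
}

// Maximal runs of equal bits between packed columns a and b over [0, m).
static void equal_runs(const uint64_t *a, const uint64_t *b, int W, int m,
                       int min_run, std::vector<Run> &zr) {
  zr.clear();
  int run_start = -1;
  for (int w = 0; w < W; ++w) {
    uint64_t d = a[w] ^ b[w];
    if (w == W - 1 && (m & 63))
      d |= (~0ULL) << (m & 63);  // pad tail bits as mismatches
    const int base = w << 6;
    if (d == 0) {
      if (run_start < 0) run_start = base;
      continue;
    }
    int pos = 0;
    while (pos < 64) {
      uint64_t rest = d >> pos;
      if (rest & 1ULL) {  // mismatch stretch starting at base + pos
        if (run_start >= 0) {
          if (base + pos - run_start >= min_run) {
            Run r; r.start = run_start; r.end = base + pos - 1;
            zr.push_back(r);
          }
          run_start = -1;
        }
        uint64_t inv = ~rest;
        pos += inv ? __builtin_ctzll(inv) : 64;  // skip the whole stretch
      } else {
        if (run_start < 0) run_start = base + pos;
        if (rest == 0) break;
        pos += __builtin_ctzll(rest);
      }
    }
  }
  if (run_start >= 0 && m - run_start >= min_run) {
    Run r; r.start = run_start; r.end = m - 1;
    zr.push_back(r);
  }
}

// Split equal runs at chromosome boundaries and keep qualifying pieces.
static void qualifying_runs(const uint64_t *a, const uint64_t *b, int W,
                            int m, const int *cs, const int *ce, int nchr,
                            const double *pos, int min_markers,
                            double min_len_bp, std::vector<Run> &scratch,
                            std::vector<Run> &out) {
  out.clear();
  equal_runs(a, b, W, m, min_markers, scratch);
  int c = 0;
  for (size_t k = 0; k < scratch.size(); ++k) {
    while (c > 0 && cs[c] > scratch[k].start) --c;
    while (c < nchr - 1 && ce[c] < scratch[k].start) ++c;
    for (int cc = c; cc < nchr && cs[cc] <= scratch[k].end; ++cc) {
      int s = scratch[k].start > cs[cc] ? scratch[k].start : cs[cc];
      int e = scratch[k].end < ce[cc] ? scratch[k].end : ce[cc];
      if (s > e) continue;
      if (e - s + 1 >= min_markers && pos[e] - pos[s] >= min_len_bp) {
        Run r; r.start = s; r.end = e;
        out.push_back(r);
      }
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_pair_runs(IntegerVector h1, IntegerVector h2,
                            IntegerVector chr_start, IntegerVector chr_end,
                            NumericVector pos, int min_markers,
                            double min_len_bp) {
  const int m = h1.size();
  IntegerMatrix H(m, 2);
  for (int i = 0; i < m; ++i) { H(i, 0) = h1[i]; H(i, 1) = h2[i]; }
  int W;
  std::vector<uint64_t> P = pack_columns(H, W);
  std::vector<Run> scratch, runs;
  qualifying_runs(&P[0], &P[W], W, m, INTEGER(chr_start), INTEGER(chr_end),
                  chr_start.size(), REAL(pos), min_markers, min_len_bp,
                  scratch, runs);
  IntegerMatrix out(runs.size(), 2);
  for (size_t i = 0; i < runs.size(); ++i) {
    out(i, 0) = runs[i].start + 1;  // 1-based for R
    out(i, 1) = runs[i].end + 1;
  }
  return out;
}

// Haplotype-by-haplotype coverage matrix: fraction of the genome (by the
// supplied weights, which should sum to 1) covered by qualifying shared
// segments of each haplotype pairing. Diagonal is 1 by convention (an
// allele always shares a segment with itself).
// [[Rcpp::export]]
NumericMatrix cpp_coverage_matrix(IntegerMatrix H, IntegerVector chr_start,
                                  IntegerVector chr_end, NumericVector pos,
                                  NumericVector w, int min_markers,
                                  double min_len_bp) {
  const int nh = H.ncol(), m = H.nrow(), nchr = chr_start.size();
  int W;
  std::vector<uint64_t> P = pack_columns(H, W);
  std::vector<double> cw(m + 1, 0.0);  // prefix sums of weights
  for (int i = 0; i < m; ++i) cw[i + 1] = cw[i] + w[i];
  NumericMatrix cov(nh, nh);
  std::vector<Run> scratch, runs;
  for (int a = 0; a < nh; ++a) {
    cov(a, a) = 1.0;
    for (int b = a + 1; b < nh; ++b) {
      qualifying_runs(&P[(size_t)a * W], &P[(size_t)b * W], W, m,
                      INTEGER(chr_start), INTEGER(chr_end), nchr,
                      REAL(pos), min_markers, min_len_bp, scratch, runs);
      double tot = 0.0;
      for (size_t k = 0; k < runs.size(); ++k)
        tot += cw[runs[k].end + 1] - cw[runs[k].start];
      cov(a, b) = cov(b, a) = tot;
    }
  }
  return cov;
}

// For each focal haplotype (column of Hf), count how many reference
// haplotypes (columns of Hr) share a qualifying segment covering each
// marker. Returns a markers x n_focal integer matrix of counts.
// [[Rcpp::export]]
IntegerMatrix cpp_share_counts(IntegerMatrix Hf, IntegerMatrix Hr,
                               IntegerVector chr_start, IntegerVector chr_end,
                               NumericVector pos, int min_markers,
                               double min_len_bp) {
  const int m = Hf.nrow(), nf = Hf.ncol(), nr = Hr.ncol();
  const int nchr = chr_start.size();
  int W;
  IntegerMatrix both(m, nf + nr);
  for (int j = 0; j < nf; ++j)
    for (int i = 0; i < m; ++i) both(i, j) = Hf(i, j);
  for (int j = 0; j < nr; ++j)
    for (int i = 0; i < m; ++i) both(i, nf + j) = Hr(i, j);
  std::vector<uint64_t> P = pack_columns(both, W);
  IntegerMatrix counts(m, nf);
  std::vector<Run> scratch, runs;
  for (int j = 0; j < nf; ++j) {
    int *cj = &counts(0, j);
    for (int k = 0; k < nr; ++k) {
      qualifying_runs(&P[(size_t)j * W], &P[(size_t)(nf + k) * W], W, m,
                      INTEGER(chr_start), INTEGER(chr_end), nchr,
                      REAL(pos), min_markers, min_len_bp, scratch, runs);
      for (size_t q = 0; q < runs.size(); ++q)
        for (int p = runs[q].start; p <= runs[q].end; ++p) ++cj[p];
    }
  }
  return counts;
}

// Numerator for kinship at native alleles, per haplotype pairing: genome
// weight of positions that lie on a qualifying shared segment of the
// pairing AND are native on both haplotypes. Diagonal: weight of the
// haplotype's own native positions.
// [[Rcpp::export]]
NumericMatrix cpp_native_shared(IntegerMatrix H, LogicalMatrix native,
                                IntegerVector chr_start, IntegerVector chr_end,
                                NumericVector pos, NumericVector w,
                                int min_markers, double min_len_bp) {
  const int nh = H.ncol(), m = H.nrow(), nchr = chr_start.size();
  int W;
  std::vector<uint64_t> P = pack_columns(H, W);
  NumericMatrix num(nh, nh);
  std::vector<Run> scratch, runs;
  for (int a = 0; a < nh; ++a) {
    const int *na = &native(0, a);
    double self = 0.0;
    for (int p = 0; p < m; ++p) if (na[p]) self += w[p];
    num(a, a) = self;
    for (int b = a + 1; b < nh; ++b) {
      const int *nb = &native(0, b);
      qualifying_runs(&P[(size_t)a * W], &P[(size_t)b * W], W, m,
                      INTEGER(chr_start), INTEGER(chr_end), nchr,
                      REAL(pos), min_markers, min_len_bp, scratch, runs);
      double tot = 0.0;
      for (size_t k = 0; k < runs.size(); ++k)
        for (int p = runs[k].start; p <= runs[k].end; ++p)
          if (na[p] && nb[p]) tot += w[p];
      num(a, b) = num(b, a) = tot;
    }
  }
  return num;
}
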