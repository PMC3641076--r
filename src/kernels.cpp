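#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <limits>
#include <cstdint>

using namespace Rcpp;

namespace {

const double NEG_INF = -std::numeric_limits<double>::infinity();

// Affine-gap global alignment with free terminal gaps (Gotoh).
// States: M = column with characters in both rows; X = gap in b (consume a,
// "up"); Y = gap in a (consume b, "left").  A gap run of length L costs
// gap_open + L * gap_extend; terminal gap runs cost nothing.
// Tie-breaks are fixed so the traceback is bit-reproducible:
// end cell corner > last column (larger i) > last row (larger j);
// state order M > X > Y (diagonal > up > left).
struct AlignResult {
  std::string a_aln;
  std::string b_aln;
  double score;
};

inline double subst(char ca, char cb, double match, double mismatch) {
  return (ca == cb) ? match : mismatch;
}

AlignResult nw_align_impl(const std::string &a, const std::string &b,
                          double match, double mismatch,
                          double gap_open, double gap_extend,
                          bool free_ends) {
  const size_t na = a.size(), nb = b.size();
  const size_t W = nb + 1;
  // DP matrices, (na+1) x (nb+1), row-major; buffers reused across calls
  static thread_local std::vector<double> M, X, Y;
  M.assign((na + 1) * W, NEG_INF);
  X.assign((na + 1) * W, NEG_INF);
  Y.assign((na + 1) * W, NEG_INF);
  auto at = [W](size_t i, size_t j) { return i * W + j; };

  M[0] = 0.0;
  if (free_ends) {
    for (size_t i = 1; i <= na; ++i) X[i * W] = 0.0;  // free leading gaps
    for (size_t j = 1; j <= nb; ++j) Y[j] = 0.0;
  } else {
    for (size_t i = 1; i <= na; ++i)
      X[i * W] = gap_open + (double)i * gap_extend;
    for (size_t j = 1; j <= nb; ++j)
      Y[j] = gap_open + (double)j * gap_extend;
  }

  const double go_ge = gap_open + gap_extend;
  for (size_t i = 1; i <= na; ++i) {
    const char ca = a[i - 1];
    const double *Mp = &M[(i - 1) * W], *Xp = &X[(i - 1) * W],
                 *Yp = &Y[(i - 1) * W];
    double *Mc = &M[i * W], *Xc = &X[i * W], *Yc = &Y[i * W];
    for (size_t j = 1; j <= nb; ++j) {
      const double s = (ca == b[j - 1]) ? match : mismatch;
      const double diag = std::max(Mp[j - 1], std::max(Xp[j - 1], Yp[j - 1]));
      Mc[j] = s + diag;
      Xc[j] = std::max(std::max(Mp[j], Yp[j]) + go_ge, Xp[j] + gap_extend);
      Yc[j] = std::max(std::max(Mc[j - 1], Xc[j - 1]) + go_ge,
                       Yc[j - 1] + gap_extend);
    }
  }

  auto H = [&](size_t i, size_t j) {
    return std::max(M[at(i, j)], std::max(X[at(i, j)], Y[at(i, j)]));
  };

  // End point: the corner under penalized ends; with free trailing gaps,
  // the best cell over the corner, last column and last row.
  size_t ei = na, ej = nb;
  double best = H(na, nb);
  if (free_ends) {
    for (size_t i = na; i-- > 0;) {      // last column, decreasing i
      if (H(i, nb) > best) { best = H(i, nb); ei = i; ej = nb; }
    }
    for (size_t j = nb; j-- > 0;) {      // last row, decreasing j
      if (H(na, j) > best) { best = H(na, j); ei = na; ej = j; }
    }
  }

  std::string ra, rb;  // built reversed
  // Trailing free gaps
  for (size_t j = nb; j > ej; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }
  for (size_t i = na; i > ei; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }

  // State at the end cell: M > X > Y
  size_t i = ei, j = ej;
  int st;
  {
    const double m = M[at(i, j)], x = X[at(i, j)], y = Y[at(i, j)];
    if (m >= x && m >= y) st = 0; else if (x >= y) st = 1; else st = 2;
  }
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (st == 0) {              // M: consumed a[i-1], b[j-1]
      if (i == 0 || j == 0) break;  // M undefined at border except (0,0)
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      const double need = M[at(i, j)] -
        subst(a[i - 1], b[j - 1], match, mismatch);
      --i; --j;
      if (i == 0 && j == 0) break;
      const double m = M[at(i, j)], x = X[at(i, j)], y = Y[at(i, j)];
      if (std::abs(m - need) < eps) st = 0;
      else if (std::abs(x - need) < eps) st = 1;
      else st = 2;
      (void)y;
    } else if (st == 1) {       // X: gap in b, consumed a[i-1]
      ra.push_back(a[i - 1]); rb.push_back('-');
      if (j == 0) { --i; st = 1; continue; }  // leading free gap region
      const double val = X[at(i, j)];
      const double upM = M[at(i - 1, j)], upX = X[at(i - 1, j)],
                   upY = Y[at(i - 1, j)];
      --i;
      if (std::abs(upM + gap_open + gap_extend - val) < eps) st = 0;
      else if (std::abs(upX + gap_extend - val) < eps) st = 1;
      else if (std::abs(upY + gap_open + gap_extend - val) < eps) st = 2;
      else st = 1;  // free leading gap column (X[i][0] == 0 path)
    } else {                    // Y: gap in a, consumed b[j-1]
      ra.push_back('-'); rb.push_back(b[j - 1]);
      if (i == 0) { --j; st = 2; continue; }
      const double val = Y[at(i, j)];
      const double lfM = M[at(i, j - 1)], lfX = X[at(i, j - 1)],
                   lfY = Y[at(i, j - 1)];
      --j;
      if (std::abs(lfM + gap_open + gap_extend - val) < eps) st = 0;
      else if (std::abs(lfY + gap_extend - val) < eps) st = 2;
      else if (std::abs(lfX + gap_open + gap_extend - val) < eps) st = 1;
      else st = 2;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  AlignResult res;
  res.a_aln = ra; res.b_aln = rb; res.score = best;
  return res;
}

// Gap-ignoring distance from an aligned pair: strip terminal columns where
// either row is gapped, drop remaining gap columns, distance = mismatches
// over gap-free columns.  comparable == 0 flags "no comparable positions".
void aligned_pair_dist(const std::string &ra, const std::string &rb,
                       int &mismatches, int &comparable) {
  const size_t L = ra.size();
  size_t lo = 0, hi = L;
  while (lo < hi && (ra[lo] == '-' || rb[lo] == '-')) ++lo;
  while (hi > lo && (ra[hi - 1] == '-' || rb[hi - 1] == '-')) --hi;
  mismatches = 0; comparable = 0;
  for (size_t c = lo; c < hi; ++c) {
    if (ra[c] == '-' || rb[c] == '-') continue;
    ++comparable;
    if (ra[c] != rb[c]) ++mismatches;
  }
}

// k-mer codes (2 bits per base) for every window of pure A/C/G/T; windows
// containing any other character are skipped.  Returned sorted.
std::vector<uint64_t> kmer_codes(const std::string &s, int k) {
  std::vector<uint64_t> out;
  const size_t n = s.size();
  if ((int)n < k) return out;
  std::vector<int> code(n);
  for (size_t i = 0; i < n; ++i) {
    switch (s[i]) {
      case 'A': code[i] = 0; break;
      case 'C': code[i] = 1; break;
      case 'G': code[i] = 2; break;
      case 'T': code[i] = 3; break;
      default:  code[i] = -1;
    }
  }
  for (size_t i = 0; i + k <= n; ++i) {
    uint64_t v = 0; bool ok = true;
    for (int p = 0; p < k; ++p) {
      if (code[i + p] < 0) { ok = false; break; }
      v = (v << 2) | (uint64_t)code[i + p];
    }
    if (ok) out.push_back(v);
  }
  std::sort(out.begin(), out.end());
  return out;
}

// Sum over shared words of min(count_i, count_j), via merge over sorted codes.
long shared_min_count(const std::vector<uint64_t> &x,
                      const std::vector<uint64_t> &y) {
  long total = 0;
  size_t i = 0, j = 0;
  while (i < x.size() && j < y.size()) {
    if (x[i] < y[j]) ++i;
    else if (y[j] < x[i]) ++j;
    else {
      const uint64_t v = x[i];
      size_t ci = 0, cj = 0;
      while (i < x.size() && x[i] == v) { ++i; ++ci; }
      while (j < y.size() && y[j] == v) { ++j; ++cj; }
      total += (long)std::min(ci, cj);
    }
  }
  return total;
}

double kmer_dist_from_codes(const std::vector<uint64_t> &ci, size_t Li,
                            const std::vector<uint64_t> &cj, size_t Lj,
                            int k) {
  const long denom = (long)std::min(Li, Lj) - k + 1;
  if (denom <= 0) return 1.0;
  double d = 1.0 - (double)shared_min_count(ci, cj) / (double)denom;
  if (d < 0) d = 0; if (d > 1) d = 1;
  return d;
}

}  // namespace

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_extend, bool free_ends) {
  AlignResult r = nw_align_impl(a, b, match, mismatch, gap_open, gap_extend,
                                free_ends);
  return List::create(_["aligned_i"] = r.a_aln, _["aligned_j"] = r.b_aln,
                      _["score"] = r.score);
}

// [[Rcpp::export]]
List aligned_dist_cpp(std::string aligned_i, std::string aligned_j) {
  int mm, comp;
  aligned_pair_dist(aligned_i, aligned_j, mm, comp);
  double d = comp > 0 ? (double)mm / (double)comp : NA_REAL;
  return List::create(_["dist"] = d, _["mismatches"] = mm,
                      _["comparable"] = comp);
}

// Pairwise NW distances for index pairs (1-based ii, jj) into seqs.
// Pairs with no comparable positions come back NA.
// [[Rcpp::export]]
NumericVector nw_dist_pairs_cpp(CharacterVector seqs,
                                IntegerVector ii, IntegerVector jj,
                                double match, double mismatch,
                                double gap_open, double gap_extend,
                                bool free_ends) {
  const int np = ii.size();
  std::vector<std::string> ss(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) ss[i] = as<std::string>(seqs[i]);
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    AlignResult r = nw_align_impl(ss[ii[p] - 1], ss[jj[p] - 1],
                                  match, mismatch, gap_open, gap_extend,
                                  free_ends);
    int mm, comp;
    aligned_pair_dist(r.a_aln, r.b_aln, mm, comp);
    out[p] = comp > 0 ? (double)mm / (double)comp : NA_REAL;
    if (p % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
NumericVector kmer_dist_pairs_cpp(CharacterVector seqs,
                                  IntegerVector ii, IntegerVector jj,
                                  int k) {
  const int n = seqs.size();
  std::vector<std::vector<uint64_t> > codes(n);
  std::vector<size_t> lens(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    lens[i] = s.size();
    codes[i] = kmer_codes(s, k);
  }
  const int np = ii.size();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    const int a = ii[p] - 1, b = jj[p] - 1;
    out[p] = kmer_dist_from_codes(codes[a], lens[a], codes[b], lens[b], k);
  }
  return out;
}

// Full symmetric k-mer distance matrix (zero diagonal).
// [[Rcpp::export]]
NumericMatrix kmer_dist_matrix_cpp(CharacterVector seqs, int k) {
  const int n = seqs.size();
  std::vector<std::vector<uint64_t> > codes(n);
  std::vector<size_t> lens(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    lens[i] = s.size();
    codes[i] = kmer_codes(s, k);
  }
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double d = kmer_dist_from_codes(codes[i], lens[i],
                                            codes[j], lens[j], k);
      out(i, j) = d; out(j, i) = d;
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
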