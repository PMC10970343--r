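#include <Rcpp.h>
#include <cmath>
#include <string>
#include <vector>

using namespace Rcpp;

// Base codes follow the lexicographic alphabet A=0, C=1, G=2, T=3 everywhere.

namespace {

struct Accum {
  double nearMatches = 0.0;
  double exactMatches = 0.0;
  double prevMatches = 0.0;
  double bonusTotal = 0.0;
  double sequencePrevLength = 0.0;
  double minPrev = 0.0;  // running minimum of prevMatches, for the runtime guard
};

// One pass of the profile accumulation recurrence over an integer-coded
// sequence. canon[b] is the position (0..3) of base b inside the benchmark
// period; the benchmark base at position i is period[i % 4]. A code of -1
// (ambiguous base admitted by the caller) scores 0 exact and 0 near.
inline Accum accumulate_one(const int *codes, int n, const int *canon,
                            const double *baseDistance, double minPoint) {
  Accum a;
  for (int i = 0; i < n; ++i) {
    double nm = 0.0, em = 0.0;
    int b = codes[i];
    if (b >= 0) {
      int d = (canon[b] - (i & 3)) & 3;  // circular distance within the period
      if (d == 0) em = 1.0; else nm = baseDistance[d];
    }
    a.nearMatches += nm + a.prevMatches * nm;
    a.exactMatches += em + a.prevMatches * em;
    a.prevMatches = a.sequencePrevLength / (i + 1) + em + nm - minPoint;
    if (i != n - 1) a.bonusTotal += a.prevMatches;
    a.sequencePrevLength += a.prevMatches;
    if (a.prevMatches < a.minPrev) a.minPrev = a.prevMatches;
  }
  return a;
}

// canon table from a period given as codes: canon[base code] = index in period
inline void canon_from_period(const int *period, int *canon) {
  for (int j = 0; j < 4; ++j) canon[period[j]] = j;
}

inline void legs_from_sides(double dNear, double dFar, double *D, double *H) {
  if (dNear == 0.0) { *D = 0.0; *H = 0.0; return; }
  double cosA = (dNear * dNear + 1.0 - dFar * dFar) / (2.0 * dNear);
  if (cosA > 1.0) cosA = 1.0;
  if (cosA < -1.0) cosA = -1.0;
  double Dv = dNear * cosA;
  double rad = dNear * dNear - Dv * Dv;
  *D = Dv;
  *H = rad > 0.0 ? std::sqrt(rad) : 0.0;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_accumulate(IntegerVector codes, IntegerVector period,
                             NumericVector baseDistance, double minPoint) {
  int canon[4];
  canon_from_period(&period[0], canon);
  Accum a = accumulate_one(&codes[0], codes.size(), canon, &baseDistance[0],
                           minPoint);
  return NumericVector::create(
      _["nearMatches"] = a.nearMatches, _["exactMatches"] = a.exactMatches,
      _["prevMatches"] = a.prevMatches, _["bonusTotal"] = a.bonusTotal,
      _["sequencePrevLength"] = a.sequencePrevLength,
      _["minPrevMatches"] = a.minPrev);
}

// Full profile pipeline for the complete space of 4^n sequences of length n,
// enumerated lexicographically (A<C<G<T). periods is a 3 x 4 integer matrix,
// rows in leg order C, A, T. Returns a 4^n x 6 matrix with columns
// C.D, C.H, A.D, A.H, T.D, T.H under the cyclic C->A->T->C pairing.
// [[Rcpp::export]]
NumericMatrix cpp_profile_space(int n, IntegerMatrix periods,
                                NumericVector baseDistance, double minPoint) {
  if (n < 1 || n > 13) stop("space profiling supports lengths 1..13");
  R_xlen_t total = 1;
  for (int i = 0; i < n; ++i) total *= 4;
  int canon[3][4];
  for (int k = 0; k < 3; ++k) {
    int per[4] = {periods(k, 0), periods(k, 1), periods(k, 2), periods(k, 3)};
    canon_from_period(per, canon[k]);
  }
  NumericMatrix out(total, 6);
  std::vector<int> codes(n, 0);
  const double *bd = &baseDistance[0];
  for (R_xlen_t s = 0; s < total; ++s) {
    double dist[3];
    for (int k = 0; k < 3; ++k) {
      Accum a = accumulate_one(codes.data(), n, canon[k], bd, minPoint);
      dist[k] = (a.nearMatches + a.exactMatches) / (a.bonusTotal + n);
    }
    for (int k = 0; k < 3; ++k) {
      double D, H;
      legs_from_sides(dist[k], dist[(k + 1) % 3], &D, &H);
      out(s, 2 * k) = D;
      out(s, 2 * k + 1) = H;
    }
    // lexicographic increment, least significant digit last
    for (int i = n - 1; i >= 0; --i) {
      if (++codes[i] < 4) break;
      codes[i] = 0;
    }
  }
  return out;
}

// For each query row index (0-based) count rows of `profiles` whose three
// per-benchmark Euclidean distances are all <= tol (a "100% match").
// [[Rcpp::export]]
IntegerVector cpp_count_full_matches(NumericMatrix profiles,
                                     IntegerVector queries, double tol) {
  R_xlen_t nrow = profiles.nrow();
  double tol2 = tol * tol;
  const double *c0 = &profiles(0, 0);
  const double *c1 = &profiles(0, 1);
  const double *c2 = &profiles(0, 2);
  const double *c3 = &profiles(0, 3);
  const double *c4 = &profiles(0, 4);
  const double *c5 = &profiles(0, 5);
  IntegerVector counts(queries.size());
  for (int q = 0; q < queries.size(); ++q) {
    R_xlen_t qi = queries[q];
    double a0 = c0[qi], a1 = c1[qi], a2 = c2[qi], a3 = c3[qi], a4 = c4[qi],
           a5 = c5[qi];
    int cnt = 0;
    for (R_xlen_t r = 0; r < nrow; ++r) {
      double dD = c0[r] - a0, dH = c1[r] - a1;
      if (dD * dD + dH * dH > tol2) continue;
      dD = c2[r] - a2; dH = c3[r] - a3;
      if (dD * dD + dH * dH > tol2) continue;
      dD = c4[r] - a4; dH = c5[r] - a5;
      if (dD * dD + dH * dH > tol2) continue;
      ++cnt;
    }
    counts[q] = cnt;
  }
  return counts;
}

// All 4^n sequences of length n as strings, lexicographic over A<C<G<T.
// [[Rcpp::export]]
CharacterVector cpp_enumerate_space(int n) {
  if (n < 1 || n > 13) stop("enumeration supports lengths 1..13");
  R_xlen_t total = 1;
  for (int i = 0; i < n; ++i) total *= 4;
  static const char alpha[] = "ACGT";
  CharacterVector out(total);
  std::string buf(n, 'A');
  std::vector<int> codes(n, 0);
  for (R_xlen_t s = 0; s < total; ++s) {
    out[s] = buf;
    for (int i = n - 1; i >= 0; --i) {
      if (++codes[i] < 4) { buf[i] = alpha[codes[i]]; break; }
      codes[i] = 0;
      buf[i] = 'A';
    }
  }
  return out;
}

// Global alignment with linear gaps and deterministic traceback
// (tie preference: diagonal, then up = gap in b, then left = gap in a).
// [[Rcpp::export]]
List cpp_needleman_wunsch(std::string a, std::string b, double match,
                          double mismatch, double gap) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  std::vector<double> F((n + 1) * (m + 1));
  std::vector<unsigned char> P((n + 1) * (m + 1));  // 0 diag, 1 up, 2 left
  for (int j = 1; j <= m; ++j) { F[j] = j * gap; P[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    F[i * (m + 1)] = i * gap;
    P[i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      double sdiag = F[(i - 1) * (m + 1) + (j - 1)] +
                     (a[i - 1] == b[j - 1] ? match : mismatch);
      double sup = F[(i - 1) * (m + 1) + j] + gap;
      double sleft = F[i * (m + 1) + (j - 1)] + gap;
      double best = sdiag;
      unsigned char p = 0;
      if (sup > best) { best = sup; p = 1; }
      if (sleft > best) { best = sleft; p = 2; }
      F[i * (m + 1) + j] = best;
      P[i * (m + 1) + j] = p;
    }
  }
  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char p = P[i * (m + 1) + j];
    if (i > 0 && j > 0 && p == 0) {
      ra.push_back(a[--i]);
      rb.push_back(b[--j]);
    } else if (i > 0 && (j == 0 || p == 1)) {
      ra.push_back(a[--i]);
      rb.push_back('-');
    } else {
      ra.push_back('-');
      rb.push_back(b[--j]);
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  int ident = 0;
  for (size_t k = 0; k < ra.size(); ++k)
    if (ra[k] == rb[k] && ra[k] != '-') ++ident;
  return List::create(_["score"] = F[n * (m + 1) + m], _["aligned_a"] = ra,
                      _["aligned_b"] = rb,
                      _["identity_percent"] = 100.0 * ident / ra.size());
}
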