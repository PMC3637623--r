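#include <Rcpp.h>
#include <climits>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Scalar exact affine-gap Smith-Waterman.
//
// Linear space: two row buffers (H and E) over the subject, scalar carries
// for F and the left/diagonal H. Residue codes are 0-based alphabet
// indices; M is the full alphabet x alphabet score matrix (column-major).
// Arithmetic runs in 32-bit integers whenever the score bound
// maxM * min(|q|,|s|) is far from INT_MAX, in 64-bit otherwise, so scores
// of any magnitude are exact.
// ---------------------------------------------------------------------------

template <typename T>
static T sw_core(const int* q, int qlen, const int* s, int slen,
                 const int* M, int nr, int alpha, int beta) {
  std::vector<T> H(slen + 1, 0), E(slen + 1, 0);
  std::vector<int> sidx(slen);
  for (int j = 0; j < slen; ++j) sidx[j] = s[j] * nr;
  T best = 0;
  const T a = (T)alpha, b = (T)beta, zero = 0;
  for (int i = 0; i < qlen; ++i) {
    const int* Mrow = M + q[i];
    T f = 0, hleft = 0, hdiag = 0;
    T* Hp = H.data();
    T* Ep = E.data();
    for (int j = 1; j <= slen; ++j) {
      T hup = Hp[j], eup = Ep[j];
      T e = std::max((T)(eup - b), (T)(hup - a));
      f = std::max((T)(f - b), (T)(hleft - a));
      T h = hdiag + (T)Mrow[sidx[j - 1]];
      h = std::max(h, e);
      h = std::max(h, f);
      h = std::max(h, zero);
      best = std::max(best, h);
      Hp[j] = h;
      Ep[j] = e;
      hdiag = hup;
      hleft = h;
    }
  }
  return best;
}

static int max_matrix_entry(const IntegerMatrix& M) {
  int m = INT_MIN;
  for (int v : M) m = std::max(m, v);
  return m;
}

// [[Rcpp::export]]
double sw_score_cpp(IntegerVector q, IntegerVector s, IntegerMatrix M,
                    int alpha, int beta) {
  // buffer over the shorter dimension (score is symmetric for symmetric M)
  if (s.size() > q.size()) std::swap(q, s);
  long long bound =
      (long long)std::max(1, max_matrix_entry(M)) * std::min(q.size(),
                                                             s.size());
  if (bound < (1LL << 30)) {
    return (double)sw_core<int>(q.begin(), q.size(), s.begin(), s.size(),
                                M.begin(), M.nrow(), alpha, beta);
  }
  return (double)sw_core<long long>(q.begin(), q.size(), s.begin(), s.size(),
                                    M.begin(), M.nrow(), alpha, beta);
}

// [[Rcpp::export]]
NumericVector sw_scores_batch_cpp(IntegerVector q, List subjects,
                                  IntegerMatrix M, int alpha, int beta) {
  int n = subjects.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    IntegerVector s = subjects[k];
    out[k] = sw_score_cpp(q, s, M, alpha, beta);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix sw_matrix_cpp(IntegerVector q, IntegerVector s, IntegerMatrix M,
                            int alpha, int beta) {
  int qlen = q.size(), slen = s.size();
  NumericMatrix H(qlen + 1, slen + 1);
  std::vector<long long> Hv((size_t)(qlen + 1) * (slen + 1), 0),
      E((size_t)(qlen + 1) * (slen + 1), 0),
      F((size_t)(qlen + 1) * (slen + 1), 0);
  int nr = M.nrow();
  for (int i = 1; i <= qlen; ++i) {
    for (int j = 1; j <= slen; ++j) {
      size_t c = (size_t)i * (slen + 1) + j;
      size_t up = (size_t)(i - 1) * (slen + 1) + j;
      long long e = std::max(E[up] - beta, Hv[up] - alpha);
      long long f = std::max(F[c - 1] - beta, Hv[c - 1] - alpha);
      long long h = Hv[up - 1] + (long long)M[(size_t)s[j - 1] * nr + q[i - 1]];
      h = std::max(h, e);
      h = std::max(h, f);
      h = std::max(h, 0LL);
      E[c] = e;
      F[c] = f;
      Hv[c] = h;
      H(i, j) = (double)h;
    }
  }
  return H;
}

// ---------------------------------------------------------------------------
// Packed-lane saturating engine.
//
// Emulates a W-lane signed integer vector unit with saturating add/subtract:
// one query is aligned against the W members of a sequence profile
// simultaneously, one alignment per lane. Lane values are plain ints clamped
// to the signed bit_width range after every add/subtract, which reproduces
// saturating SIMD arithmetic exactly. Padding lanes carry the sentinel
// substitution score (-128), so their h/e/f stay <= 0 and their running
// maximum S is frozen at 0.
// ---------------------------------------------------------------------------

static inline int sat(int v, int lo, int hi) {
  return std::min(std::max(v, lo), hi);
}

// rows: l x W matrix of 0-based residue codes (pad lanes hold the pad code).
// P:    sigma x qlen query profile (row r = scores of residue r along the
//       query); the pad row holds the sentinel.
// Va/Vb: (sigma*sigma) x qlen planes of the K=2 query-profile variant; row
//       r1*sigma+r2 holds (M(r1,S[i]), M(r2,S[i])). Used when use_variant,
//       consuming lane residues in adjacent pairs (W must be even).
static void lane_align_one(const int* q, int qlen, const IntegerMatrix& rows,
                           const IntegerMatrix& P, const IntegerMatrix& Va,
                           const IntegerMatrix& Vb, bool use_variant,
                           int alpha, int beta, int lo, int hi, int limit,
                           int* scores, int* flags) {
  const int l = rows.nrow(), W = rows.ncol();
  const int sigma = P.nrow();
  std::vector<int> H((size_t)l * W, 0), E((size_t)l * W, 0);
  std::vector<int> f(W), hleft(W), hdiag(W), S(W, 0), sub(W);
  // lane-interleaved residue codes, and variant pair codes per position
  std::vector<int> code((size_t)l * W);
  std::vector<int> pairc((size_t)l * (W / 2 + 1));
  for (int j = 0; j < l; ++j) {
    for (int w = 0; w < W; ++w) code[(size_t)j * W + w] = rows(j, w);
    if (use_variant)
      for (int w = 0; w < W; w += 2)
        pairc[(size_t)j * (W / 2) + w / 2] =
            rows(j, w) * sigma + rows(j, w + 1);
  }
  const int* Pp = P.begin();
  const int* Vap = Va.begin();
  const int* Vbp = Vb.begin();
  const size_t vnr = Va.nrow();
  for (int i = 0; i < qlen; ++i) {
    const int* Pcol = Pp + (size_t)i * sigma;
    const int* Vacol = Vap + (size_t)i * vnr;
    const int* Vbcol = Vbp + (size_t)i * vnr;
    std::fill(f.begin(), f.end(), 0);
    std::fill(hleft.begin(), hleft.end(), 0);
    std::fill(hdiag.begin(), hdiag.end(), 0);
    for (int j = 0; j < l; ++j) {
      if (use_variant) {
        const int* pj = &pairc[(size_t)j * (W / 2)];
        for (int w = 0; w < W; w += 2) {
          sub[w] = Vacol[pj[w / 2]];
          sub[w + 1] = Vbcol[pj[w / 2]];
        }
      } else {
        const int* cj = &code[(size_t)j * W];
        for (int w = 0; w < W; ++w) sub[w] = Pcol[cj[w]];
      }
      int* Hj = &H[(size_t)j * W];
      int* Ej = &E[(size_t)j * W];
      for (int w = 0; w < W; ++w) {
        int hup = Hj[w], eup = Ej[w];
        int e = std::max(sat(eup - beta, lo, hi), sat(hup - alpha, lo, hi));
        int fw = std::max(sat(f[w] - beta, lo, hi),
                          sat(hleft[w] - alpha, lo, hi));
        int h = sat(hdiag[w] + sub[w], lo, hi);
        h = std::max(h, e);
        h = std::max(h, fw);
        h = std::max(h, 0);
        S[w] = std::max(S[w], h);
        Hj[w] = h;
        Ej[w] = e;
        f[w] = fw;
        hdiag[w] = hup;
        hleft[w] = h;
      }
    }
  }
  for (int w = 0; w < W; ++w) {
    scores[w] = S[w];
    flags[w] = S[w] >= limit ? 1 : 0;
  }
}

// [[Rcpp::export]]
List lanes_align_cpp(IntegerVector q, IntegerMatrix rows, IntegerMatrix P,
                     IntegerMatrix Va, IntegerMatrix Vb, bool use_variant,
                     int alpha, int beta, int bit_width, int limit) {
  int W = rows.ncol();
  if (use_variant && (W % 2))
    stop("variant score source requires an even lane width");
  int hi = (bit_width == 8) ? 127 : 32767;
  int lo = -hi - 1;
  IntegerVector scores(W);
  IntegerVector flags(W);
  lane_align_one(q.begin(), q.size(), rows, P, Va, Vb, use_variant, alpha,
                 beta, lo, hi, limit, scores.begin(), flags.begin());
  return List::create(_["scores"] = scores, _["flags"] = flags);
}

// [[Rcpp::export]]
List lanes_align_batch_cpp(IntegerVector q, List rowmats, IntegerMatrix P,
                           IntegerMatrix Va, IntegerMatrix Vb,
                           bool use_variant, int alpha, int beta,
                           int bit_width, int limit) {
  int hi = (bit_width == 8) ? 127 : 32767;
  int lo = -hi - 1;
  int nprof = rowmats.size();
  int total = 0;
  for (int k = 0; k < nprof; ++k)
    total += as<IntegerMatrix>(rowmats[k]).ncol();
  IntegerVector scores(total);
  IntegerVector flags(total);
  int off = 0;
  for (int k = 0; k < nprof; ++k) {
    IntegerMatrix rows = rowmats[k];
    int W = rows.ncol();
    if (use_variant && (W % 2))
      stop("variant score source requires an even lane width");
    lane_align_one(q.begin(), q.size(), rows, P, Va, Vb, use_variant, alpha,
                   beta, lo, hi, limit, scores.begin() + off,
                   flags.begin() + off);
    off += W;
  }
  return List::create(_["scores"] = scores, _["flags"] = flags);
}
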