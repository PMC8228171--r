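#include <Rcpp.h>
#include <climits>
#include <cctype>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gap penalties.
// A gap run of length L costs gap_open + gap_extend * L (the opening charge
// is paid once, on top of the per-position extension, matching the usual
// DNA-aligner convention). Only exact A/C/G/T identities score as matches;
// IUPAC ambiguity codes are tolerated but always score as mismatches.
//
// band <= 0 runs the full quadratic DP. band > 0 restricts the DP to
// |i - j| <= band (widened automatically to at least the length difference),
// which is exact whenever the optimal path stays inside the band.
//
// Traceback tie-break: diagonal first, then gap-in-B (consuming A), then
// gap-in-A.

static const int NEG = INT_MIN / 4;

static inline int subscore(char x, char y, int match, int mismatch) {
  x = (char)std::toupper((unsigned char)x);
  y = (char)std::toupper((unsigned char)y);
  bool canon = (x == 'A' || x == 'C' || x == 'G' || x == 'T');
  return (canon && x == y) ? match : mismatch;
}

// [[Rcpp::export]]
List align_affine_cpp(std::string a, std::string b, int match, int mismatch,
                      int gap_open, int gap_extend, int band) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  long eb = band <= 0 ? std::max(n, m) : band;
  if (eb < std::abs(n - m)) eb = std::abs(n - m);
  if (eb > std::max(n, m)) eb = std::max(n, m);
  const long W = 2 * eb + 1;
  const int open_cost = gap_open + gap_extend;

  std::vector<int> M((size_t)(n + 1) * W, NEG), X = M, Y = M;
  std::vector<unsigned char> tM((size_t)(n + 1) * W, 0), tX = tM, tY = tM;
  // index of column j in row i
  #define IDX(i, j) ((size_t)(i) * W + ((j) - (i) + eb))
  #define INBAND(i, j) ((j) >= 0 && (j) <= m && (j) - (i) + eb >= 0 && \
                        (j) - (i) + eb < W)

  M[IDX(0, 0)] = 0;
  for (int j = 1; j <= m && INBAND(0, j); ++j) {
    Y[IDX(0, j)] = -(gap_open + gap_extend * j);
    tY[IDX(0, j)] = (j == 1) ? 1 : 2;  // 1 = opened from M, 2 = extended
  }
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(0, (int)(i - eb)), jhi = std::min(m, (int)(i + eb));
    if (jlo == 0) {
      X[IDX(i, 0)] = -(gap_open + gap_extend * i);
      tX[IDX(i, 0)] = (i == 1) ? 1 : 2;
      jlo = 1;
    }
    for (int j = jlo; j <= jhi; ++j) {
      size_t c = IDX(i, j);
      // M: diagonal predecessor always in band
      {
        size_t d = IDX(i - 1, j - 1);
        int s = subscore(a[i - 1], b[j - 1], match, mismatch);
        int best = M[d]; unsigned char t = 0;
        if (X[d] > best) { best = X[d]; t = 1; }
        if (Y[d] > best) { best = Y[d]; t = 2; }
        M[c] = (best <= NEG / 2) ? NEG : best + s;
        tM[c] = t;
      }
      // X: gap in B, consumes a[i-1]; predecessor (i-1, j)
      if (INBAND(i - 1, j) && j - (i - 1) + eb < W) {
        size_t u = IDX(i - 1, j);
        int fromM = (M[u] <= NEG / 2) ? NEG : M[u] - open_cost;
        int fromX = (X[u] <= NEG / 2) ? NEG : X[u] - gap_extend;
        if (fromM >= fromX) { X[c] = fromM; tX[c] = 1; }
        else { X[c] = fromX; tX[c] = 2; }
      }
      // Y: gap in A, consumes b[j-1]; predecessor (i, j-1)
      if (j - 1 - i + eb >= 0) {
        size_t l = IDX(i, j - 1);
        int fromM = (M[l] <= NEG / 2) ? NEG : M[l] - open_cost;
        int fromY = (Y[l] <= NEG / 2) ? NEG : Y[l] - gap_extend;
        if (fromM >= fromY) { Y[c] = fromM; tY[c] = 1; }
        else { Y[c] = fromY; tY[c] = 2; }
      }
    }
  }

  size_t endc = IDX(n, m);
  int state = 0, score = M[endc];
  if (X[endc] > score) { score = X[endc]; state = 1; }
  if (Y[endc] > score) { score = Y[endc]; state = 2; }

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    size_t c = IDX(i, j);
    if (state == 0) {
      unsigned char t = tM[c];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j; state = t;
    } else if (state == 1) {
      unsigned char t = tX[c];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; state = (t == 1) ? 0 : 1;
    } else {
      unsigned char t = tY[c];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j; state = (t == 1) ? 0 : 2;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  #undef IDX
  #undef INBAND
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score);
}
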