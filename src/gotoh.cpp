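#include <Rcpp.h>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh three-state DP).
//
// Scoring: match / mismatch per aligned pair; N is neutral (0 against
// anything). A gap of length L costs gap_open + L * gap_extend (the open
// charge is paid once, on top of the per-base extend). End gaps are
// charged like any other gap.
//
// States: M = a[i] aligned to b[j]
//         X = gap in B (a[i] over '-'; deletion-in-B)
//         Y = gap in A ('-' over b[j]; insertion-in-B)
// Explicit traceback pointers; ties resolved M > X > Y, deterministic.
// The R wrapper additionally left-normalizes gap runs.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string a, std::string b, double match, double mismatch,
                 double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be nonempty");
  if ((double)n * (double)m > 1.2e7) stop("sequence pair too long for the DP");

  const int w = m + 1;
  std::vector<double> M((n + 1) * w, NEG_INF), X((n + 1) * w, NEG_INF),
      Y((n + 1) * w, NEG_INF);
  std::vector<signed char> pM((n + 1) * w, -1), pX((n + 1) * w, -1),
      pY((n + 1) * w, -1);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * w] = gap_open + i * gap_extend;
    pX[i * w] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = gap_open + j * gap_extend;
    pY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    const char ca = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const char cb = b[j - 1];
      const double s =
          (ca == 'N' || cb == 'N') ? 0.0 : (ca == cb ? match : mismatch);
      const int d = (i - 1) * w + (j - 1), u = (i - 1) * w + j,
                l = i * w + (j - 1), c = i * w + j;
      // M: diagonal from any state, prefer M > X > Y on ties
      double best = M[d];
      signed char p = 0;
      if (X[d] > best) { best = X[d]; p = 1; }
      if (Y[d] > best) { best = Y[d]; p = 2; }
      if (best > NEG_INF / 2) { M[c] = best + s; pM[c] = p; }
      // X: from above
      double xm = M[u] + gap_open + gap_extend;
      double xx = X[u] + gap_extend;
      double xy = Y[u] + gap_open + gap_extend;
      best = xm; p = 0;
      if (xx > best) { best = xx; p = 1; }
      if (xy > best) { best = xy; p = 2; }
      if (best > NEG_INF / 2) { X[c] = best; pX[c] = p; }
      // Y: from the left
      double ym = M[l] + gap_open + gap_extend;
      double yy = Y[l] + gap_extend;
      double yx = X[l] + gap_open + gap_extend;
      best = ym; p = 0;
      if (yx > best) { best = yx; p = 1; }
      if (yy > best) { best = yy; p = 2; }
      if (best > NEG_INF / 2) { Y[c] = best; pY[c] = p; }
    }
  }

  const int end = n * w + m;
  int state = 0;
  double score = M[end];
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int c = i * w + j;
    if (state == 0) {
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      state = pM[c];
      --i; --j;
    } else if (state == 1) {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      state = pX[c];
      --i;
    } else {
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      state = pY[c];
      --j;
    }
    if (state < 0) stop("internal error: broken traceback");
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score);
}
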