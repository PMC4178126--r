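#include <Rcpp.h>
using namespace Rcpp;

// Global pairwise alignment with affine gap costs (Gotoh three-state DP).
//
// States: M = aligned column (diagonal move), X = gap in the second row
// (vertical move, consumes a residue of `a`), Y = gap in the first row
// (horizontal move, consumes a residue of `b`). A gap run of length L costs
// gap_open + gap_extend * (L - 1). Terminal gaps are penalised like internal
// ones (true global alignment).
//
// Determinism: ties are broken in fixed preference order M > X > Y both when
// filling the DP and when choosing the final state, so the traceback is a
// pure function of the inputs. All default scores are exactly representable
// doubles, so tie comparisons are exact.

static const double NEG_INF = -1e300;

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b, NumericMatrix score,
                  double gap_open, double gap_extend) {
  const int m = (int)a.size();
  const int n = (int)b.size();
  if (m == 0 || n == 0) stop("sequences must be non-empty");
  if (score.nrow() != 128 || score.ncol() != 128)
    stop("score must be a 128x128 lookup matrix");

  std::vector<double> S(128 * 128);
  for (int i = 0; i < 128; ++i)
    for (int j = 0; j < 128; ++j) S[i * 128 + j] = score(i, j);
  std::vector<int> ai(m), bi(n);
  for (int i = 0; i < m; ++i) ai[i] = (unsigned char)a[i] & 127;
  for (int j = 0; j < n; ++j) bi[j] = (unsigned char)b[j] & 127;

  const size_t W = (size_t)n + 1;
  // rolling score rows; full traceback matrices (predecessor state, 2 bits
  // would do, a byte is simpler)
  std::vector<double> pM(W), pX(W), pY(W), cM(W), cX(W), cY(W);
  std::vector<unsigned char> tM((size_t)(m + 1) * W), tX((size_t)(m + 1) * W),
      tY((size_t)(m + 1) * W);

  pM[0] = 0.0;
  pX[0] = NEG_INF;
  pY[0] = NEG_INF;
  for (int j = 1; j <= n; ++j) {
    pM[j] = NEG_INF;
    pX[j] = NEG_INF;
    pY[j] = -(gap_open + (j - 1) * gap_extend);
    tY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= m; ++i) {
    cM[0] = NEG_INF;
    cY[0] = NEG_INF;
    cX[0] = -(gap_open + (i - 1) * gap_extend);
    tX[(size_t)i * W] = (i == 1) ? 0 : 1;
    for (int j = 1; j <= n; ++j) {
      const size_t k = (size_t)i * W + j;
      // M: diagonal from (i-1, j-1), any state
      double best = pM[j - 1];
      unsigned char st = 0;
      if (pX[j - 1] > best) { best = pX[j - 1]; st = 1; }
      if (pY[j - 1] > best) { best = pY[j - 1]; st = 2; }
      cM[j] = best + S[ai[i - 1] * 128 + bi[j - 1]];
      tM[k] = st;
      // X: vertical from (i-1, j); extending an X run is cheap
      best = pM[j] - gap_open;
      st = 0;
      if (pX[j] - gap_extend > best) { best = pX[j] - gap_extend; st = 1; }
      if (pY[j] - gap_open > best) { best = pY[j] - gap_open; st = 2; }
      cX[j] = best;
      tX[k] = st;
      // Y: horizontal from (i, j-1); extending a Y run is cheap
      best = cM[j - 1] - gap_open;
      st = 0;
      if (cX[j - 1] - gap_open > best) { best = cX[j - 1] - gap_open; st = 1; }
      if (cY[j - 1] - gap_extend > best) { best = cY[j - 1] - gap_extend; st = 2; }
      cY[j] = best;
      tY[k] = st;
    }
    std::swap(pM, cM);
    std::swap(pX, cX);
    std::swap(pY, cY);
  }

  double bestScore = pM[n];
  unsigned char state = 0;
  if (pX[n] > bestScore) { bestScore = pX[n]; state = 1; }
  if (pY[n] > bestScore) { bestScore = pY[n]; state = 2; }

  std::string ga, gb;
  ga.reserve(m + n);
  gb.reserve(m + n);
  int i = m, j = n;
  while (i > 0 || j > 0) {
    const size_t k = (size_t)i * W + j;
    if (state == 0) {
      ga.push_back(a[i - 1]);
      gb.push_back(b[j - 1]);
      state = tM[k];
      --i; --j;
    } else if (state == 1) {
      ga.push_back(a[i - 1]);
      gb.push_back('-');
      state = tX[k];
      --i;
    } else {
      ga.push_back('-');
      gb.push_back(b[j - 1]);
      state = tY[k];
      --j;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());

  return List::create(_["gapped_a"] = ga, _["gapped_b"] = gb,
                      _["score"] = bestScore);
}

// Reference scorer: exhaustively enumerates every global alignment (every
// monotone path of diagonal / vertical / horizontal moves with no gap-gap
// column) by unmemoised recursion and returns the maximum score. Exponential
// in m + n; intended only for validating the DP on short strings.
static double enum_best(const std::vector<int>& ai, const std::vector<int>& bi,
                        const std::vector<double>& S, double gap_open,
                        double gap_extend, int i, int j, int last) {
  // `last` = type of the final column of the prefix alignment:
  // 0 diagonal (or empty), 1 vertical run, 2 horizontal run
  if (i == 0 && j == 0) return (last == 0) ? 0.0 : NEG_INF;
  double best = NEG_INF;
  if (last == 0) {
    if (i > 0 && j > 0) {
      double sub = S[ai[i - 1] * 128 + bi[j - 1]];
      for (int p = 0; p < 3; ++p) {
        double v = enum_best(ai, bi, S, gap_open, gap_extend, i - 1, j - 1, p);
        if (v > NEG_INF / 2 && v + sub > best) best = v + sub;
      }
    }
  } else if (last == 1) {
    if (i > 0) {
      for (int p = 0; p < 3; ++p) {
        double cost = (p == 1) ? gap_extend : gap_open;
        double v = enum_best(ai, bi, S, gap_open, gap_extend, i - 1, j, p);
        if (v > NEG_INF / 2 && v - cost > best) best = v - cost;
      }
    }
  } else {
    if (j > 0) {
      for (int p = 0; p < 3; ++p) {
        double cost = (p == 2) ? gap_extend : gap_open;
        double v = enum_best(ai, bi, S, gap_open, gap_extend, i, j - 1, p);
        if (v > NEG_INF / 2 && v - cost > best) best = v - cost;
      }
    }
  }
  return best;
}

// [[Rcpp::export(name = ".nw_enum_score_cpp")]]
double nw_enum_score_cpp(std::string a, std::string b, NumericMatrix score,
                         double gap_open, double gap_extend) {
  const int m = (int)a.size();
  const int n = (int)b.size();
  if (m == 0 || n == 0) stop("sequences must be non-empty");
  if (m + n > 24) stop("enumeration oracle is restricted to short strings");
  std::vector<double> S(128 * 128);
  for (int i = 0; i < 128; ++i)
    for (int j = 0; j < 128; ++j) S[i * 128 + j] = score(i, j);
  std::vector<int> ai(m), bi(n);
  for (int i = 0; i < m; ++i) ai[i] = (unsigned char)a[i] & 127;
  for (int j = 0; j < n; ++j) bi[j] = (unsigned char)b[j] & 127;
  double best = NEG_INF;
  for (int p = 0; p < 3; ++p) {
    double v = enum_best(ai, bi, S, gap_open, gap_extend, m, n, p);
    if (v > best) best = v;
  }
  return best;
}
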