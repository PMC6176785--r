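#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global alignment restricted to "licit" alignments: a gap column
// in one sequence may never be immediately followed by a gap column in the
// other.  Three-state DP (match M, gap-in-y X, gap-in-x Y) with the X<->Y
// transitions forbidden enforces the restriction exactly.  A gap run of
// length k is charged gap_open + (k-1) * gap_extend.
//
// Sequences are 1-based integer codes into the score matrix.

static const double NEG_INF = -1e300;

static inline double max3(double a, double b, double c) {
  return std::max(a, std::max(b, c));
}

static void dp_fill(const IntegerVector &x, const IntegerVector &y,
                    const NumericMatrix &pmi, double go, double ge,
                    std::vector<double> &M, std::vector<double> &X,
                    std::vector<double> &Y) {
  int n = x.size(), m = y.size();
  int w = m + 1;
  M.assign((n + 1) * w, NEG_INF);
  X.assign((n + 1) * w, NEG_INF);
  Y.assign((n + 1) * w, NEG_INF);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i * w] = go + (i - 1) * ge;
  for (int j = 1; j <= m; ++j) Y[j] = go + (j - 1) * ge;
  for (int i = 1; i <= n; ++i) {
    int xi = x[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      int c = i * w + j, d = (i - 1) * w + (j - 1), u = (i - 1) * w + j,
          l = i * w + (j - 1);
      M[c] = pmi(xi, y[j - 1] - 1) + max3(M[d], X[d], Y[d]);
      X[c] = std::max(M[u] + go, X[u] + ge);
      Y[c] = std::max(M[l] + go, Y[l] + ge);
    }
  }
}

static double dp_score(const IntegerVector &x, const IntegerVector &y,
                       const NumericMatrix &pmi, double go, double ge) {
  std::vector<double> M, X, Y;
  dp_fill(x, y, pmi, go, ge, M, X, Y);
  int n = x.size(), m = y.size();
  int c = n * (m + 1) + m;
  return max3(M[c], X[c], Y[c]);
}

// [[Rcpp::export]]
double cpp_pmi_score(IntegerVector x, IntegerVector y, NumericMatrix pmi,
                     double gap_open, double gap_extend) {
  return dp_score(x, y, pmi, gap_open, gap_extend);
}

// [[Rcpp::export]]
NumericMatrix cpp_pmi_score_matrix(List xs, List ys, NumericMatrix pmi,
                                   double gap_open, double gap_extend) {
  int n = xs.size(), m = ys.size();
  NumericMatrix out(n, m);
  for (int i = 0; i < n; ++i) {
    IntegerVector xi = xs[i];
    for (int j = 0; j < m; ++j) {
      IntegerVector yj = ys[j];
      out(i, j) = dp_score(xi, yj, pmi, gap_open, gap_extend);
    }
  }
  return out;
}

// Traceback with deterministic tie-breaking: match preferred over gap-in-y
// (x against gap), preferred over gap-in-x; gap opening preferred over
// extension on ties.  Output uses 0 for the gap symbol.
// [[Rcpp::export]]
List cpp_pmi_align(IntegerVector x, IntegerVector y, NumericMatrix pmi,
                   double gap_open, double gap_extend) {
  std::vector<double> M, X, Y;
  dp_fill(x, y, pmi, gap_open, gap_extend, M, X, Y);
  int n = x.size(), m = y.size(), w = m + 1;
  int c = n * w + m;
  double sc = max3(M[c], X[c], Y[c]);
  int state = (M[c] >= X[c] && M[c] >= Y[c]) ? 0 : (X[c] >= Y[c] ? 1 : 2);
  std::vector<int> ax, ay;
  int i = n, j = m;
  const double eps = 1e-12;
  while (i > 0 || j > 0) {
    int cc = i * w + j;
    if (state == 0) {
      int d = (i - 1) * w + (j - 1);
      double base = M[cc] - pmi(x[i - 1] - 1, y[j - 1] - 1);
      ax.push_back(x[i - 1]);
      ay.push_back(y[j - 1]);
      --i; --j;
      if (std::abs(base - M[d]) < eps) state = 0;
      else if (std::abs(base - X[d]) < eps) state = 1;
      else state = 2;
    } else if (state == 1) {
      int u = (i - 1) * w + j;
      ax.push_back(x[i - 1]);
      ay.push_back(0);
      double v = X[cc];
      --i;
      if (std::abs(v - (M[u] + gap_open)) < eps) state = 0;
      else state = 1;
    } else {
      int l = i * w + (j - 1);
      ax.push_back(0);
      ay.push_back(y[j - 1]);
      double v = Y[cc];
      --j;
      if (std::abs(v - (M[l] + gap_open)) < eps) state = 0;
      else state = 2;
    }
  }
  std::reverse(ax.begin(), ax.end());
  std::reverse(ay.begin(), ay.end());
  return List::create(_["score"] = sc, _["ax"] = wrap(ax), _["ay"] = wrap(ay));
}

// Batch PMI alignment over paired word lists: re-align every pair, and for
// pairs whose alignment score reaches `theta`, accumulate counts of aligned
// (non-gap) symbol columns.  Used by the iterative score re-estimation.
// [[Rcpp::export]]
List cpp_pmi_align_counts(List xs, List ys, NumericMatrix pmi,
                          double gap_open, double gap_extend, double theta,
                          int nsym) {
  int n = xs.size();
  NumericVector scores(n);
  IntegerMatrix counts(nsym, nsym);
  int kept = 0;
  for (int k = 0; k < n; ++k) {
    IntegerVector x = xs[k], y = ys[k];
    List al = cpp_pmi_align(x, y, pmi, gap_open, gap_extend);
    double sc = al["score"];
    scores[k] = sc;
    if (sc >= theta) {
      ++kept;
      IntegerVector ax = al["ax"], ay = al["ay"];
      for (int t = 0; t < ax.size(); ++t)
        if (ax[t] > 0 && ay[t] > 0) counts(ax[t] - 1, ay[t] - 1)++;
    }
  }
  return List::create(_["counts"] = counts, _["scores"] = scores,
                      _["n_kept"] = kept);
}

// Levenshtein alignment (unit costs) of paired word lists, counting aligned
// non-gap symbol columns.  Traceback preference: substitution/match over
// deletion over insertion.  Used for the initial score estimate.
// [[Rcpp::export]]
IntegerMatrix cpp_lev_align_counts(List xs, List ys, int nsym) {
  int np = xs.size();
  IntegerMatrix counts(nsym, nsym);
  for (int k = 0; k < np; ++k) {
    IntegerVector x = xs[k], y = ys[k];
    int n = x.size(), m = y.size(), w = m + 1;
    std::vector<int> D((n + 1) * w);
    for (int i = 0; i <= n; ++i) D[i * w] = i;
    for (int j = 0; j <= m; ++j) D[j] = j;
    for (int i = 1; i <= n; ++i)
      for (int j = 1; j <= m; ++j) {
        int sub = D[(i - 1) * w + (j - 1)] + (x[i - 1] != y[j - 1] ? 1 : 0);
        int del = D[(i - 1) * w + j] + 1;
        int ins = D[i * w + (j - 1)] + 1;
        D[i * w + j] = std::min(sub, std::min(del, ins));
      }
    int i = n, j = m;
    while (i > 0 && j > 0) {
      int cur = D[i * w + j];
      int sub = D[(i - 1) * w + (j - 1)] + (x[i - 1] != y[j - 1] ? 1 : 0);
      if (cur == sub) {
        counts(x[i - 1] - 1, y[j - 1] - 1)++;
        --i; --j;
      } else if (cur == D[(i - 1) * w + j] + 1) {
        --i;
      } else {
        --j;
      }
    }
  }
  return counts;
}

// Max-aggregation of a word-by-word score matrix into a group-by-group
// (concept-by-concept) matrix.
// [[Rcpp::export]]
NumericMatrix cpp_group_max(NumericMatrix m, IntegerVector gx,
                            IntegerVector gy, int ngx, int ngy) {
  NumericMatrix out(ngx, ngy);
  std::fill(out.begin(), out.end(), NEG_INF);
  for (int i = 0; i < m.nrow(); ++i) {
    int a = gx[i] - 1;
    for (int j = 0; j < m.ncol(); ++j) {
      int b = gy[j] - 1;
      if (m(i, j) > out(a, b)) out(a, b) = m(i, j);
    }
  }
  return out;
}
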