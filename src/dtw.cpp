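#include <Rcpp.h>
using namespace Rcpp;

// Slope-constrained dynamic time warping between two equal-length,
// z-normalised signals.
//
// Allowed step blocks (appended to a partial path ending at D[i', j']):
//   (1,1): cost d(i, j)                                   local slope 1
//   (2,3): cost d(i-1, j-2) + d(i, j-1) + d(i, j)         local slope 2/3
//   (3,2): cost d(i-2, j-1) + d(i-1, j) + d(i, j)         local slope 3/2
// with d(x, y) = (x - y)^2.  D[0][0] = 0, all other border cells are
// unreachable, so every path starts by pairing (1,1) and ends at (m,m).
// Reachable local slopes are exactly {2/3, 1, 3/2}: any 6 points on one
// axis are matched against between 4 and 9 points on the other.
//
// Tie-break in the traceback prefers (1,1), then (2,3), then (3,2).

static inline double sq(double x) { return x * x; }

// [[Rcpp::export]]
List dtw_core(NumericVector S, NumericVector T) {
  const int m = S.size();
  if (T.size() != m)
    stop("length mismatch");
  if (m < 3)
    stop("need at least 3 data points");

  const double INF = R_PosInf;
  // D is (m+1) x (m+1), row-major; D[i * (m+1) + j]
  std::vector<double> D((m + 1) * (m + 1), INF);
  std::vector<signed char> move_((m + 1) * (m + 1), 0);
  const int w = m + 1;
  D[0] = 0.0;

  for (int i = 1; i <= m; ++i) {
    const double si = S[i - 1];
    for (int j = 1; j <= m; ++j) {
      const double d11 = sq(si - T[j - 1]);
      double best = INF;
      signed char arg = 0;
      // (1,1)
      double c = D[(i - 1) * w + (j - 1)];
      if (c < INF) {
        c += d11;
        if (c < best) { best = c; arg = 1; }
      }
      // (2,3): pairs (i-1,j-2), (i,j-1), (i,j)
      if (i >= 2 && j >= 3) {
        c = D[(i - 2) * w + (j - 3)];
        if (c < INF) {
          c += sq(S[i - 2] - T[j - 3]) + sq(si - T[j - 2]) + d11;
          if (c < best) { best = c; arg = 2; }
        }
      }
      // (3,2): pairs (i-2,j-1), (i-1,j), (i,j)
      if (i >= 3 && j >= 2) {
        c = D[(i - 3) * w + (j - 2)];
        if (c < INF) {
          c += sq(S[i - 3] - T[j - 2]) + sq(S[i - 2] - T[j - 1]) + d11;
          if (c < best) { best = c; arg = 3; }
        }
      }
      D[i * w + j] = best;
      move_[i * w + j] = arg;
    }
  }

  const double dist = D[m * w + m];
  if (!R_FINITE(dist))
    stop("no feasible warp path");  // cannot happen for m >= 3

  // Traceback: collect blocks from the end, then expand into pairs.
  std::vector<signed char> blocks;
  int i = m, j = m;
  while (i > 0 || j > 0) {
    signed char a = move_[i * w + j];
    blocks.push_back(a);
    if (a == 1)      { i -= 1; j -= 1; }
    else if (a == 2) { i -= 2; j -= 3; }
    else if (a == 3) { i -= 3; j -= 2; }
    else stop("corrupt traceback");
  }

  // Emit pairs in forward order (1-based indices).
  std::vector<int> pi, pj;
  i = 0; j = 0;
  for (int b = (int)blocks.size() - 1; b >= 0; --b) {
    signed char a = blocks[b];
    if (a == 1) {
      i += 1; j += 1;
      pi.push_back(i); pj.push_back(j);
    } else if (a == 2) {
      // pairs (i+1, j+2), (i+2, j+3)... block advances i by 2, j by 3
      pi.push_back(i + 1); pj.push_back(j + 1);
      pi.push_back(i + 2); pj.push_back(j + 2);
      pi.push_back(i + 2); pj.push_back(j + 3);
      i += 2; j += 3;
    } else {
      pi.push_back(i + 1); pj.push_back(j + 1);
      pi.push_back(i + 2); pj.push_back(j + 2);
      pi.push_back(i + 3); pj.push_back(j + 2);
      i += 3; j += 2;
    }
  }

  IntegerMatrix path(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) {
    path(k, 0) = pi[k];
    path(k, 1) = pj[k];
  }
  colnames(path) = CharacterVector::create("i", "j");

  return List::create(_["distance"] = dist, _["path"] = path);
}

// Classic unconstrained DTW distance (steps (1,1), (1,0), (0,1)) used as a
// relaxation bound in tests; squared-error local cost.
// [[Rcpp::export]]
double dtw_unconstrained(NumericVector S, NumericVector T) {
  const int m = S.size(), n = T.size();
  std::vector<double> prev(n + 1, R_PosInf), cur(n + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= m; ++i) {
    cur[0] = R_PosInf;
    for (int j = 1; j <= n; ++j) {
      double d = sq(S[i - 1] - T[j - 1]);
      double best = std::min(prev[j - 1], std::min(prev[j], cur[j - 1]));
      cur[j] = d + best;
    }
    std::swap(prev, cur);
  }
  return prev[n];
}
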