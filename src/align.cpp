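#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap dynamic programming on a precomputed column-score matrix.
// Rows index the first sequence (or profile columns), columns the second.
// A gap of length k costs open + (k - 1) * ext.
// Traceback tie order: diagonal > up (consume row) > left (consume column).

static const double NEG = -1e30;

// [[Rcpp::export]]
List cpp_affine_global(NumericMatrix S, double open, double ext) {
  int n = S.nrow(), m = S.ncol();
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -open - (i - 1) * ext;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -open - (j - 1) * ext;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double best = M(i - 1, j - 1);
      if (X(i - 1, j - 1) > best) best = X(i - 1, j - 1);
      if (Y(i - 1, j - 1) > best) best = Y(i - 1, j - 1);
      M(i, j) = S(i - 1, j - 1) + best;
      X(i, j) = std::max(M(i - 1, j) - open, X(i - 1, j) - ext);
      Y(i, j) = std::max(M(i, j - 1) - open, Y(i, j - 1) - ext);
    }
  }
  // traceback: state 0 = M, 1 = X (up), 2 = Y (left); ties prefer lower state
  int i = n, j = m, state;
  double sc;
  if (M(n, m) >= X(n, m) && M(n, m) >= Y(n, m)) { state = 0; sc = M(n, m); }
  else if (X(n, m) >= Y(n, m)) { state = 1; sc = X(n, m); }
  else { state = 2; sc = Y(n, m); }
  std::string moves;
  while (i > 0 || j > 0) {
    if (i == 0) { moves.push_back('L'); --j; continue; }
    if (j == 0) { moves.push_back('U'); --i; continue; }
    if (state == 0) {
      moves.push_back('D');
      double prev = M(i, j) - S(i - 1, j - 1);
      --i; --j;
      if (std::abs(M(i, j) - prev) < 1e-9) state = 0;
      else if (std::abs(X(i, j) - prev) < 1e-9) state = 1;
      else state = 2;
    } else if (state == 1) {
      moves.push_back('U');
      double cur = X(i, j);
      --i;
      state = (std::abs(M(i, j) - open - cur) < 1e-9) ? 0 : 1;
    } else {
      moves.push_back('L');
      double cur = Y(i, j);
      --j;
      state = (std::abs(M(i, j) - open - cur) < 1e-9) ? 0 : 2;
    }
  }
  std::reverse(moves.begin(), moves.end());
  return List::create(_["score"] = sc, _["moves"] = moves);
}

// Score-only local affine DP for threshold calibration: profile score
// matrix (L x alphabet) against many integer-coded random sequences.
// [[Rcpp::export]]
NumericVector cpp_calibrate_scores(NumericMatrix scores, IntegerMatrix seqs,
                                   double open, double ext) {
  int L = scores.nrow();
  int ncal = seqs.nrow(), m = seqs.ncol();
  NumericVector out(ncal);
  std::vector<double> M0(m + 1), M1(m + 1), X0(m + 1), X1(m + 1),
      Y0(m + 1), Y1(m + 1);
  for (int r = 0; r < ncal; ++r) {
    double best = 0.0;
    std::fill(M0.begin(), M0.end(), 0.0);
    std::fill(X0.begin(), X0.end(), NEG);
    std::fill(Y0.begin(), Y0.end(), NEG);
    for (int i = 1; i <= L; ++i) {
      M1[0] = 0.0; X1[0] = NEG; Y1[0] = NEG;
      for (int j = 1; j <= m; ++j) {
        double prev = M0[j - 1];
        if (X0[j - 1] > prev) prev = X0[j - 1];
        if (Y0[j - 1] > prev) prev = Y0[j - 1];
        if (prev < 0.0) prev = 0.0;
        M1[j] = scores(i - 1, seqs(r, j - 1) - 1) + prev;
        X1[j] = std::max(M0[j] - open, X0[j] - ext);
        Y1[j] = std::max(M1[j - 1] - open, Y1[j - 1] - ext);
        if (M1[j] > best) best = M1[j];
      }
      std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
    }
    out[r] = best;
  }
  return out;
}

// Local (Smith-Waterman-style) affine DP; zero floor on the match state.
// Returns the best-scoring segment: score, row/col span (1-based inclusive)
// and the number of diagonal (row-to-column matched) steps.
// [[Rcpp::export]]
List cpp_affine_local(NumericMatrix S, double open, double ext) {
  int n = S.nrow(), m = S.ncol();
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  for (int j = 0; j <= m; ++j) { M(0, j) = 0; X(0, j) = NEG; Y(0, j) = NEG; }
  for (int i = 0; i <= n; ++i) { M(i, 0) = 0; X(i, 0) = NEG; Y(i, 0) = NEG; }
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double prev = M(i - 1, j - 1);
      if (X(i - 1, j - 1) > prev) prev = X(i - 1, j - 1);
      if (Y(i - 1, j - 1) > prev) prev = Y(i - 1, j - 1);
      if (prev < 0.0) prev = 0.0;
      M(i, j) = S(i - 1, j - 1) + prev;
      X(i, j) = std::max(M(i - 1, j) - open, X(i - 1, j) - ext);
      Y(i, j) = std::max(M(i, j - 1) - open, Y(i, j - 1) - ext);
      if (M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }
  if (best <= 0.0)
    return List::create(_["score"] = 0.0, _["i0"] = NA_INTEGER, _["i1"] = NA_INTEGER,
                        _["j0"] = NA_INTEGER, _["j1"] = NA_INTEGER, _["ndiag"] = 0);
  // traceback from (bi, bj) in state M until the zero floor
  int i = bi, j = bj, state = 0, ndiag = 0;
  int i0 = bi, j0 = bj;
  while (true) {
    if (state == 0) {
      ++ndiag; i0 = i; j0 = j;
      double prev = M(i, j) - S(i - 1, j - 1);
      --i; --j;
      if (prev < 1e-9) break;
      if (std::abs(M(i, j) - prev) < 1e-9) state = 0;
      else if (std::abs(X(i, j) - prev) < 1e-9) state = 1;
      else if (std::abs(Y(i, j) - prev) < 1e-9) state = 2;
      else break;
    } else if (state == 1) {
      double cur = X(i, j);
      --i;
      if (std::abs(M(i, j) - open - cur) < 1e-9) state = 0;
      else state = 1;
    } else {
      double cur = Y(i, j);
      --j;
      if (std::abs(M(i, j) - open - cur) < 1e-9) state = 0;
      else state = 2;
    }
  }
  return List::create(_["score"] = best, _["i0"] = i0, _["i1"] = bi,
                      _["j0"] = j0, _["j1"] = bj, _["ndiag"] = ndiag);
}
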