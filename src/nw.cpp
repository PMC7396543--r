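#include <Rcpp.h>
using namespace Rcpp;

// Global profile-profile alignment with affine gaps (Gotoh).
// Profiles are integer matrices (rows = sequences, cols = alignment
// columns) of 0-based codes into the scoring matrix; NA = gap.
// A gap of length L costs gap_open + gap_ext * L (terminal gaps included).
// Column-pair score is the mean substitution score over all row pairs,
// with gap-vs-anything contributing 0.
// [[Rcpp::export]]
List nw_profile_align(IntegerMatrix p1, IntegerMatrix p2, NumericMatrix score,
                      double gap_open, double gap_ext) {
  const int L1 = p1.ncol(), L2 = p2.ncol();
  const int n1 = p1.nrow(), n2 = p2.nrow();
  NumericMatrix cs(L1 + 1, L2 + 1);
  for (int i = 1; i <= L1; i++) {
    for (int j = 1; j <= L2; j++) {
      double s = 0.0;
      for (int a = 0; a < n1; a++) {
        int ca = p1(a, i - 1);
        if (ca == NA_INTEGER) continue;
        for (int b = 0; b < n2; b++) {
          int cb = p2(b, j - 1);
          if (cb == NA_INTEGER) continue;
          s += score(ca, cb);
        }
      }
      cs(i, j) = s / (double)(n1 * n2);
    }
  }
  const double NEG = -1e30;
  NumericMatrix M(L1 + 1, L2 + 1), X(L1 + 1, L2 + 1), Y(L1 + 1, L2 + 1);
  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= L1; i++) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -(gap_open + gap_ext * i);
  }
  for (int j = 1; j <= L2; j++) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -(gap_open + gap_ext * j);
  }
  for (int i = 1; i <= L1; i++) {
    for (int j = 1; j <= L2; j++) {
      double m = M(i - 1, j - 1), x = X(i - 1, j - 1), y = Y(i - 1, j - 1);
      double best = m >= x ? (m >= y ? m : y) : (x >= y ? x : y);
      M(i, j) = cs(i, j) + best;
      double open_x = M(i - 1, j) - (gap_open + gap_ext);
      double ext_x = X(i - 1, j) - gap_ext;
      X(i, j) = open_x >= ext_x ? open_x : ext_x;
      double open_y = M(i, j - 1) - (gap_open + gap_ext);
      double ext_y = Y(i, j - 1) - gap_ext;
      Y(i, j) = open_y >= ext_y ? open_y : ext_y;
    }
  }
  // traceback, deterministic preference M > X > Y
  std::vector<int> o1, o2;
  int i = L1, j = L2;
  char state;
  double m = M(L1, L2), x = X(L1, L2), y = Y(L1, L2);
  double total = m;
  state = 'M';
  if (x > total) { total = x; state = 'X'; }
  if (y > total) { total = y; state = 'Y'; }
  while (i > 0 || j > 0) {
    if (i == 0) state = 'Y';
    else if (j == 0) state = 'X';
    if (state == 'M') {
      o1.push_back(i); o2.push_back(j);
      double prev = M(i, j) - cs(i, j);
      i--; j--;
      if (std::abs(M(i, j) - prev) < 1e-9) state = 'M';
      else if (std::abs(X(i, j) - prev) < 1e-9) state = 'X';
      else state = 'Y';
    } else if (state == 'X') {
      o1.push_back(i); o2.push_back(0);
      double cur = X(i, j);
      i--;
      if (std::abs((M(i, j) - (gap_open + gap_ext)) - cur) < 1e-9) state = 'M';
      else state = 'X';
    } else {
      o1.push_back(0); o2.push_back(j);
      double cur = Y(i, j);
      j--;
      if (std::abs((M(i, j) - (gap_open + gap_ext)) - cur) < 1e-9) state = 'M';
      else state = 'Y';
    }
  }
  std::reverse(o1.begin(), o1.end());
  std::reverse(o2.begin(), o2.end());
  return List::create(_["score"] = total,
                      _["cols1"] = wrap(o1),
                      _["cols2"] = wrap(o2));
}
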