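#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Hartigan's dip statistic for a sorted sample.
//
// The dip is the smallest sup-norm distance between the empirical CDF and
// any unimodal CDF (convex below the mode, concave above it, with an atom
// allowed at the mode).  Collapsing ties into blocks with cumulative counts
// bot_b (samples strictly below the block value) and top_b (samples up to
// and including it), a distance d is attainable with the mode placed between
// blocks a and b (b = a+1, or b = a+2 when the mode sits exactly on block
// a+1 and its mass is absorbed by the atom) if and only if
//
//   max_{i <= a} [ top_i - gcm_a(v_i) ] <= 2 d n   and
//   max_{i >= b} [ lcm_b(v_i) - bot_i ] <= 2 d n,
//
// where gcm_a is the greatest convex minorant of the points (v_i, bot_i),
// i <= a, and lcm_b the least concave majorant of (v_i, top_i), i >= b:
// any convex fit within distance d of the ECDF must, after shifting by d,
// run below the lower step corners, hence below their minorant, while the
// ECDF's upper corners must stay within 2d of it (and conversely the
// minorant shifted up by d is itself a feasible convex fit).  The dip is
// therefore half the count-scale min-max over mode placements, floored at
// 1/(2n) (the jump of the ECDF at any retained data point).

namespace {

struct Blocks {
  std::vector<double> v;     // distinct sorted values
  std::vector<double> bot;   // cumulative count strictly before block
  std::vector<double> top;   // cumulative count through block
};

Blocks collapse_ties(const NumericVector& x) {
  Blocks b;
  const int n = x.size();
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && x[j] == x[i]) ++j;
    b.v.push_back(x[i]);
    b.bot.push_back(i);
    b.top.push_back(j);
    i = j;
  }
  return b;
}

// Incrementally build the lower convex hull of (v_i, y_i) over prefixes and
// record, for each prefix length p+1, the largest gap between the upper
// corners z_i and the hull.  Collinear hull points are retained so that
// gaps at hull vertices are computed exactly (no interpolation error).
// Adding point p only changes the hull after the last surviving vertex, so
// only gaps in that suffix are recomputed; a running prefix-max of the gaps
// gives each prefix's answer without a full rescan.
std::vector<double> prefix_gaps(const std::vector<double>& v,
                                const std::vector<double>& y,
                                const std::vector<double>& z) {
  const int B = v.size();
  std::vector<double> out(B + 1);
  out[0] = 0.0;  // empty prefix
  std::vector<int> hull;
  std::vector<double> gap(B), prefmax(B);
  hull.reserve(B);
  for (int p = 0; p < B; ++p) {
    while (hull.size() >= 2) {
      int a = hull[hull.size() - 2], m = hull[hull.size() - 1];
      // pop m only when strictly above the chord a -> p
      if ((y[m] - y[a]) * (v[p] - v[a]) > (y[p] - y[a]) * (v[m] - v[a]))
        hull.pop_back();
      else
        break;
    }
    // hull on [0, last] is unchanged; the new segment last -> p replaces
    // everything after it
    int last = hull.empty() ? p : hull.back();
    hull.push_back(p);
    for (int i = last + 1; i <= p; ++i) {
      double h;
      if (i == p) {
        h = y[p];
      } else {
        h = y[last] + (y[p] - y[last]) * (v[i] - v[last]) / (v[p] - v[last]);
      }
      gap[i] = z[i] - h;
      prefmax[i] = std::max(i > 0 ? prefmax[i - 1] : 0.0, gap[i]);
    }
    if (last == p) {  // first point
      gap[p] = z[p] - y[p];
      prefmax[p] = std::max(p > 0 ? prefmax[p - 1] : 0.0, gap[p]);
    }
    out[p + 1] = prefmax[p];
  }
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".dip_sorted")]]
double dip_sorted(NumericVector x) {
  const int n = x.size();
  if (n < 2) stop("dip statistic requires at least 2 values");
  for (int i = 1; i < n; ++i)
    if (x[i] < x[i - 1]) stop("internal error: input to .dip_sorted not sorted");

  Blocks b = collapse_ties(x);
  const int B = b.v.size();

  // Convex (left) side: gcm of lower corners vs upper corners.
  std::vector<double> A = prefix_gaps(b.v, b.bot, b.top);

  // Concave (right) side: reflect x -> -x, which swaps the roles of the
  // lower and upper corners: blocks reversed, v -> -v, bot -> n - top,
  // top -> n - bot.
  std::vector<double> rv(B), rbot(B), rtop(B);
  for (int i = 0; i < B; ++i) {
    rv[i] = -b.v[B - 1 - i];
    rbot[i] = n - b.top[B - 1 - i];
    rtop[i] = n - b.bot[B - 1 - i];
  }
  std::vector<double> Crev = prefix_gaps(rv, rbot, rtop);
  // C[q] = gap of suffix starting at block q (q = 0..B)
  std::vector<double> C(B + 1);
  for (int q = 0; q <= B; ++q) C[q] = Crev[B - q];

  double raw = R_PosInf;
  for (int a = -1; a < B; ++a) {
    double left = A[a + 1];
    // mode strictly between blocks a and a+1
    double m1 = std::max(left, C[a + 1]);
    if (m1 < raw) raw = m1;
    // mode on block a+1, its mass absorbed by the atom
    if (a + 2 <= B) {
      double m2 = std::max(left, C[a + 2]);
      if (m2 < raw) raw = m2;
    }
  }
  if (raw < 1.0) raw = 1.0;  // floor: ECDF jump at a retained point
  return raw / (2.0 * n);
}
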