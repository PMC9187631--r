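#include <Rcpp.h>
using namespace Rcpp;

// Sequences arrive as 0-based integer codes into the substitution-matrix
// alphabet. All heavy loops live here; the R wrappers do validation only.

// Sliding self-scores: self[i] = sum_{k<w} m[s[i+k]][s[i+k]], one per window.
static std::vector<int> window_self_scores(const IntegerVector& s,
                                           const IntegerMatrix& m, int w) {
  int n = s.size() - w + 1;
  std::vector<int> out(std::max(n, 0));
  if (n <= 0) return out;
  int acc = 0;
  for (int k = 0; k < w; ++k) acc += m(s[k], s[k]);
  out[0] = acc;
  for (int i = 1; i < n; ++i) {
    acc += m(s[i + w - 1], s[i + w - 1]) - m(s[i - 1], s[i - 1]);
    out[i] = acc;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_self_scores(IntegerVector s, IntegerMatrix m, int w) {
  std::vector<int> v = window_self_scores(s, m, w);
  return IntegerVector(v.begin(), v.end());
}

struct Hit { int q, p, sim; };

// Enumerate all window pairs (i, j) with sim >= tau * min(selfQ[i], selfP[j]).
// Windows whose smaller self-score is non-positive cannot be thresholded
// meaningfully and never produce hits.
static void window_hits(const IntegerVector& q, const IntegerVector& p,
                        const IntegerMatrix& m, int w, double tau,
                        std::vector<Hit>& hits) {
  int nq = q.size() - w + 1, np = p.size() - w + 1;
  if (nq <= 0 || np <= 0) return;
  std::vector<int> selfq = window_self_scores(q, m, w);
  std::vector<int> selfp = window_self_scores(p, m, w);
  // One diagonal at a time: positional scores then a sliding window sum.
  for (int d = -(nq - 1); d <= np - 1; ++d) {
    int i0 = std::max(0, -d);          // first q window start on diagonal d
    int j0 = i0 + d;
    int len = std::min((int)q.size() - i0, (int)p.size() - j0);
    if (len < w) continue;
    int acc = 0;
    for (int k = 0; k < w; ++k) acc += m(q[i0 + k], p[j0 + k]);
    int nwin = len - w + 1;
    for (int t = 0; t < nwin; ++t) {
      int i = i0 + t, j = j0 + t;
      if (t > 0)
        acc += m(q[i + w - 1], p[j + w - 1]) - m(q[i - 1], p[j - 1]);
      int lo = std::min(selfq[i], selfp[j]);
      if (lo > 0 && acc >= tau * lo) hits.push_back({i, j, acc});
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_window_hits(IntegerVector q, IntegerVector p, IntegerMatrix m,
                          int w, double tau) {
  std::vector<Hit> hits;
  window_hits(q, p, m, w, tau, hits);
  std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    return a.q != b.q ? a.q < b.q : a.p < b.p;
  });
  int n = hits.size();
  IntegerVector qs(n), ps(n), sim(n);
  for (int i = 0; i < n; ++i) {
    qs[i] = hits[i].q; ps[i] = hits[i].p; sim[i] = hits[i].sim;
  }
  return DataFrame::create(_["q_start"] = qs, _["p_start"] = ps,
                           _["sim"] = sim);
}

// Merge hits on one diagonal into regions (query spans overlapping or within
// merge_gap of abutting are one region); region weight = max normalized sim.
// Returns the sum of region weights = the evidence weight ev(Q, P).
// [[Rcpp::export]]
double cpp_evidence_weight(IntegerVector q, IntegerVector p, IntegerMatrix m,
                           int w, double tau, int merge_gap) {
  std::vector<Hit> hits;
  window_hits(q, p, m, w, tau, hits);
  if (hits.empty()) return 0.0;
  std::vector<int> selfq = window_self_scores(q, m, w);
  std::vector<int> selfp = window_self_scores(p, m, w);
  // group by diagonal; hits are produced diagonal-by-diagonal in q order
  std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    int da = a.p - a.q, db = b.p - b.q;
    return da != db ? da < db : a.q < b.q;
  });
  double total = 0.0;
  int cur_d = hits[0].p - hits[0].q;
  int cur_end = hits[0].q + w;  // exclusive end of current region's q span
  double cur_w = (double)hits[0].sim /
                 std::min(selfq[hits[0].q], selfp[hits[0].p]);
  for (size_t k = 1; k < hits.size(); ++k) {
    int d = hits[k].p - hits[k].q;
    double nw = (double)hits[k].sim /
                std::min(selfq[hits[k].q], selfp[hits[k].p]);
    if (d == cur_d && hits[k].q <= cur_end + merge_gap) {
      cur_end = std::max(cur_end, hits[k].q + w);
      if (nw > cur_w) cur_w = nw;
    } else {
      total += cur_w;
      cur_d = d; cur_end = hits[k].q + w; cur_w = nw;
    }
  }
  total += cur_w;
  return total;
}

// Smith-Waterman local alignment, affine gaps: a gap of length L costs
// gap_open + L * gap_extend. Tie-break for the optimal cell: highest score,
// then smallest query end, then smallest subject end.
// [[Rcpp::export]]
List cpp_smith_waterman(IntegerVector q, IntegerVector p, IntegerMatrix m,
                        int gap_open, int gap_extend) {
  int n = q.size(), np = p.size();
  int go = gap_open + gap_extend;  // cost of opening a length-1 gap
  std::vector<std::vector<int>> H(n + 1, std::vector<int>(np + 1, 0));
  std::vector<std::vector<int>> E(n + 1, std::vector<int>(np + 1, 0));
  std::vector<std::vector<int>> F(n + 1, std::vector<int>(np + 1, 0));
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= np; ++j) {
      E[i][j] = std::max(H[i][j - 1] - go, E[i][j - 1] - gap_extend);
      F[i][j] = std::max(H[i - 1][j] - go, F[i - 1][j] - gap_extend);
      int diag = H[i - 1][j - 1] + m(q[i - 1], p[j - 1]);
      int h = std::max(0, std::max(diag, std::max(E[i][j], F[i][j])));
      H[i][j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best == 0)
    return List::create(_["score"] = 0, _["q_start"] = 0, _["q_end"] = 0,
                        _["p_start"] = 0, _["p_end"] = 0,
                        _["identity"] = NA_REAL);
  // traceback from (bi, bj)
  int i = bi, j = bj, matched = 0, cols = 0;
  enum { MH, ME, MF } state = MH;
  while (true) {
    if (state == MH) {
      if (H[i][j] == 0) break;
      if (H[i][j] == E[i][j]) { state = ME; continue; }
      if (H[i][j] == F[i][j]) { state = MF; continue; }
      // diagonal move
      ++cols;
      if (q[i - 1] == p[j - 1]) ++matched;
      --i; --j;
    } else if (state == ME) {
      ++cols;
      if (E[i][j] == H[i][j - 1] - go) state = MH;
      --j;
    } else {
      ++cols;
      if (F[i][j] == H[i - 1][j] - go) state = MH;
      --i;
    }
  }
  return List::create(
      _["score"] = best,
      _["q_start"] = i,      // 0-based half-open span [i, bi)
      _["q_end"] = bi,
      _["p_start"] = j,
      _["p_end"] = bj,
      _["identity"] = cols > 0 ? (double)matched / cols : NA_REAL);
}
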