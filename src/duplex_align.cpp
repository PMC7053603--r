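#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment of a (reversed) miRNA query against a
// target with affine gaps, a 4x4 base-substitution matrix and per-query-row
// multiplicative weights (the seed-window scaling). Repeatedly extracts the
// best local alignment, masks its target span and realigns, yielding
// maximal non-overlapping local optima in score order.
//
// Bases are encoded 1=A, 2=C, 3=G, 4=U. In the emitted alignment index
// vectors a 0 denotes a gap in that strand.

struct Hit {
  double score;
  int tstart, tend;                 // 1-based inclusive on target
  std::vector<int> q_idx, t_idx;    // aligned positions, 0 = gap
};

static bool sw_best(const IntegerVector& q, const IntegerVector& t,
                    const NumericMatrix& sub, const NumericVector& rowWeight,
                    double gapOpen, double gapExtend,
                    const std::vector<bool>& masked, Hit& hit) {
  const int m = q.size(), n = t.size();
  const double NEG = -1e18;
  // DP matrices: M (match/mismatch), X (gap in target / consume query),
  // Y (gap in query / consume target)
  std::vector<double> M((m + 1) * (n + 1), 0.0), X((m + 1) * (n + 1), NEG),
      Y((m + 1) * (n + 1), NEG);
  std::vector<unsigned char> tbM((m + 1) * (n + 1), 0), tbX((m + 1) * (n + 1), 0),
      tbY((m + 1) * (n + 1), 0);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  double best = 0.0;
  int bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      if (masked[j - 1]) {  // disallow alignments touching masked columns
        M[at(i, j)] = 0.0;
        X[at(i, j)] = NEG;
        Y[at(i, j)] = NEG;
        continue;
      }
      double s = sub(q[i - 1] - 1, t[j - 1] - 1) * rowWeight[i - 1];
      double dM = M[at(i - 1, j - 1)], dX = X[at(i - 1, j - 1)],
             dY = Y[at(i - 1, j - 1)];
      double dbest = dM;
      unsigned char dtb = 0;  // 0=M, 1=X, 2=Y
      if (dX > dbest) { dbest = dX; dtb = 1; }
      if (dY > dbest) { dbest = dY; dtb = 2; }
      double mv = dbest + s;
      if (mv < 0.0 || masked[j - 1]) mv = (mv < 0.0) ? 0.0 : mv;
      if (mv <= 0.0) { M[at(i, j)] = 0.0; tbM[at(i, j)] = 3; }  // local restart
      else { M[at(i, j)] = mv; tbM[at(i, j)] = dtb; }

      // X: gap in target (advance query)
      double xo = M[at(i - 1, j)] + gapOpen;
      double xe = X[at(i - 1, j)] + gapExtend;
      if (xo >= xe) { X[at(i, j)] = xo; tbX[at(i, j)] = 0; }
      else { X[at(i, j)] = xe; tbX[at(i, j)] = 1; }

      // Y: gap in query (advance target)
      double yo = M[at(i, j - 1)] + gapOpen;
      double ye = Y[at(i, j - 1)] + gapExtend;
      if (yo >= ye) { Y[at(i, j)] = yo; tbY[at(i, j)] = 0; }
      else { Y[at(i, j)] = ye; tbY[at(i, j)] = 2; }

      if (M[at(i, j)] > best) { best = M[at(i, j)]; bi = i; bj = j; }
    }
  }
  if (best <= 0.0 || bi < 0) return false;

  // traceback from (bi, bj) in state M until a local restart / zero cell
  std::vector<int> qi, tj;
  int i = bi, j = bj;
  int state = 0;  // 0=M, 1=X, 2=Y
  while (i > 0 && j > 0) {
    if (state == 0) {
      if (M[at(i, j)] <= 0.0) break;
      unsigned char tb = tbM[at(i, j)];
      qi.push_back(i); tj.push_back(j);
      --i; --j;
      if (tb == 3) break;  // restart cell consumed (shouldn't happen: score>0)
      state = tb;
      if (M[at(i, j)] <= 0.0 && state == 0 && tbM[at(i, j)] == 3) break;
      if (state == 0 && M[at(i, j)] == 0.0) break;
    } else if (state == 1) {
      qi.push_back(i); tj.push_back(0);
      unsigned char tb = tbX[at(i, j)];
      --i;
      state = (tb == 1) ? 1 : 0;
    } else {
      qi.push_back(0); tj.push_back(j);
      unsigned char tb = tbY[at(i, j)];
      --j;
      state = (tb == 2) ? 2 : 0;
    }
  }
  std::reverse(qi.begin(), qi.end());
  std::reverse(tj.begin(), tj.end());

  hit.score = best;
  hit.q_idx = qi;
  hit.t_idx = tj;
  int tmin = n + 1, tmax = 0;
  for (int v : tj) if (v > 0) { tmin = std::min(tmin, v); tmax = std::max(tmax, v); }
  hit.tstart = tmin;
  hit.tend = tmax;
  return tmax >= tmin;
}

// [[Rcpp::export]]
List duplex_align_cpp(IntegerVector q, IntegerVector t, NumericMatrix sub,
                      NumericVector rowWeight, double gapOpen,
                      double gapExtend, int maxHits, double minScore) {
  std::vector<bool> masked(t.size(), false);
  List hits;
  for (int h = 0; h < maxHits; ++h) {
    Hit hit;
    if (!sw_best(q, t, sub, rowWeight, gapOpen, gapExtend, masked, hit)) break;
    if (hit.score <= minScore) break;  // greedy scores are non-increasing
    for (int j = hit.tstart; j <= hit.tend; ++j) masked[j - 1] = true;
    hits.push_back(List::create(
        _["score"] = hit.score, _["tstart"] = hit.tstart,
        _["tend"] = hit.tend, _["q_idx"] = IntegerVector(hit.q_idx.begin(), hit.q_idx.end()),
        _["t_idx"] = IntegerVector(hit.t_idx.begin(), hit.t_idx.end())));
  }
  return hits;
}
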