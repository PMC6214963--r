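#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// miRNA target-site scanner. The miRNA binds its target site
// antiparallel, miRNA 5' end opposite the site 3' end. We align the
// miRNA read 3'->5' (index k below) along the transcript 5'->3' and
// score each aligned column with the plant complementarity expectation
// penalty: perfect Watson-Crick 0, G:U wobble 0.5, mismatch 1.0,
// gap/bulge 2.0; penalties are doubled when the column touches a
// miRNA position in [seedFrom, seedTo] counted from the miRNA 5' end.
// An inserted transcript base (bulge) is attributed to the next miRNA
// position toward the 5' end. Total gaps per site are capped.

// encoding A=0, C=1, G=2, U/T=3
static inline bool isWC(int m, int t) {
  return (m == 0 && t == 3) || (m == 3 && t == 0) || (m == 1 && t == 2) ||
         (m == 2 && t == 1);
}
static inline bool isWobble(int m, int t) {
  return (m == 2 && t == 3) || (m == 3 && t == 2);
}

// [[Rcpp::export(name = ".scanCpp")]]
DataFrame scanCpp(IntegerVector mirnaCode, IntegerVector txCode,
                  double cutoff, int maxGap, int seedFrom, int seedTo,
                  double mismatchPen, double wobblePen, double gapPen) {
  const int M = mirnaCode.size();
  const int T = txCode.size();
  const double INF = 1e18;

  std::vector<int> start_out, end_out;
  std::vector<double> e_out;
  std::vector<std::string> ops_out;

  // position weight of miRNA position p (1-based from 5')
  auto w = [&](int p) {
    if (p < 1) p = 1;
    if (p > M) p = M;
    return (p >= seedFrom && p <= seedTo) ? 2.0 : 1.0;
  };
  // mr[k] (k 1-based) is miRNA position M-k+1

  const int maxJ = M + maxGap;
  for (int s = 0; s + (M - maxGap) <= T; ++s) {
    int jlim = std::min(maxJ, T - s);
    // D[g][k][j]
    std::vector<double> D((size_t)(maxGap + 1) * (M + 1) * (jlim + 1), INF);
    auto at = [&](int g, int k, int j) {
      return ((size_t)g * (M + 1) + k) * (jlim + 1) + j;
    };
    for (int g = 0; g <= maxGap; ++g) D[at(g, 0, 0)] = 0.0;
    for (int k = 0; k <= M; ++k) {
      for (int j = 0; j <= jlim; ++j) {
        for (int g = 0; g <= maxGap; ++g) {
          double cur = D[at(g, k, j)];
          if (cur >= INF) continue;
          int pos = M - k; // miRNA position of mr[k+1]
          if (k < M && j < jlim) { // aligned column
            int m = mirnaCode[M - (k + 1)]; // mr[k+1] = mirna[M-k-1] 0-based
            int t = txCode[s + j];
            double pen = isWC(m, t) ? 0.0
                         : (isWobble(m, t) ? wobblePen * w(pos) : mismatchPen * w(pos));
            double v = cur + pen;
            if (v < D[at(g, k + 1, j + 1)]) D[at(g, k + 1, j + 1)] = v;
          }
          if (k < M && g < maxGap) { // miRNA base unpaired (gap in site)
            double v = cur + gapPen * w(pos);
            if (v < D[at(g + 1, k + 1, j)]) D[at(g + 1, k + 1, j)] = v;
          }
          if (j < jlim && g < maxGap && k < M) { // site base inserted (bulge)
            double v = cur + gapPen * w(pos);
            if (v < D[at(g + 1, k, j + 1)]) D[at(g + 1, k, j + 1)] = v;
          }
        }
      }
    }
    // best complete alignment for this start over site lengths
    double best = INF;
    int bestJ = -1, bestG = 0;
    for (int j = std::max(1, M - maxGap); j <= jlim; ++j) {
      for (int g = 0; g <= maxGap; ++g) {
        if (D[at(g, M, j)] < best) {
          best = D[at(g, M, j)];
          bestJ = j;
          bestG = g;
        }
      }
    }
    if (bestJ < 0 || best > cutoff + 1e-9) continue;
    // traceback for ops string (from miRNA 3' end toward 5')
    std::string ops;
    int k = M, j = bestJ, g = bestG;
    while (k > 0 || j > 0) {
      double cur = D[at(g, k, j)];
      int pos = M - k + 1; // position of mr[k] (column just placed)
      bool moved = false;
      if (k > 0 && j > 0) {
        int m = mirnaCode[M - k];
        int t = txCode[s + j - 1];
        double pen = isWC(m, t) ? 0.0
                     : (isWobble(m, t) ? wobblePen * w(pos) : mismatchPen * w(pos));
        if (D[at(g, k - 1, j - 1)] + pen == cur) {
          ops.push_back(isWC(m, t) ? 'M' : (isWobble(m, t) ? 'W' : 'X'));
          --k; --j;
          moved = true;
        }
      }
      if (!moved && k > 0 && g > 0 &&
          D[at(g - 1, k - 1, j)] + gapPen * w(pos) == cur) {
        ops.push_back('D'); // miRNA base unpaired
        --k; --g;
        moved = true;
      }
      if (!moved && j > 0 && g > 0 &&
          D[at(g - 1, k, j - 1)] + gapPen * w(M - k) == cur) {
        ops.push_back('I'); // transcript base inserted
        --j; --g;
        moved = true;
      }
      if (!moved) break; // numerical safety; should not happen
    }
    start_out.push_back(s + 1);
    end_out.push_back(s + bestJ);
    e_out.push_back(best);
    ops_out.push_back(ops); // miRNA 5'->3' (5'-end column first)
  }
  return DataFrame::create(_["start"] = start_out, _["end"] = end_out,
                           _["E"] = e_out, _["ops"] = ops_out,
                           _["stringsAsFactors"] = false);
}
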