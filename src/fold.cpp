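#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Secondary-structure folder with a stacking-energy model:
// a base pair contributes its stacking energy only when the adjacent
// inner pair (i+1, j-1) is also formed, so a helix of k pairs scores
// k-1 stacks and isolated pairs score 0. Unpaired bases are free.
// Stack energies (kcal/mol, attributed to the outer pair of the stack):
//   GC/CG -3, AU/UA -2, GU/UG -1.
// Minimum hairpin loop: 3 unpaired bases. Structures are nested
// (no pseudoknots). Ties in energy are broken by maximal pair count,
// then by 5'-most pairing during traceback, so output is deterministic.

static inline int pairEnergy(int a, int b) {
  // encoding A=0, C=1, G=2, U=3; returns 0 if not pairable
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return -3;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return -2;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return -1;
  return 0;
}

static inline bool canPair(int a, int b) { return pairEnergy(a, b) != 0; }

// Combined objective: minimize energy, then maximize pair count.
// key = energy * 2048 - npairs  (npairs < 1024 for n <= 1000 so the
// lexicographic order is preserved).
static inline int mkKey(int energy, int npairs) { return energy * 2048 - npairs; }

#define KEY_INF 0x3FFFFFFF

// [[Rcpp::export(name = ".foldCpp")]]
List foldCpp(IntegerVector seqCode, int minLoop) {
  const int n = seqCode.size();
  std::vector<int> s(seqCode.begin(), seqCode.end());

  // W[i][j]  : best key for region i..j, unconstrained
  // Wns[i][j]: best key for region i..j with (i,j) not paired together
  // V[i][j]  : best key for region i..j given i pairs with j
  std::vector<int> W((size_t)n * n, 0), Wns((size_t)n * n, 0),
      V((size_t)n * n, KEY_INF);
  auto at = [n](int i, int j) { return (size_t)i * n + j; };

  for (int d = 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      // V: (i,j) paired
      if (canPair(s[i], s[j]) && d - 1 >= minLoop) {
        int best = KEY_INF;
        // inner region empty or generic, (i+1,j-1) NOT paired together
        int inner = (d - 1 >= 2) ? Wns[at(i + 1, j - 1)] : 0;
        if (inner < KEY_INF) best = inner + mkKey(0, 1);
        // stacked on (i+1, j-1)
        if (d - 1 >= 2 && V[at(i + 1, j - 1)] < KEY_INF) {
          int cand = V[at(i + 1, j - 1)] + mkKey(pairEnergy(s[i], s[j]), 1);
          if (cand < best) best = cand;
        }
        V[at(i, j)] = best;
      }
      // W and Wns: j unpaired, or j paired with some k
      int bw = W[at(i, j - 1)];      // j unpaired
      int bwns = bw;
      for (int k = i; k <= j - minLoop - 1; ++k) {
        if (V[at(k, j)] == KEY_INF) continue;
        int left = (k > i) ? W[at(i, k - 1)] : 0;
        int cand = left + V[at(k, j)];
        if (cand < bw) bw = cand;
        if (k > i && cand < bwns) bwns = cand;
      }
      W[at(i, j)] = bw;
      Wns[at(i, j)] = bwns;
    }
  }

  // traceback (deterministic: prefer 5'-most pairing k, stack before open)
  IntegerVector pt(n, 0); // 1-based partner, 0 = unpaired
  struct Frame { int i, j, m; }; // m: 0=W, 1=Wns, 2=V
  std::vector<Frame> stack;
  if (n > 1) stack.push_back({0, n - 1, 0});
  while (!stack.empty()) {
    Frame f = stack.back();
    stack.pop_back();
    int i = f.i, j = f.j;
    if (j <= i) continue;
    if (f.m == 2) { // V: (i,j) paired
      pt[i] = j + 1;
      pt[j] = i + 1;
      int d = j - i;
      int target = V[at(i, j)] - mkKey(0, 1);
      if (d - 1 >= 2 && V[at(i + 1, j - 1)] < KEY_INF &&
          V[at(i + 1, j - 1)] + mkKey(pairEnergy(s[i], s[j]), 0) == target) {
        stack.push_back({i + 1, j - 1, 2});
      } else if (d - 1 >= 2) {
        stack.push_back({i + 1, j - 1, 1});
      }
      continue;
    }
    int goal = (f.m == 0) ? W[at(i, j)] : Wns[at(i, j)];
    int kmin = (f.m == 0) ? i : i + 1;
    bool done = false;
    for (int k = kmin; k <= j - minLoop - 1 && !done; ++k) {
      if (V[at(k, j)] == KEY_INF) continue;
      int left = (k > i) ? W[at(i, k - 1)] : 0;
      if (left + V[at(k, j)] == goal) {
        if (k > i) stack.push_back({i, k - 1, 0});
        stack.push_back({k, j, 2});
        done = true;
      }
    }
    if (!done) stack.push_back({i, j - 1, 0}); // j unpaired
  }

  int key = (n > 1) ? W[at(0, n - 1)] : 0;
  int npairs = 0;
  for (int i = 0; i < n; ++i)
    if (pt[i] > i + 1) ++npairs;
  int energy = (key + npairs) / 2048;
  return List::create(_["pairTable"] = pt, _["energy"] = (double)energy,
                      _["npairs"] = npairs);
}
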