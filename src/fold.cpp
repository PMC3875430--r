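#include <Rcpp.h>
#include <vector>
#include <stack>
using namespace Rcpp;

// Maximum weighted base-pairing (Nussinov-style) with a stacking-energy
// readout. The DP maximizes the sum of pair weights (GC > AU > GU); the
// reported energy then counts only stacked pairs, so isolated pairs in a
// random sequence contribute nothing while a contiguous helix scores about
// -2 to -3 kcal/mol per stack, in the range of nearest-neighbour stacks.

static inline double pair_weight(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3.0;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2.0;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1.0;
  return -1.0;  // not pairable
}

static inline double pair_energy(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3.3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2.1;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1.4;
  return 0.0;
}

// [[Rcpp::export]]
List nussinov_fold(std::string seq, int min_loop = 3) {
  int n = (int)seq.size();
  std::vector<int> partner(n, -1);
  if (n > 1) {
    std::vector<std::vector<double> > M(n, std::vector<double>(n, 0.0));
    for (int span = min_loop + 1; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        double best = M[i][j - 1];
        for (int k = i; k <= j - min_loop - 1; ++k) {
          double w = pair_weight(seq[k], seq[j]);
          if (w <= 0) continue;
          double cand = w + (k > i ? M[i][k - 1] : 0.0) + M[k + 1][j - 1];
          if (cand > best) best = cand;
        }
        M[i][j] = best;
      }
    }
    // iterative traceback; deterministic (first maximizing k wins)
    std::stack<std::pair<int, int> > todo;
    todo.push(std::make_pair(0, n - 1));
    while (!todo.empty()) {
      int i = todo.top().first, j = todo.top().second;
      todo.pop();
      if (j - i <= min_loop) continue;
      if (M[i][j] == M[i][j - 1]) {
        todo.push(std::make_pair(i, j - 1));
        continue;
      }
      for (int k = i; k <= j - min_loop - 1; ++k) {
        double w = pair_weight(seq[k], seq[j]);
        if (w <= 0) continue;
        double cand = w + (k > i ? M[i][k - 1] : 0.0) + M[k + 1][j - 1];
        if (cand == M[i][j]) {
          partner[k] = j;
          partner[j] = k;
          if (k > i) todo.push(std::make_pair(i, k - 1));
          todo.push(std::make_pair(k + 1, j - 1));
          break;
        }
      }
    }
  }
  std::string db(n, '.');
  double energy = 0.0;
  for (int i = 0; i < n; ++i) {
    int j = partner[i];
    if (j > i) {
      db[i] = '(';
      db[j] = ')';
      if (i + 1 < n && partner[i + 1] == j - 1 && j - 1 > i + 1) {
        energy -= (pair_energy(seq[i], seq[j]) +
                   pair_energy(seq[i + 1], seq[j - 1])) / 2.0;
      }
    } else if (j >= 0) {
      db[i] = ')';
    }
  }
  IntegerVector part(n);
  for (int i = 0; i < n; ++i) part[i] = partner[i] + 1;  // 1-based, 0 = unpaired
  return List::create(_["structure"] = db, _["mfe"] = energy,
                      _["partner"] = part);
}
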