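#include <Rcpp.h>
using namespace Rcpp;

// Backtracking search for a block-balanced serially counterbalanced
// sequence: n blocks of n trial types, each block a permutation of the
// types, such that every ordered pair of types (self-pairs included)
// occurs exactly once among the n^2 cyclic adjacencies. Junction
// adjacencies between blocks are then necessarily the self-pairs.
//
// Candidate successors are ordered by fewest onward options (Warnsdorff's
// rule) with random tie-breaking; the search restarts from scratch when a
// backtrack budget is exhausted. Randomness comes from R's RNG so results
// are reproducible under set.seed().

// [[Rcpp::export(name = ".type1_blocked_search")]]
IntegerVector type1_blocked_search(int n, int max_backtracks,
                                   int max_restarts) {
  const int N = n * n;
  std::vector<char> used(n * n);     // used[prev * n + v]
  std::vector<char> inblock(n);      // membership of current-position block
  std::vector<int> seq(N);
  // per-position candidate stacks
  std::vector<std::vector<int> > cand(N);
  std::vector<char> cand_set(N);

  for (int restart = 0; restart < max_restarts; ++restart) {
    std::fill(used.begin(), used.end(), 0);
    std::fill(cand_set.begin(), cand_set.end(), 0);
    std::vector<std::vector<char> > blk(n, std::vector<char>(n, 0));
    int p = 0;
    long backtracks = 0;
    bool fail = false;

    while (p < N) {
      int b = p / n;
      int posb = p % n;
      if (!cand_set[p]) {
        std::vector<int> cc;
        if (p == 0) {
          for (int v = 0; v < n; ++v) cc.push_back(v);
          // Fisher-Yates with R RNG
          for (int i = n - 1; i > 0; --i) {
            int j = (int)(unif_rand() * (i + 1));
            if (j > i) j = i;
            std::swap(cc[i], cc[j]);
          }
        } else if (posb == 0) {
          int prev = seq[p - 1];
          if (!used[prev * n + prev]) cc.push_back(prev);
        } else {
          int prev = seq[p - 1];
          std::vector<int> ok;
          for (int v = 0; v < n; ++v)
            if (v != prev && !blk[b][v] && !used[prev * n + v])
              ok.push_back(v);
          if (p == N - 1) {
            int s0 = seq[0];
            bool feas = false;
            for (size_t i = 0; i < ok.size(); ++i)
              if (ok[i] == s0) feas = true;
            cc.clear();
            if (feas && !used[s0 * n + s0]) cc.push_back(s0);
          } else {
            // onward degree of each candidate; zero onward = dead end
            std::vector<std::pair<double, int> > scored;
            for (size_t i = 0; i < ok.size(); ++i) {
              int v = ok[i];
              int deg = 0;
              if (posb == n - 1) {
                deg = used[v * n + v] ? 0 : 1;
              } else {
                for (int w = 0; w < n; ++w)
                  if (w != v && !blk[b][w] && !used[v * n + w]) ++deg;
              }
              if (deg > 0)
                scored.push_back(std::make_pair(deg + unif_rand(), v));
            }
            std::sort(scored.begin(), scored.end());
            // stack pops from the back: push worst first
            for (int i = (int)scored.size() - 1; i >= 0; --i)
              cc.push_back(scored[i].second);
            std::reverse(cc.begin(), cc.end());
          }
        }
        cand[p] = cc;
        cand_set[p] = 1;
      }
      if (cand[p].empty()) {
        cand_set[p] = 0;
        --p;
        ++backtracks;
        if (p < 0 || backtracks > max_backtracks) { fail = true; break; }
        int v = seq[p];
        blk[p / n][v] = 0;
        if (p > 0) used[seq[p - 1] * n + v] = 0;
        continue;
      }
      int v = cand[p].front();
      cand[p].erase(cand[p].begin());
      seq[p] = v;
      blk[b][v] = 1;
      if (p > 0) used[seq[p - 1] * n + v] = 1;
      ++p;
    }
    if (!fail) {
      IntegerVector out(N);
      for (int i = 0; i < N; ++i) out[i] = seq[i] + 1;
      return out;
    }
  }
  return IntegerVector(0);  // signals failure
}
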