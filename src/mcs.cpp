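// Branch-and-bound search for the maximum common connected induced
// subgraph of two molecular graphs. Atoms match by element, bonds by order
// class (aromatic is its own class); budgets au/bu allow a bounded number
// of atom-label and bond-label mismatches (bond presence/absence must
// always agree: the common subgraph is induced). Deterministic expansion:
// seed atoms in index order, fail-first vertex selection, candidate
// targets in index order, so results are machine-independent.

#include <Rcpp.h>
#include <chrono>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Searcher {
  int nA, nB;
  std::vector<int> elA, elB;
  std::vector<std::vector<int>> adjA, adjB;   // bond class, 0 = none
  std::vector<std::vector<int>> nbrA;
  int au, bu;
  double timeout;
  std::chrono::steady_clock::time_point t0;
  bool exhausted;
  int best;
  std::vector<int> bestMapA;
  std::vector<int> mapA, mapB;
  long long ticks;

  bool timeUp() {
    if ((++ticks & 1023) != 0) return false;
    double el = std::chrono::duration<double>(
        std::chrono::steady_clock::now() - t0).count();
    if (el > timeout) { exhausted = false; return true; }
    return false;
  }

  bool done() const { return best >= std::min(nA, nB); }

  void record(int size) {
    if (size > best) { best = size; bestMapA = mapA; }
  }

  void extend(std::vector<char>& excluded, int size, int usedAu, int usedBu) {
    record(size);
    if (done() || !exhausted || timeUp()) return;
    int remA = 0, remB = 0;
    for (int i = 0; i < nA; ++i) if (mapA[i] < 0 && !excluded[i]) ++remA;
    for (int j = 0; j < nB; ++j) if (mapB[j] < 0) ++remB;
    if (size + std::min(remA, remB) <= best) return;

    // frontier vertex with fewest compatible candidates (fail-first)
    int pickV = -1;
    std::vector<int> pickCand;
    for (int v = 0; v < nA; ++v) {
      if (mapA[v] >= 0 || excluded[v]) continue;
      bool frontier = false;
      for (int u : nbrA[v]) if (mapA[u] >= 0) { frontier = true; break; }
      if (!frontier) continue;
      std::vector<int> cand;
      for (int w = 0; w < nB; ++w) {
        if (mapB[w] >= 0) continue;
        int aCost = (elA[v] != elB[w]) ? 1 : 0;
        if (usedAu + aCost > au) continue;
        bool ok = true, attached = false;
        int bCost = 0;
        for (int u = 0; u < nA; ++u) {
          if (mapA[u] < 0) continue;
          int ca = adjA[v][u], cb = adjB[w][mapA[u]];
          if ((ca == 0) != (cb == 0)) { ok = false; break; }
          if (ca != 0) {
            attached = true;
            if (ca != cb) ++bCost;
          }
        }
        if (!ok || !attached || usedBu + bCost > bu) continue;
        cand.push_back(w);
      }
      if (pickV < 0 || cand.size() < pickCand.size()) {
        pickV = v;
        pickCand.swap(cand);
        if (pickCand.empty()) break;
      }
    }
    if (pickV < 0) return;
    int v = pickV;
    for (int w : pickCand) {
      int aCost = (elA[v] != elB[w]) ? 1 : 0;
      int bCost = 0;
      for (int u = 0; u < nA; ++u) {
        if (mapA[u] < 0) continue;
        int ca = adjA[v][u];
        if (ca != 0 && ca != adjB[w][mapA[u]]) ++bCost;
      }
      mapA[v] = w; mapB[w] = v;
      extend(excluded, size + 1, usedAu + aCost, usedBu + bCost);
      mapA[v] = -1; mapB[w] = -1;
      if (done() || !exhausted) return;
    }
    excluded[v] = 1;
    extend(excluded, size, usedAu, usedBu);
    excluded[v] = 0;
  }

  void run() {
    best = 0;
    exhausted = true;
    ticks = 0;
    mapA.assign(nA, -1);
    mapB.assign(nB, -1);
    t0 = std::chrono::steady_clock::now();
    for (int v0 = 0; v0 < nA; ++v0) {
      if (nA - v0 <= best || done() || !exhausted) break;
      std::vector<char> excluded(nA, 0);
      for (int i = 0; i < v0; ++i) excluded[i] = 1;
      for (int w = 0; w < nB; ++w) {
        int aCost = (elA[v0] != elB[w]) ? 1 : 0;
        if (aCost > au) continue;
        mapA[v0] = w; mapB[w] = v0;
        extend(excluded, 1, aCost, 0);
        mapA[v0] = -1; mapB[w] = -1;
        if (done() || !exhausted) break;
      }
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".mcsSearch")]]
List mcsSearch(IntegerVector elA, IntegerMatrix bondsA,
               IntegerVector elB, IntegerMatrix bondsB,
               int au, int bu, double timeout) {
  Searcher s;
  s.nA = elA.size();
  s.nB = elB.size();
  s.elA.assign(elA.begin(), elA.end());
  s.elB.assign(elB.begin(), elB.end());
  s.adjA.assign(s.nA, std::vector<int>(s.nA, 0));
  s.adjB.assign(s.nB, std::vector<int>(s.nB, 0));
  s.nbrA.assign(s.nA, {});
  for (int i = 0; i < bondsA.nrow(); ++i) {
    int a = bondsA(i, 0) - 1, b = bondsA(i, 1) - 1, c = bondsA(i, 2);
    s.adjA[a][b] = s.adjA[b][a] = c;
    s.nbrA[a].push_back(b);
    s.nbrA[b].push_back(a);
  }
  for (int i = 0; i < bondsB.nrow(); ++i) {
    int a = bondsB(i, 0) - 1, b = bondsB(i, 1) - 1, c = bondsB(i, 2);
    s.adjB[a][b] = s.adjB[b][a] = c;
  }
  s.au = au; s.bu = bu; s.timeout = timeout;
  if (s.nA == 0 || s.nB == 0) {
    return List::create(_["c"] = 0, _["mapping"] = IntegerMatrix(0, 2),
                        _["exhausted"] = true);
  }
  s.run();
  int c = s.best;
  IntegerMatrix mapping(c, 2);
  int k = 0;
  for (int v = 0; v < s.nA; ++v)
    if (s.bestMapA.size() && s.bestMapA[v] >= 0) {
      mapping(k, 0) = v + 1;
      mapping(k, 1) = s.bestMapA[v] + 1;
      ++k;
    }
  return List::create(_["c"] = c, _["mapping"] = mapping,
                      _["exhausted"] = s.exhausted);
}
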