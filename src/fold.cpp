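#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Minimum-free-energy RNA folding (single strand, pseudoknot-free) and
// intermolecular duplex hybridisation under a simplified nearest-neighbour
// model. Energies are handled internally as integer tenths of kcal/mol.
//
// Tie-breaking: subproblem keys are E*1024 + npairs, so lexicographic
// minimisation of (energy, number of pairs) is exact as long as a structure
// never holds >= 1024 pairs (sequence length is capped well below that).

static const int64_t INF = INT64_C(1) << 50;
static const int64_t KP = 1024;  // pair-count slot width in the key

// base codes: A=0, C=1, G=2, U=3
static inline int pair_index(int a, int b) {
  if (a == 0 && b == 3) return 0;  // AU
  if (a == 1 && b == 2) return 1;  // CG
  if (a == 2 && b == 1) return 2;  // GC
  if (a == 2 && b == 3) return 3;  // GU
  if (a == 3 && b == 0) return 4;  // UA
  if (a == 3 && b == 2) return 5;  // UG
  return -1;
}

struct LoopPar {
  int hairpin_base, hairpin_per, bulge_base, bulge_per;
  int internal_base, internal_per;
  int multi_base, multi_branch, multi_unpaired;
  int max_loop, min_hairpin;
};

static LoopPar read_loop_par(List lp) {
  LoopPar p;
  // values arrive in kcal/mol; convert to decikcal integers
  p.hairpin_base = (int)std::lround(10.0 * as<double>(lp["hairpin_base"]));
  p.hairpin_per = (int)std::lround(10.0 * as<double>(lp["hairpin_per_nt"]));
  p.bulge_base = (int)std::lround(10.0 * as<double>(lp["bulge_base"]));
  p.bulge_per = (int)std::lround(10.0 * as<double>(lp["bulge_per_nt"]));
  p.internal_base = (int)std::lround(10.0 * as<double>(lp["internal_base"]));
  p.internal_per = (int)std::lround(10.0 * as<double>(lp["internal_per_nt"]));
  p.multi_base = (int)std::lround(10.0 * as<double>(lp["multi_base"]));
  p.multi_branch = (int)std::lround(10.0 * as<double>(lp["multi_branch"]));
  p.multi_unpaired = (int)std::lround(10.0 * as<double>(lp["multi_unpaired"]));
  p.max_loop = as<int>(lp["max_loop"]);
  p.min_hairpin = as<int>(lp["min_hairpin"]);
  return p;
}

// interior-loop / bulge / stack step cost between pair (i,j) and inner pair
// (k,l), unpaired g1 = k-i-1 on the 5' side and g2 = j-l-1 on the 3' side
static inline int64_t step_cost(int g1, int g2, int pij, int pkl,
                                const IntegerMatrix &st, const LoopPar &p) {
  if (g1 == 0 && g2 == 0) return st(pij, pkl);
  if (g1 == 0 || g2 == 0) return p.bulge_base + p.bulge_per * (g1 + g2);
  return p.internal_base + p.internal_per * (g1 + g2);
}

// [[Rcpp::export]]
List c_fold_mfe(IntegerVector seq, IntegerMatrix stack_deci, List loop_par) {
  const int n = seq.size();
  LoopPar p = read_loop_par(loop_par);
  if (n < 1) stop("empty sequence");
  if (n >= 1000) stop("sequence too long for folding");

  std::vector<int> s(seq.begin(), seq.end());
  std::vector<int64_t> V((size_t)n * n, INF), WM((size_t)n * n, INF),
      WM1((size_t)n * n, INF);
  auto at = [n](int i, int j) { return (size_t)i * n + j; };

  const int64_t b_br = (int64_t)p.multi_branch * KP;
  const int64_t c_up = (int64_t)p.multi_unpaired * KP;

  for (int span = p.min_hairpin + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int pij = pair_index(s[i], s[j]);
      if (pij >= 0 && j - i - 1 >= p.min_hairpin) {
        // hairpin loop
        int L = j - i - 1;
        int64_t best = (int64_t)(p.hairpin_base + p.hairpin_per * L) * KP + 1;
        // stack / bulge / interior
        for (int k = i + 1; k < j && k - i - 1 <= p.max_loop; ++k) {
          for (int l = j - 1; l > k; --l) {
            int g1 = k - i - 1, g2 = j - l - 1;
            if (g1 + g2 > p.max_loop) break;
            int64_t vkl = V[at(k, l)];
            if (vkl >= INF) continue;
            int pkl = pair_index(s[k], s[l]);
            int64_t cand =
                vkl + step_cost(g1, g2, pij, pkl, stack_deci, p) * KP + 1;
            if (cand < best) best = cand;
          }
        }
        // multiloop: closing pair + >= 2 branches
        int64_t mlbase = (int64_t)(p.multi_base) * KP + b_br + 1;
        for (int k = i + 2; k <= j - 2; ++k) {
          int64_t a = WM[at(i + 1, k - 1)];
          int64_t b = WM1[at(k, j - 1)];
          if (a >= INF || b >= INF) continue;
          int64_t cand = mlbase + a + b;
          if (cand < best) best = cand;
        }
        V[at(i, j)] = best;
      }
      // WM1: exactly one branch starting at i, optional trailing unpaired
      {
        int64_t best = INF;
        if (V[at(i, j)] < INF) best = V[at(i, j)] + b_br;
        if (j > i && WM1[at(i, j - 1)] < INF) {
          int64_t cand = WM1[at(i, j - 1)] + c_up;
          if (cand < best) best = cand;
        }
        WM1[at(i, j)] = best;
      }
      // WM: >= 1 branch anywhere in [i, j]
      {
        int64_t best = WM1[at(i, j)];
        if (WM[at(i + 1, j)] < INF) {
          int64_t cand = WM[at(i + 1, j)] + c_up;
          if (cand < best) best = cand;
        }
        for (int k = i + 1; k <= j; ++k) {
          int64_t a = WM[at(i, k - 1)], b = WM1[at(k, j)];
          if (a >= INF || b >= INF) continue;
          int64_t cand = a + b;
          if (cand < best) best = cand;
        }
        WM[at(i, j)] = best;
      }
    }
  }
  // small spans: WM/WM1 over spans < min_hairpin + 1 stay INF except
  // unpaired-extension, which cannot start without a branch; leave INF.

  // external loop
  std::vector<int64_t> W(n, 0);
  for (int j = 0; j < n; ++j) {
    int64_t best = (j > 0) ? W[j - 1] : 0;  // j unpaired, free
    for (int i = 0; i <= j; ++i) {
      int64_t v = V[at(i, j)];
      if (v >= INF) continue;
      int64_t cand = (i > 0 ? W[i - 1] : 0) + v;
      if (cand < best) best = cand;
    }
    W[j] = best;
  }

  // traceback
  std::string db(n, '.');
  struct Item { int type, i, j; };  // 0=EXT(0..j), 1=V, 2=WM, 3=WM1
  std::vector<Item> stk;
  if (n > 0) stk.push_back({0, 0, n - 1});
  while (!stk.empty()) {
    Item it = stk.back();
    stk.pop_back();
    int i = it.i, j = it.j;
    if (it.type == 0) {
      int jj = j;
      while (jj >= 0) {
        int64_t target = W[jj];
        if (jj > 0 && W[jj - 1] == target) { --jj; continue; }
        if (jj == 0 && target == 0) break;
        bool found = false;
        for (int i0 = 0; i0 <= jj && !found; ++i0) {
          int64_t v = V[at(i0, jj)];
          if (v >= INF) continue;
          if ((i0 > 0 ? W[i0 - 1] : 0) + v == target) {
            stk.push_back({1, i0, jj});
            jj = i0 - 1;
            found = true;
          }
        }
        if (!found) break;  // defensive; should not happen
      }
    } else if (it.type == 1) {
      int64_t target = V[at(i, j)];
      db[i] = '(';
      db[j] = ')';
      int pij = pair_index(s[i], s[j]);
      int L = j - i - 1;
      if ((int64_t)(p.hairpin_base + p.hairpin_per * L) * KP + 1 == target)
        continue;
      bool found = false;
      for (int k = i + 1; k < j && k - i - 1 <= p.max_loop && !found; ++k) {
        for (int l = j - 1; l > k; --l) {
          int g1 = k - i - 1, g2 = j - l - 1;
          if (g1 + g2 > p.max_loop) break;
          int64_t vkl = V[at(k, l)];
          if (vkl >= INF) continue;
          int pkl = pair_index(s[k], s[l]);
          if (vkl + step_cost(g1, g2, pij, pkl, stack_deci, p) * KP + 1 ==
              target) {
            stk.push_back({1, k, l});
            found = true;
            break;
          }
        }
      }
      if (found) continue;
      int64_t mlbase = (int64_t)(p.multi_base) * KP + b_br + 1;
      for (int k = i + 2; k <= j - 2 && !found; ++k) {
        int64_t a = WM[at(i + 1, k - 1)], b = WM1[at(k, j - 1)];
        if (a >= INF || b >= INF) continue;
        if (mlbase + a + b == target) {
          stk.push_back({2, i + 1, k - 1});
          stk.push_back({3, k, j - 1});
          found = true;
        }
      }
    } else if (it.type == 2) {
      int64_t target = WM[at(i, j)];
      if (WM1[at(i, j)] == target) { stk.push_back({3, i, j}); continue; }
      if (i + 1 <= j && WM[at(i + 1, j)] < INF &&
          WM[at(i + 1, j)] + c_up == target) {
        stk.push_back({2, i + 1, j});
        continue;
      }
      for (int k = i + 1; k <= j; ++k) {
        int64_t a = WM[at(i, k - 1)], b = WM1[at(k, j)];
        if (a >= INF || b >= INF) continue;
        if (a + b == target) {
          stk.push_back({2, i, k - 1});
          stk.push_back({3, k, j});
          break;
        }
      }
    } else {
      int64_t target = WM1[at(i, j)];
      int jj = j;
      while (jj > i && WM1[at(i, jj - 1)] < INF &&
             WM1[at(i, jj - 1)] + c_up == target) {
        target = WM1[at(i, jj - 1)];
        --jj;
      }
      stk.push_back({1, i, jj});
    }
  }

  int64_t key = W[n - 1];
  int64_t np = ((key % KP) + KP) % KP;
  int64_t e = (key - np) / KP;
  return List::create(_["mfe"] = (double)e / 10.0,
                      _["npairs"] = (int)np,
                      _["structure"] = db);
}

// Intermolecular duplex: miRNA (5'->3') vs target window, antiparallel.
// No intramolecular structure; consecutive pairs score nearest-neighbour
// stacks, gaps score bulge/interior penalties; helix ends are free.
// [[Rcpp::export]]
List c_duplex_mfe(IntegerVector mirna, IntegerVector window,
                  IntegerMatrix stack_deci, List loop_par, int max_gap) {
  LoopPar p = read_loop_par(loop_par);
  const int m = mirna.size(), w = window.size();
  if (m < 1 || w < 1) stop("empty sequence");
  std::vector<int> a(mirna.begin(), mirna.end());
  std::vector<int> t(w);  // reversed target: t[k] = window[w-1-k]
  for (int k = 0; k < w; ++k) t[k] = window[w - 1 - k];

  std::vector<int64_t> D((size_t)m * w, INF);
  auto at = [w](int i, int k) { return (size_t)i * w + k; };
  for (int i = 0; i < m; ++i) {
    for (int k = 0; k < w; ++k) {
      int pik = pair_index(a[i], t[k]);
      if (pik < 0) continue;
      int64_t best = 1;  // first pair of the duplex: energy 0, one pair
      for (int ip = std::max(0, i - 1 - max_gap); ip < i; ++ip) {
        for (int kp = std::max(0, k - 1 - max_gap); kp < k; ++kp) {
          int64_t d = D[at(ip, kp)];
          if (d >= INF) continue;
          int g1 = i - ip - 1, g2 = k - kp - 1;
          int pprev = pair_index(a[ip], t[kp]);
          int64_t cand =
              d + step_cost(g1, g2, pprev, pik, stack_deci, p) * KP + 1;
          if (cand < best) best = cand;
        }
      }
      D[at(i, k)] = best;
    }
  }

  int64_t bestkey = INF;
  int bi = -1, bk = -1;
  for (int i = 0; i < m; ++i)
    for (int k = 0; k < w; ++k) {
      int64_t d = D[at(i, k)];
      // prefer larger k (leftmost on the original target) on ties
      if (d < bestkey || (d == bestkey && k > bk)) {
        bestkey = d;
        bi = i;
        bk = k;
      }
    }
  if (bestkey >= INF) {  // no pair possible anywhere
    return List::create(_["energy"] = 0.0, _["npairs"] = 0,
                        _["target_start"] = NA_INTEGER,
                        _["target_end"] = NA_INTEGER,
                        _["mirna_start"] = NA_INTEGER,
                        _["mirna_end"] = NA_INTEGER);
  }
  // traceback for duplex extent
  int i = bi, k = bk, i0 = bi, k0 = bk;
  int64_t key = bestkey;
  while (key != 1) {
    bool found = false;
    int pik = pair_index(a[i], t[k]);
    for (int ip = std::max(0, i - 1 - max_gap); ip < i && !found; ++ip) {
      for (int kp = std::max(0, k - 1 - max_gap); kp < k; ++kp) {
        int64_t d = D[at(ip, kp)];
        if (d >= INF) continue;
        int g1 = i - ip - 1, g2 = k - kp - 1;
        int pprev = pair_index(a[ip], t[kp]);
        if (d + step_cost(g1, g2, pprev, pik, stack_deci, p) * KP + 1 == key) {
          key = d;
          i = ip;
          k = kp;
          i0 = ip;
          k0 = kp;
          found = true;
          break;
        }
      }
    }
    if (!found) break;  // defensive
  }
  int64_t np = ((bestkey % KP) + KP) % KP;
  int64_t e = (bestkey - np) / KP;
  // original target coordinates (0-based): reversed index k -> w-1-k
  int tstart = w - 1 - bk, tend = w - 1 - k0;
  return List::create(_["energy"] = (double)e / 10.0, _["npairs"] = (int)np,
                      _["target_start"] = tstart, _["target_end"] = tend + 1,
                      _["mirna_start"] = i0, _["mirna_end"] = bi + 1);
}
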