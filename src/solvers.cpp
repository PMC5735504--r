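#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Deterministic RNG independent of R's RNG state: splitmix64 seeded stream.
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed + 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  int below(int n) { return n <= 1 ? 0 : (int)(next() % (uint64_t)n); }
};

static inline double tour_len(const std::vector<int>& t, const NumericMatrix& w) {
  double c = 0.0;
  int n = t.size();
  for (int i = 0; i < n; ++i) c += w(t[i], t[(i + 1) % n]);
  return c;
}

// k nearest neighbours of each vertex by weight (ties by index).
static std::vector<std::vector<int> > neighbour_lists(const NumericMatrix& w, int k) {
  int n = w.nrow();
  std::vector<std::vector<int> > cand(n);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) {
    idx.clear();
    for (int j = 0; j < n; ++j) if (j != i) idx.push_back(j);
    int kk = std::min(k, (int)idx.size());
    std::partial_sort(idx.begin(), idx.begin() + kk, idx.end(),
                      [&](int a, int b) {
                        double wa = w(i, a), wb = w(i, b);
                        return wa < wb || (wa == wb && a < b);
                      });
    cand[i].assign(idx.begin(), idx.begin() + kk);
  }
  return cand;
}

// 2-opt + Or-opt local search on a cyclic tour with candidate lists and
// don't-look bits. Improves `tour` in place until no improving move remains.
static void local_search(std::vector<int>& tour, const NumericMatrix& w,
                         const std::vector<std::vector<int> >& cand) {
  int n = tour.size();
  if (n < 4) return;
  std::vector<int> pos(n);
  for (int i = 0; i < n; ++i) pos[tour[i]] = i;
  std::vector<char> dontlook(n, 0);
  std::vector<int> queue;
  for (int i = 0; i < n; ++i) queue.push_back(i);

  auto succ = [&](int v) { return tour[(pos[v] + 1) % n]; };
  auto pred = [&](int v) { return tour[(pos[v] + n - 1) % n]; };
  auto reverse_seg = [&](int i, int j) {
    // reverse tour positions i..j (cyclic), choosing the shorter side
    int len = (j - i + n) % n + 1;
    if (len > n / 2) { int ni = (j + 1) % n, nj = (i + n - 1) % n; i = ni; j = nj; len = n - len; }
    for (int k2 = 0; k2 < len / 2; ++k2) {
      int a = (i + k2) % n, b = (j - k2 + n) % n;
      std::swap(tour[a], tour[b]);
      pos[tour[a]] = a; pos[tour[b]] = b;
    }
  };

  bool improved = true;
  while (improved) {
    improved = false;
    for (int a = 0; a < n; ++a) {
      if (dontlook[a]) continue;
      bool found = false;
      // 2-opt: remove (a, succ a) and (b, succ b), add (a,b), (sa, sb)
      for (int dir = 0; dir < 2 && !found; ++dir) {
        int sa = dir == 0 ? succ(a) : pred(a);
        double w_asa = w(a, sa);
        for (size_t ci = 0; ci < cand[a].size(); ++ci) {
          int b = cand[a][ci];
          if (b == sa) continue;
          double w_ab = w(a, b);
          if (w_ab >= w_asa) break;  // candidates sorted; no gain possible
          int sb = dir == 0 ? succ(b) : pred(b);
          if (sb == a) continue;
          double gain = w_asa + w(b, sb) - w_ab - w(sa, sb);
          if (gain > 1e-9) {
            if (dir == 0) reverse_seg(pos[sa], pos[b]);
            else reverse_seg(pos[b], pos[sa]);
            dontlook[a] = dontlook[b] = dontlook[sa] = dontlook[sb] = 0;
            found = true; improved = true;
            break;
          }
        }
      }
      // Or-opt: move segment of length 1..3 starting at a elsewhere
      if (!found) {
        for (int L = 1; L <= 3 && !found; ++L) {
          if (n < L + 3) break;
          int p0 = pos[a];
          int pend = (p0 + L - 1) % n;
          int s_first = a, s_last = tour[pend];
          int before = tour[(p0 + n - 1) % n], after = tour[(pend + 1) % n];
          if (after == before) break;
          double removed = w(before, s_first) + w(s_last, after) - w(before, after);
          if (removed <= 1e-9) continue;
          for (size_t ci = 0; ci < cand[s_first].size() && !found; ++ci) {
            int c = cand[s_first][ci];
            // skip if c inside segment or adjacent boundary
            int pc = pos[c];
            int off = (pc - p0 + n) % n;
            if (off < L) continue;
            if (c == before) continue;
            int d = succ(c);
            int offd = (pos[d] - p0 + n) % n;
            if (offd < L) continue;
            // insert segment (possibly reversed) between c and d
            double add_f = w(c, s_first) + w(s_last, d);
            double add_r = w(c, s_last) + w(s_first, d);
            bool rev = add_r < add_f;
            double added = (rev ? add_r : add_f) - w(c, d);
            if (removed - added > 1e-9) {
              // rebuild tour: remove L elements at p0.., insert after c
              std::vector<int> seg(L);
              for (int k2 = 0; k2 < L; ++k2) seg[k2] = tour[(p0 + k2) % n];
              if (rev) std::reverse(seg.begin(), seg.end());
              std::vector<int> nt; nt.reserve(n);
              int v = after;
              while (true) {
                nt.push_back(v);
                if (v == c) for (int k2 = 0; k2 < L; ++k2) nt.push_back(seg[k2]);
                if ((int)nt.size() >= n) break;
                int pv = (pos[v] + 1) % n;
                // advance skipping the removed segment
                v = tour[pv];
                int offv = (pos[v] - p0 + n) % n;
                if (offv < L) { pv = (pend + 1) % n; v = tour[pv]; }
              }
              tour.swap(nt);
              for (int k2 = 0; k2 < n; ++k2) pos[tour[k2]] = k2;
              dontlook.assign(n, 0);
              found = true; improved = true;
            }
          }
        }
      }
      if (!found) dontlook[a] = 1;
    }
  }
}

static std::vector<int> nn_tour(const NumericMatrix& w, int start) {
  int n = w.nrow();
  std::vector<int> tour; tour.reserve(n);
  std::vector<char> used(n, 0);
  int cur = start; used[cur] = 1; tour.push_back(cur);
  for (int step = 1; step < n; ++step) {
    int best = -1; double bw = 0;
    for (int j = 0; j < n; ++j) {
      if (used[j]) continue;
      double wj = w(cur, j);
      if (best < 0 || wj < bw || (wj == bw && j < best)) { best = j; bw = wj; }
    }
    used[best] = 1; tour.push_back(best); cur = best;
  }
  return tour;
}

static void double_bridge(std::vector<int>& tour, SplitMix& rng) {
  int n = tour.size();
  if (n < 8) return;
  int a = 1 + rng.below(n - 3);
  int b = a + 1 + rng.below(n - a - 2);
  int c = b + 1 + rng.below(n - b - 1);
  std::vector<int> nt; nt.reserve(n);
  nt.insert(nt.end(), tour.begin(), tour.begin() + a);
  nt.insert(nt.end(), tour.begin() + b, tour.begin() + c);
  nt.insert(nt.end(), tour.begin() + a, tour.begin() + b);
  nt.insert(nt.end(), tour.begin() + c, tour.end());
  tour.swap(nt);
}

// [[Rcpp::export]]
IntegerVector cpp_solve_tour(NumericMatrix w, int n_starts, int n_perturb,
                             double seed, int n_candidates) {
  int n = w.nrow();
  if (n == 1) return IntegerVector::create(1);
  if (n == 2) return IntegerVector::create(1, 2);
  SplitMix rng((uint64_t)seed);
  std::vector<std::vector<int> > cand =
      neighbour_lists(w, std::min(n_candidates, n - 1));
  std::vector<int> best;
  double best_cost = 0;
  for (int s = 0; s < n_starts; ++s) {
    int start = (s == 0) ? 0 : rng.below(n);
    std::vector<int> tour = nn_tour(w, start);
    local_search(tour, w, cand);
    double cost = tour_len(tour, w);
    // chained local search: perturb + reoptimize, keep improvements
    std::vector<int> cur = tour; double cur_cost = cost;
    for (int p = 0; p < n_perturb; ++p) {
      std::vector<int> t2 = cur;
      double_bridge(t2, rng);
      local_search(t2, w, cand);
      double c2 = tour_len(t2, w);
      if (c2 < cur_cost - 1e-9) { cur = t2; cur_cost = c2; }
    }
    if (cur_cost < cost) { tour = cur; cost = cur_cost; }
    if (best.empty() || cost < best_cost - 1e-9) { best = tour; best_cost = cost; }
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = best[i] + 1;
  return out;
}

// Held-Karp dynamic programming: optimal Hamiltonian cycle through all
// vertices, anchored at `start` (0-based). Returns the cycle as a vertex
// sequence beginning at start. Ties broken toward smaller vertex indices.
// [[Rcpp::export]]
IntegerVector cpp_held_karp(NumericMatrix w, int start) {
  int n = w.nrow();
  if (n > 24) stop("Held-Karp limited to 24 vertices");
  std::vector<int> others;
  for (int i = 0; i < n; ++i) if (i != start) others.push_back(i);
  int m = others.size();
  if (m == 0) return IntegerVector::create(start + 1);
  size_t nstates = (size_t)1 << m;
  std::vector<double> dp(nstates * m, R_PosInf);
  std::vector<int> par(nstates * m, -1);
  for (int j = 0; j < m; ++j)
    dp[((size_t)1 << j) * m + j] = w(start, others[j]);
  for (size_t S = 1; S < nstates; ++S) {
    for (int j = 0; j < m; ++j) {
      if (!(S & ((size_t)1 << j))) continue;
      double dj = dp[S * m + j];
      if (!R_FINITE(dj)) continue;
      for (int k = 0; k < m; ++k) {
        if (S & ((size_t)1 << k)) continue;
        size_t S2 = S | ((size_t)1 << k);
        size_t idx = S2 * m + k;
        double nd = dj + w(others[j], others[k]);
        if (nd < dp[idx] - 1e-12) {
          dp[idx] = nd; par[idx] = j;
        } else if (nd <= dp[idx] + 1e-12 &&
                   (par[idx] < 0 || others[j] < others[par[idx]])) {
          par[idx] = j;
        }
      }
    }
  }
  size_t full = nstates - 1;
  int bj = -1; double bcost = R_PosInf;
  for (int j = 0; j < m; ++j) {
    double c = dp[full * m + j] + w(others[j], start);
    if (bj < 0 || c < bcost - 1e-12) { bcost = c; bj = j; }
    else if (c <= bcost + 1e-12 && others[j] < others[bj]) { bj = j; }
  }
  std::vector<int> seq;
  size_t S = full; int j = bj;
  while (j >= 0) {
    seq.push_back(others[j]);
    int pj = par[S * m + j];
    S &= ~((size_t)1 << j);
    j = pj;
    if (S == 0) break;
  }
  std::reverse(seq.begin(), seq.end());
  IntegerVector out(m + 1);
  out[0] = start + 1;
  for (int i = 0; i < m; ++i) out[i + 1] = seq[i] + 1;
  return out;
}

struct DSU {
  std::vector<int> p;
  explicit DSU(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  bool join(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    p[b] = a; return true;
  }
};

// Kruskal MST on a complete graph given by a symmetric weight matrix.
// Edges are considered in order (weight, min index, max index); returns the
// m-1 accepted edges (1-based i < j) with their weights.
// [[Rcpp::export]]
List cpp_kruskal_mst(NumericMatrix w) {
  int n = w.nrow();
  size_t ne = (size_t)n * (n - 1) / 2;
  std::vector<int> ei(ne), ej(ne);
  std::vector<double> ew(ne);
  std::vector<size_t> ord(ne);
  size_t t = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) { ei[t] = i; ej[t] = j; ew[t] = w(i, j); ++t; }
  for (size_t x = 0; x < ne; ++x) ord[x] = x;
  std::stable_sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (ew[a] != ew[b]) return ew[a] < ew[b];
    if (ei[a] != ei[b]) return ei[a] < ei[b];
    return ej[a] < ej[b];
  });
  DSU dsu(n);
  IntegerVector mi(n - 1), mj(n - 1);
  NumericVector mw(n - 1);
  int got = 0;
  for (size_t x = 0; x < ne && got < n - 1; ++x) {
    size_t e = ord[x];
    if (dsu.join(ei[e], ej[e])) {
      mi[got] = ei[e] + 1; mj[got] = ej[e] + 1; mw[got] = ew[e]; ++got;
    }
  }
  return List::create(_["i"] = mi, _["j"] = mj, _["rf"] = mw);
}

// Inversion count of an integer sequence via merge sort.
// [[Rcpp::export]]
double cpp_count_inversions(IntegerVector x) {
  int n = x.size();
  std::vector<int> a(x.begin(), x.end()), buf(n);
  double inv = 0;
  for (int width = 1; width < n; width *= 2) {
    for (int lo = 0; lo < n; lo += 2 * width) {
      int mid = std::min(lo + width, n), hi = std::min(lo + 2 * width, n);
      int i = lo, j = mid, k = lo;
      while (i < mid && j < hi) {
        if (a[i] <= a[j]) buf[k++] = a[i++];
        else { inv += mid - i; buf[k++] = a[j++]; }
      }
      while (i < mid) buf[k++] = a[i++];
      while (j < hi) buf[k++] = a[j++];
    }
    std::copy(buf.begin(), buf.end(), a.begin());
  }
  return inv;
}
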