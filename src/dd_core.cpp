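// Double-description inner loop for elementary mode enumeration.
//
// Rays are exact int64 vectors (kept primitive by gcd reduction); supports
// over processed coordinates are packed bitsets.  Combination products are
// formed in 128-bit intermediates and must reduce back into +/- 2^62,
// otherwise enumeration aborts rather than lose exactness.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

typedef int64_t i64;
#ifdef __SIZEOF_INT128__
typedef __int128 i128;
#else
#error "128-bit integer support required"
#endif

static const i64 HARD_MAX = (i64(1) << 62);

static i64 gcd64(i64 a, i64 b) {
  if (a < 0) a = -a;
  if (b < 0) b = -b;
  while (b) { i64 t = a % b; a = b; b = t; }
  return a;
}

// Bit-pattern tree over ray supports for fast "exists support subset of U"
// queries: each node splits on one coordinate bit; a query only descends
// into the with-bit branch when that bit is present in U.
struct BPTree {
  struct Node { int bit; int lo, hi; std::vector<int> leaf; };
  std::vector<Node> nodes;
  const std::vector<std::vector<uint64_t> >* supp;
  int words;

  int build(std::vector<int>& idx, int begin, int end,
            std::vector<uint64_t>& avail) {
    Node nd; nd.bit = -1; nd.lo = nd.hi = -1;
    if (end - begin <= 8) {
      nd.leaf.assign(idx.begin() + begin, idx.begin() + end);
      nodes.push_back(nd);
      return (int) nodes.size() - 1;
    }
    // choose the available bit closest to an even split
    int best_bit = -1, best_score = -1;
    const int n = end - begin;
    for (int w = 0; w < words; ++w) {
      uint64_t m = avail[w];
      while (m) {
        int b = w * 64 + __builtin_ctzll(m);
        m &= m - 1;
        int c = 0;
        for (int k = begin; k < end; ++k)
          if ((*supp)[idx[k]][b / 64] & (uint64_t(1) << (b % 64))) ++c;
        int score = std::min(c, n - c);
        if (score > best_score) { best_score = score; best_bit = b; }
      }
    }
    if (best_bit < 0 || best_score == 0) {
      nd.leaf.assign(idx.begin() + begin, idx.begin() + end);
      nodes.push_back(nd);
      return (int) nodes.size() - 1;
    }
    int mid = begin;
    for (int k = begin; k < end; ++k)
      if (!((*supp)[idx[k]][best_bit / 64] &
            (uint64_t(1) << (best_bit % 64)))) std::swap(idx[mid++], idx[k]);
    avail[best_bit / 64] &= ~(uint64_t(1) << (best_bit % 64));
    nd.bit = best_bit;
    int self = (int) nodes.size();
    nodes.push_back(nd);
    int lo = build(idx, begin, mid, avail);   // rays without the bit
    int hi = build(idx, mid, end, avail);     // rays with the bit
    avail[best_bit / 64] |= (uint64_t(1) << (best_bit % 64));
    nodes[self].lo = lo; nodes[self].hi = hi;
    return self;
  }

  // true iff some ray (other than p, q) has support contained in U
  bool query(int node, const std::vector<uint64_t>& U, int p, int q) const {
    const Node& nd = nodes[node];
    if (nd.bit < 0) {
      for (size_t k = 0; k < nd.leaf.size(); ++k) {
        int r = nd.leaf[k];
        if (r == p || r == q) continue;
        bool subset = true;
        for (int w = 0; w < words; ++w)
          if ((*supp)[r][w] & ~U[w]) { subset = false; break; }
        if (subset) return true;
      }
      return false;
    }
    if (query(nd.lo, U, p, q)) return true;
    if (U[nd.bit / 64] & (uint64_t(1) << (nd.bit % 64)))
      return query(nd.hi, U, p, q);
    return false;
  }
};

// [[Rcpp::export(name = ".dd_core_cpp")]]
NumericMatrix dd_core_cpp(NumericMatrix rays0, IntegerVector pivots,
                          IntegerVector remaining0, double max_rays,
                          bool quiet) {
  const int nn = rays0.ncol();
  const int words = (nn + 63) / 64;

  std::vector<std::vector<i64> > val;
  for (int i = 0; i < rays0.nrow(); ++i) {
    std::vector<i64> v(nn);
    for (int j = 0; j < nn; ++j) v[j] = (i64) rays0(i, j);
    val.push_back(v);
  }
  const int d0 = rays0.nrow();       // kernel dimension
  std::vector<char> processed(nn, 0);
  int pcount = 0;
  for (int k = 0; k < pivots.size(); ++k) {
    processed[pivots[k] - 1] = 1;
    ++pcount;
  }
  std::vector<int> remaining;
  for (int k = 0; k < remaining0.size(); ++k)
    remaining.push_back(remaining0[k] - 1);

  auto build_supp = [&](const std::vector<i64>& v) {
    std::vector<uint64_t> s(words, 0);
    for (int j = 0; j < nn; ++j)
      if (processed[j] && v[j] != 0) s[j / 64] |= (uint64_t(1) << (j % 64));
    return s;
  };

  while (!remaining.empty()) {
    // cheapest constraint first: fewest (+)x(-) combinations
    size_t best = 0; double best_cost = -1;
    for (size_t k = 0; k < remaining.size(); ++k) {
      int h = remaining[k];
      double np = 0, nm = 0;
      for (size_t i = 0; i < val.size(); ++i) {
        if (val[i][h] > 0) ++np; else if (val[i][h] < 0) ++nm;
      }
      double cost = std::max(np, 1.0) * std::max(nm, 1.0);
      if (best_cost < 0 || cost < best_cost) { best_cost = cost; best = k; }
    }
    int h = remaining[best];
    remaining.erase(remaining.begin() + best);

    std::vector<int> P, N, Z;
    for (size_t i = 0; i < val.size(); ++i) {
      if (val[i][h] > 0) P.push_back(i);
      else if (val[i][h] < 0) N.push_back(i);
      else Z.push_back(i);
    }

    std::vector<std::vector<uint64_t> > supp(val.size());
    for (size_t i = 0; i < val.size(); ++i) supp[i] = build_supp(val[i]);
    BPTree tree;
    tree.supp = &supp;
    tree.words = words;
    int root = -1;
    {
      std::vector<int> idx(val.size());
      for (size_t i = 0; i < val.size(); ++i) idx[i] = i;
      std::vector<uint64_t> avail(words, 0);
      for (int j = 0; j < nn; ++j)
        if (processed[j]) avail[j / 64] |= (uint64_t(1) << (j % 64));
      root = tree.build(idx, 0, (int) idx.size(), avail);
    }

    std::vector<std::vector<i64> > keep;
    for (size_t k = 0; k < P.size(); ++k) keep.push_back(val[P[k]]);
    for (size_t k = 0; k < Z.size(); ++k) keep.push_back(val[Z[k]]);

    std::vector<uint64_t> uni(words);
    for (size_t ip = 0; ip < P.size(); ++ip) {
      for (size_t iq = 0; iq < N.size(); ++iq) {
        const int p = P[ip], q = N[iq];
        // rank-based necessary condition for adjacency: the two rays must
        // share at least d0 - 2 zero coordinates among the processed ones
        int ipc = 0;
        for (int w = 0; w < words; ++w) {
          uni[w] = supp[p][w] | supp[q][w];
          ipc += __builtin_popcountll(uni[w]);
        }
        if (pcount - ipc < d0 - 2) continue;
        // adjacency: no third ray's processed support inside the union
        if (tree.query(root, uni, p, q)) continue;
        const i64 a = val[q][h] < 0 ? -val[q][h] : val[q][h];
        const i64 b = val[p][h];
        std::vector<i64> comb(nn);
        i64 g = 0;
        for (int j = 0; j < nn; ++j) {
          i128 x = (i128) a * val[p][j] + (i128) b * val[q][j];
          if (x > (i128) HARD_MAX || x < -(i128) HARD_MAX)
            stop("elementary mode enumeration: exact integer range exceeded");
          comb[j] = (i64) x;
          g = gcd64(g, comb[j]);
        }
        if (g > 1) for (int j = 0; j < nn; ++j) comb[j] /= g;
        keep.push_back(comb);
        if ((double) keep.size() > max_rays)
          stop("elementary mode enumeration exceeded ray ceiling (%d)",
               (int) max_rays);
      }
      if (ip % 64 == 0) Rcpp::checkUserInterrupt();
    }
    val.swap(keep);
    processed[h] = 1;
    ++pcount;
    if (!quiet)
      Rcpp::Rcout << "  constraint " << (h + 1) << " processed: "
                  << val.size() << " rays (" << P.size() << "+ " << N.size()
                  << "- " << Z.size() << "0)" << std::endl;
    if (val.empty()) break;
  }

  NumericMatrix out(val.size(), nn);
  for (size_t i = 0; i < val.size(); ++i)
    for (int j = 0; j < nn; ++j) out(i, j) = (double) val[i][j];
  return out;
}
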