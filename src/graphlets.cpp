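// Per-node graphlet orbit counting by ESU enumeration of connected
// induced subgraphs on 2-5 nodes. Orbit identity is resolved through
// lookup tables (labelled adjacency mask -> per-position orbit id)
// precomputed in R from the graphlet catalogue.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct EsuState {
  const std::vector<std::vector<int> >* adj; // neighbour lists
  const std::vector<uint64_t>* bits;         // adjacency bit matrix, row stride
  size_t stride;                             // words per row
  std::vector<int> cntAdj;                   // #neighbours inside sub
  std::vector<int> sub;
  int k;
  const int* lookup;                         // length (1<<C(k,2)) * k
  NumericMatrix* counts;                     // n x 73
};

inline bool adjacent(const EsuState& st, int u, int v) {
  return ((*st.bits)[st.stride * u + (v >> 6)] >> (v & 63)) & 1ull;
}

void record(EsuState& st) {
  const int k = st.k;
  int s[5];
  for (int i = 0; i < k; ++i) s[i] = st.sub[i];
  std::sort(s, s + k);
  int mask = 0, bit = 0;
  for (int i = 0; i < k - 1; ++i)
    for (int j = i + 1; j < k; ++j, ++bit)
      if (adjacent(st, s[i], s[j])) mask |= (1 << bit);
  const int* row = st.lookup + (size_t)mask * k;
  for (int pos = 0; pos < k; ++pos) {
    int orb = row[pos];
    if (orb >= 0) (*st.counts)(s[pos], orb) += 1.0;
  }
}

void extend(EsuState& st, std::vector<int>& ext, int v) {
  if ((int)st.sub.size() == st.k) { record(st); return; }
  std::vector<int> pool(ext);
  while (!pool.empty()) {
    int w = pool.back();
    pool.pop_back();
    std::vector<int> nxt(pool);
    const std::vector<int>& nb = (*st.adj)[w];
    for (size_t t = 0; t < nb.size(); ++t) {
      int u = nb[t];
      if (u > v && st.cntAdj[u] == 0) nxt.push_back(u);
    }
    st.sub.push_back(w);
    for (size_t t = 0; t < nb.size(); ++t) st.cntAdj[nb[t]]++;
    extend(st, nxt, v);
    for (size_t t = 0; t < nb.size(); ++t) st.cntAdj[nb[t]]--;
    st.sub.pop_back();
  }
}

} // namespace

// [[Rcpp::export(name = ".countGraphletOrbits")]]
NumericMatrix countGraphletOrbits(List adjList, IntegerVector lk2,
                                  IntegerVector lk3, IntegerVector lk4,
                                  IntegerVector lk5) {
  const int n = adjList.size();
  std::vector<std::vector<int> > adj(n);
  const size_t stride = (size_t)((n + 63) / 64);
  std::vector<uint64_t> bits(stride * (size_t)n, 0ull);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adjList[i];
    adj[i].assign(nb.begin(), nb.end());
    std::sort(adj[i].begin(), adj[i].end());
    for (size_t t = 0; t < adj[i].size(); ++t)
      bits[stride * i + (adj[i][t] >> 6)] |= (1ull << (adj[i][t] & 63));
  }
  NumericMatrix counts(n, 73);
  const IntegerVector* lks[4] = { &lk2, &lk3, &lk4, &lk5 };
  for (int k = 2; k <= 5; ++k) {
    EsuState st;
    st.adj = &adj;
    st.bits = &bits;
    st.stride = stride;
    st.cntAdj.assign(n, 0);
    st.k = k;
    st.lookup = lks[k - 2]->begin();
    st.counts = &counts;
    for (int v = 0; v < n; ++v) {
      std::vector<int> ext;
      const std::vector<int>& nb = adj[v];
      for (size_t t = 0; t < nb.size(); ++t)
        if (nb[t] > v) ext.push_back(nb[t]);
      st.sub.clear();
      st.sub.push_back(v);
      for (size_t t = 0; t < nb.size(); ++t) st.cntAdj[nb[t]]++;
      extend(st, ext, v);
      for (size_t t = 0; t < nb.size(); ++t) st.cntAdj[nb[t]]--;
      st.sub.pop_back();
    }
  }
  return counts;
}
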