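#include <Rcpp.h>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Degree-preserving double-edge-swap chain over a simple undirected graph.
// Edges are 1-based node index pairs.  Each of n_swaps attempts picks two
// distinct edges; if their four endpoints are distinct, one of the two
// rewirings is proposed uniformly and accepted unless it would create a
// duplicate edge (self-loops cannot arise with distinct endpoints).  Uses
// R's RNG so results are reproducible under set.seed().

static inline long long ekey(int u, int v, int n) {
    int a = u < v ? u : v;
    int b = u < v ? v : u;
    return (long long)a * (n + 1) + b;
}

static void run_chain(std::vector<int> &a, std::vector<int> &b,
                      std::unordered_set<long long> &present,
                      int n_nodes, int n_swaps) {
    int m = (int)a.size();
    for (int s = 0; s < n_swaps; ++s) {
        int e1 = (int)(unif_rand() * m);
        int e2 = (int)(unif_rand() * m);
        if (e1 >= m) e1 = m - 1;
        if (e2 >= m) e2 = m - 1;
        if (e1 == e2) continue;
        int x1 = a[e1], y1 = b[e1], x2 = a[e2], y2 = b[e2];
        if (x1 == x2 || x1 == y2 || y1 == x2 || y1 == y2) continue;
        int na1, nb1, na2, nb2;
        if (unif_rand() < 0.5) {
            na1 = x1; nb1 = x2; na2 = y1; nb2 = y2;  // (a-c, b-d)
        } else {
            na1 = x1; nb1 = y2; na2 = y1; nb2 = x2;  // (a-d, b-c)
        }
        long long k1 = ekey(na1, nb1, n_nodes), k2 = ekey(na2, nb2, n_nodes);
        if (present.count(k1) || present.count(k2)) continue;
        present.erase(ekey(x1, y1, n_nodes));
        present.erase(ekey(x2, y2, n_nodes));
        present.insert(k1);
        present.insert(k2);
        a[e1] = na1; b[e1] = nb1;
        a[e2] = na2; b[e2] = nb2;
    }
}

static void load_edges(const IntegerMatrix &edges, int n_nodes,
                       std::vector<int> &a, std::vector<int> &b,
                       std::unordered_set<long long> &present) {
    int m = edges.nrow();
    a.resize(m); b.resize(m);
    for (int i = 0; i < m; ++i) {
        a[i] = edges(i, 0);
        b[i] = edges(i, 1);
        present.insert(ekey(a[i], b[i], n_nodes));
    }
}

// [[Rcpp::export]]
IntegerMatrix edge_swap_cpp(IntegerMatrix edges, int n_nodes, int n_swaps) {
    if (edges.nrow() < 2) return clone(edges);
    std::vector<int> a, b;
    std::unordered_set<long long> present;
    load_edges(edges, n_nodes, a, b, present);
    RNGScope scope;
    run_chain(a, b, present, n_nodes, n_swaps);
    int m = (int)a.size();
    IntegerMatrix out(m, 2);
    for (int i = 0; i < m; ++i) {
        out(i, 0) = a[i];
        out(i, 1) = b[i];
    }
    return out;
}

// Randomize once and count, for each nominated node, its neighbors with
// enriched == TRUE.  `enriched` is indexed by node id (1-based).
// [[Rcpp::export]]
IntegerVector swap_and_count_cpp(IntegerMatrix edges, int n_nodes,
                                 int n_swaps, LogicalVector enriched,
                                 IntegerVector nominated) {
    std::vector<int> a, b;
    std::unordered_set<long long> present;
    load_edges(edges, n_nodes, a, b, present);
    if (edges.nrow() >= 2) {
        RNGScope scope;
        run_chain(a, b, present, n_nodes, n_swaps);
    }
    std::vector<int> count(n_nodes + 1, 0);
    std::vector<bool> wanted(n_nodes + 1, false);
    for (int j = 0; j < nominated.size(); ++j) wanted[nominated[j]] = true;
    int m = (int)a.size();
    for (int i = 0; i < m; ++i) {
        if (wanted[a[i]] && enriched[b[i] - 1]) count[a[i]]++;
        if (wanted[b[i]] && enriched[a[i] - 1]) count[b[i]]++;
    }
    IntegerVector out(nominated.size());
    for (int j = 0; j < nominated.size(); ++j) out[j] = count[nominated[j]];
    return out;
}
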