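#include <Rcpp.h>
#include <vector>

// Bounded enumeration of simple paths (no repeated node) between two
// distinct vertices of an undirected graph, counting lengths in edges.
// The search aborts once `ceiling` paths have been found and reports
// truncation, so pathological gene pairs cannot hang the caller.

namespace {

struct SearchState {
    const std::vector<std::vector<int>>& adj;
    std::vector<char> visited;
    int target;
    int cap;
    double ceiling;
    double count = 0.0;
    int shortest = -1;
    int longest = -1;
    bool truncated = false;

    SearchState(const std::vector<std::vector<int>>& a, int t, int cap_,
                double ceil_)
        : adj(a), visited(a.size(), 0), target(t), cap(cap_),
          ceiling(ceil_) {}

    void dfs(int u, int depth) {
        if (truncated) return;
        for (int v : adj[u]) {
            int d = depth + 1;
            if (d > cap) break;  // depth+1 identical for all neighbors
            if (v == target) {
                count += 1.0;
                if (shortest < 0 || d < shortest) shortest = d;
                if (d > longest) longest = d;
                if (count >= ceiling) { truncated = true; return; }
            } else if (!visited[v] && d < cap) {
                visited[v] = 1;
                dfs(v, d);
                visited[v] = 0;
                if (truncated) return;
            }
        }
    }
};

} // namespace

// adj: list of integer vectors, 1-based neighbor indices per vertex.
// from/to: 1-based vertex indices, from != to.
// Returns c(count, shortest, longest, truncated); -1 = unreachable.
// [[Rcpp::export(name = ".count_simple_paths")]]
Rcpp::NumericVector count_simple_paths(Rcpp::List adj, int from, int to,
                                       int cap, double ceiling) {
    int n = adj.size();
    if (from < 1 || from > n || to < 1 || to > n || from == to)
        Rcpp::stop("invalid vertex indices");
    std::vector<std::vector<int>> a(n);
    for (int i = 0; i < n; ++i) {
        Rcpp::IntegerVector nb = adj[i];
        a[i].assign(nb.begin(), nb.end());
        for (int& v : a[i]) --v;
    }
    SearchState st(a, to - 1, cap, ceiling);
    if (cap >= 1) {
        st.visited[from - 1] = 1;
        st.dfs(from - 1, 0);
    }
    return Rcpp::NumericVector::create(
        st.count, st.shortest, st.longest, st.truncated ? 1.0 : 0.0);
}
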