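// String-to-DAG matching kernels.
//
// A haplotype is consistent with a variation graph iff some source->sink
// path spells it, with epsilon (sequence-free) nodes consuming no
// characters. Consistency is decided by NFA-style simulation over node
// sets with epsilon closure; accepting paths are enumerated from the
// forward/backward-pruned product DAG of (node, characters consumed).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Graph {
  int n;
  std::vector<int> is_base;    // 0/1
  std::vector<int> code;       // base nodes: 0..3 (ACGT), else -1
  // CSR out-adjacency (targets sorted by construction order = node index
  // order when the caller pre-sorts edges)
  std::vector<int> out_ptr, out_v;
  std::vector<int> in_ptr, in_v;
  int source, sink;
};

int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

Graph build_graph(int n, const IntegerVector& is_base,
                  const CharacterVector& label,
                  const IntegerVector& from, const IntegerVector& to,
                  int source, int sink) {
  Graph g;
  g.n = n;
  g.is_base.assign(is_base.begin(), is_base.end());
  g.code.assign(n, -1);
  for (int i = 0; i < n; ++i) {
    if (g.is_base[i]) {
      const char* s = CHAR(STRING_ELT(label, i));
      g.code[i] = base_code(s[0]);
      if (g.code[i] < 0) stop("base node with non-ACGT label");
    }
  }
  int m = from.size();
  g.out_ptr.assign(n + 1, 0);
  g.in_ptr.assign(n + 1, 0);
  for (int e = 0; e < m; ++e) {
    ++g.out_ptr[from[e] + 1];   // caller passes 0-based endpoints
    ++g.in_ptr[to[e] + 1];
  }
  for (int i = 0; i < n; ++i) {
    g.out_ptr[i + 1] += g.out_ptr[i];
    g.in_ptr[i + 1] += g.in_ptr[i];
  }
  g.out_v.assign(m, 0);
  g.in_v.assign(m, 0);
  std::vector<int> op(g.out_ptr.begin() + 1, g.out_ptr.end());
  std::vector<int> ip(g.in_ptr.begin() + 1, g.in_ptr.end());
  // fill in reverse so each adjacency block keeps ascending edge order
  for (int e = m - 1; e >= 0; --e) {
    g.out_v[--op[from[e]]] = to[e];
    g.in_v[--ip[to[e]]] = from[e];
  }
  g.source = source;
  g.sink = sink;
  return g;
}

// add v and everything reachable from v through epsilon-kind nodes
void closure_from(const Graph& g, int v, std::vector<int>& set,
                  std::vector<int>& stamp, int tick) {
  if (stamp[v] == tick) return;
  stamp[v] = tick;
  set.push_back(v);
  static thread_local std::vector<int> stk;
  stk.clear();
  stk.push_back(v);
  while (!stk.empty()) {
    int u = stk.back(); stk.pop_back();
    for (int k = g.out_ptr[u]; k < g.out_ptr[u + 1]; ++k) {
      int w = g.out_v[k];
      if (!g.is_base[w] && stamp[w] != tick) {
        stamp[w] = tick;
        set.push_back(w);
        stk.push_back(w);
      }
    }
  }
}

bool consistent_one(const Graph& g, const std::string& hap,
                    std::vector<int>& stamp, int& tick) {
  std::vector<int> cur, nxt;
  ++tick;
  closure_from(g, g.source, cur, stamp, tick);
  for (char ch : hap) {
    int c = base_code(ch);
    if (c < 0) stop("haplotype contains a non-ACGT character");
    ++tick;
    nxt.clear();
    for (int u : cur) {
      for (int k = g.out_ptr[u]; k < g.out_ptr[u + 1]; ++k) {
        int v = g.out_v[k];
        if (g.is_base[v] && g.code[v] == c && stamp[v] != tick) {
          closure_from(g, v, nxt, stamp, tick);
        }
      }
    }
    cur.swap(nxt);
    if (cur.empty()) return false;
  }
  return stamp[g.sink] == tick;
}

} // namespace

// [[Rcpp::export]]
LogicalVector cpp_consistent(int n, IntegerVector is_base,
                             CharacterVector label,
                             IntegerVector from, IntegerVector to,
                             int source, int sink,
                             CharacterVector haplotypes) {
  Graph g = build_graph(n, is_base, label, from, to, source, sink);
  std::vector<int> stamp(n, 0);
  int tick = 0;
  int nh = haplotypes.size();
  LogicalVector res(nh);
  for (int i = 0; i < nh; ++i) {
    std::string hap = as<std::string>(haplotypes[i]);
    res[i] = consistent_one(g, hap, stamp, tick);
  }
  return res;
}

// [[Rcpp::export]]
List cpp_accepting_paths(int n, IntegerVector is_base, CharacterVector label,
                         IntegerVector from, IntegerVector to,
                         int source, int sink,
                         std::string hap, int cap) {
  Graph g = build_graph(n, is_base, label, from, to, source, sink);
  const long long L = (long long)hap.size();
  const long long total = (long long)n * (L + 1);
  if (total > 200000000LL) {
    stop("product of graph size and haplotype length too large to enumerate");
  }
  std::vector<int> hcode(L);
  for (long long i = 0; i < L; ++i) {
    hcode[i] = base_code(hap[i]);
    if (hcode[i] < 0) stop("haplotype contains a non-ACGT character");
  }
  auto sid = [&](int node, long long i) { return (long long)node * (L + 1) + i; };

  // forward reachability over product states (node, chars consumed)
  std::vector<uint8_t> fwd(total, 0);
  std::vector<long long> stk;
  fwd[sid(g.source, 0)] = 1;
  stk.push_back(sid(g.source, 0));
  while (!stk.empty()) {
    long long s = stk.back(); stk.pop_back();
    int u = (int)(s / (L + 1));
    long long i = s % (L + 1);
    for (int k = g.out_ptr[u]; k < g.out_ptr[u + 1]; ++k) {
      int v = g.out_v[k];
      long long j;
      if (g.is_base[v]) {
        if (i >= L || g.code[v] != hcode[i]) continue;
        j = i + 1;
      } else {
        j = i;
      }
      long long t = sid(v, j);
      if (!fwd[t]) { fwd[t] = 1; stk.push_back(t); }
    }
  }

  List out;
  long long accept = sid(g.sink, L);
  if (!fwd[accept]) {
    return List::create(_["paths"] = List(0), _["truncated"] = false);
  }

  // backward co-reachability from the accepting state
  std::vector<uint8_t> keep(total, 0);
  keep[accept] = 1;
  stk.push_back(accept);
  while (!stk.empty()) {
    long long s = stk.back(); stk.pop_back();
    int v = (int)(s / (L + 1));
    long long i = s % (L + 1);
    long long j = g.is_base[v] ? i - 1 : i;
    if (j < 0) continue;
    for (int k = g.in_ptr[v]; k < g.in_ptr[v + 1]; ++k) {
      int u = g.in_v[k];
      long long t = sid(u, j);
      if (fwd[t] && !keep[t]) { keep[t] = 1; stk.push_back(t); }
    }
  }

  // deterministic DFS (out-neighbours in node-index order) with a path cap
  std::vector<IntegerVector> paths;
  bool truncated = false;
  std::vector<int> path_nodes;
  // frame: (state, next out-edge offset)
  std::vector<std::pair<long long, int>> frames;
  frames.push_back({sid(g.source, 0), 0});
  path_nodes.push_back(g.source);
  while (!frames.empty()) {
    auto& fr = frames.back();
    int u = (int)(fr.first / (L + 1));
    long long i = fr.first % (L + 1);
    if (fr.first == accept && fr.second == 0) {
      if ((int)paths.size() >= cap) { truncated = true; break; }
      IntegerVector pv(path_nodes.size());
      for (size_t q = 0; q < path_nodes.size(); ++q) pv[q] = path_nodes[q] + 1;
      paths.push_back(pv);
      // sink has no outgoing edges worth exploring; fall through to pop
    }
    bool descended = false;
    while (fr.second < g.out_ptr[u + 1] - g.out_ptr[u]) {
      int v = g.out_v[g.out_ptr[u] + fr.second];
      ++fr.second;
      long long j = g.is_base[v] ? i + 1 : i;
      if (g.is_base[v] && (i >= L || g.code[v] != hcode[i])) continue;
      long long t = sid(v, j);
      if (!keep[t]) continue;
      frames.push_back({t, 0});
      path_nodes.push_back(v);
      descended = true;
      break;
    }
    if (!descended) {
      frames.pop_back();
      path_nodes.pop_back();
    }
  }

  List plist(paths.size());
  for (size_t q = 0; q < paths.size(); ++q) plist[q] = paths[q];
  return List::create(_["paths"] = plist, _["truncated"] = truncated);
}
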