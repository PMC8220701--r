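#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exhaustive enumeration of simple paths that start at given source nodes,
// end at target nodes, and have at most max_len edges.  Directed arcs only
// (undirected interactions are passed as two opposite arcs).  Paths may run
// through intermediate targets; every prefix ending at a target is recorded.
// Node and arc indices are 0-based; adjacency order follows the input arc
// order, so deterministic output requires arcs sorted by (from, to, edge).
// [[Rcpp::export]]
List enumerate_seed_paths_cpp(IntegerVector arc_from,
                              IntegerVector arc_to,
                              IntegerVector arc_edge,
                              int n_nodes,
                              IntegerVector sources,
                              LogicalVector is_target,
                              int max_len,
                              double max_paths,
                              double max_steps) {
  const int n_arcs = arc_from.size();
  std::vector<int> head(n_nodes + 1, 0);
  for (int a = 0; a < n_arcs; ++a) head[arc_from[a] + 1]++;
  for (int v = 0; v < n_nodes; ++v) head[v + 1] += head[v];
  std::vector<int> adj_to(n_arcs), adj_edge(n_arcs);
  {
    std::vector<int> pos(head.begin(), head.end() - 1);
    for (int a = 0; a < n_arcs; ++a) {
      int p = pos[arc_from[a]]++;
      adj_to[p] = arc_to[a];
      adj_edge[p] = arc_edge[a];
    }
  }

  std::vector<int> out_nodes, out_edges, out_len;
  std::vector<char> visited(n_nodes, 0);
  std::vector<int> pnodes(max_len + 1), pedges(max_len);
  double n_paths = 0.0, steps = 0.0;

  // iterative DFS: frame = (node, next adjacency cursor)
  std::vector<int> st_node(max_len + 2), st_cursor(max_len + 2);

  for (int si = 0; si < sources.size(); ++si) {
    int s = sources[si];
    int depth = 0;
    st_node[0] = s;
    st_cursor[0] = head[s];
    visited[s] = 1;
    pnodes[0] = s;
    while (depth >= 0) {
      int v = st_node[depth];
      bool descended = false;
      while (st_cursor[depth] < head[v + 1]) {
        int cur = st_cursor[depth]++;
        int w = adj_to[cur];
        if (visited[w]) continue;
        if (++steps > max_steps)
          stop("path enumeration exceeded the step budget");
        pnodes[depth + 1] = w;
        pedges[depth] = adj_edge[cur];
        if (is_target[w]) {
          if (++n_paths > max_paths)
            stop("path enumeration exceeded the path budget");
          int len = depth + 1;
          out_len.push_back(len);
          for (int i = 0; i <= len; ++i) out_nodes.push_back(pnodes[i]);
          for (int i = 0; i < len; ++i) out_edges.push_back(pedges[i]);
        }
        if (depth + 1 < max_len) {
          visited[w] = 1;
          ++depth;
          st_node[depth] = w;
          st_cursor[depth] = head[w];
          descended = true;
          break;
        }
      }
      if (!descended && st_cursor[depth] >= head[v + 1]) {
        visited[v] = 0;
        --depth;
      }
    }
  }

  return List::create(_["nodes"] = wrap(out_nodes),
                      _["edges"] = wrap(out_edges),
                      _["len"] = wrap(out_len));
}

// Greedy parsimonious path selection over pooled candidates: repeatedly
// add the path maximizing (newly connected endpoint seeds) / (cost of its
// not-yet-selected edges) until no path connects a new seed.  Candidates
// whose endpoints are not both active are ignored (stability resampling).
// Indices are 0-based; paths must arrive in canonical tie-break order
// (cost, length, lexicographic node sequence) so that the first maximum
// is the deterministic choice.
// [[Rcpp::export]]
List greedy_select_cpp(IntegerVector path_first,
                       IntegerVector path_last,
                       IntegerVector edge_flat,
                       IntegerVector path_len,
                       NumericVector edge_costs,
                       LogicalVector active_node,
                       int n_nodes) {
  const int n_paths = path_len.size();
  const int n_edges = edge_costs.size();
  std::vector<int> off(n_paths + 1, 0);
  for (int p = 0; p < n_paths; ++p) off[p + 1] = off[p] + path_len[p];

  // edge -> paths index (CSR)
  std::vector<int> ehead(n_edges + 1, 0);
  for (int i = 0; i < edge_flat.size(); ++i) ehead[edge_flat[i] + 1]++;
  for (int e = 0; e < n_edges; ++e) ehead[e + 1] += ehead[e];
  std::vector<int> epath(edge_flat.size());
  {
    std::vector<int> pos(ehead.begin(), ehead.end() - 1);
    for (int p = 0; p < n_paths; ++p)
      for (int i = off[p]; i < off[p + 1]; ++i)
        epath[pos[edge_flat[i]]++] = p;
  }

  std::vector<double> marg(n_paths, 0.0);
  std::vector<char> valid(n_paths, 0);
  for (int p = 0; p < n_paths; ++p) {
    valid[p] = active_node[path_first[p]] && active_node[path_last[p]];
    for (int i = off[p]; i < off[p + 1]; ++i)
      marg[p] += edge_costs[edge_flat[i]];
  }

  std::vector<char> connected(n_nodes, 0), selected(n_edges, 0);
  std::vector<int> sel_paths;
  for (;;) {
    int best = -1;
    double best_ratio = 0.0;
    for (int p = 0; p < n_paths; ++p) {
      if (!valid[p]) continue;
      int delta = (connected[path_first[p]] ? 0 : 1) +
                  (connected[path_last[p]] ? 0 : 1);
      if (delta == 0) continue;
      double m = marg[p] > 1e-12 ? marg[p] : 1e-12;
      double ratio = delta / m;
      if (ratio > best_ratio) {
        best_ratio = ratio;
        best = p;
      }
    }
    if (best < 0) break;
    sel_paths.push_back(best + 1);
    for (int i = off[best]; i < off[best + 1]; ++i) {
      int e = edge_flat[i];
      if (!selected[e]) {
        selected[e] = 1;
        for (int j = ehead[e]; j < ehead[e + 1]; ++j)
          marg[epath[j]] -= edge_costs[e];
      }
    }
    connected[path_first[best]] = 1;
    connected[path_last[best]] = 1;
  }

  std::vector<int> sel_edges, conn_nodes;
  double total_cost = 0.0;
  for (int e = 0; e < n_edges; ++e)
    if (selected[e]) {
      sel_edges.push_back(e + 1);
      total_cost += edge_costs[e];
    }
  int n_conn = 0;
  for (int v = 0; v < n_nodes; ++v)
    if (connected[v]) {
      conn_nodes.push_back(v + 1);
      if (active_node[v]) ++n_conn;
    }
  return List::create(_["edges"] = wrap(sel_edges),
                      _["connected"] = wrap(conn_nodes),
                      _["paths"] = wrap(sel_paths),
                      _["score"] = n_conn - total_cost);
}
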