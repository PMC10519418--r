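#include <Rcpp.h>
using namespace Rcpp;

// Which of the three pairings a quartet induces under the four-point
// condition on (unit-length) path distances: 1 = ab|cd, 2 = ac|bd,
// 3 = ad|bc, 0 = unresolved (tie).
static inline int pairing(int dab, int dcd, int dac, int dbd, int dad, int dbc) {
  int s1 = dab + dcd, s2 = dac + dbd, s3 = dad + dbc;
  if (s1 < s2 && s1 < s3) return 1;
  if (s2 < s1 && s2 < s3) return 2;
  if (s3 < s1 && s3 < s2) return 3;
  return 0;
}

// Total quartet agreement between a candidate topology and a set of gene
// trees. All matrices are indexed over one shared taxon universe; entry -1
// marks a taxon absent from that tree (whole row/column). A 4-subset
// contributes 1 when present and identically resolved in both trees.

// [[Rcpp::export]]
double quartet_score_cpp(IntegerMatrix Dc, List Dg) {
  const int n = Dc.nrow();
  const int G = Dg.size();
  std::vector<IntegerMatrix> gs;
  gs.reserve(G);
  for (int g = 0; g < G; ++g) gs.push_back(as<IntegerMatrix>(Dg[g]));

  // taxa present in the candidate
  std::vector<int> present;
  for (int i = 0; i < n; ++i)
    if (Dc(i, i) >= 0) present.push_back(i);
  const int p = (int)present.size();
  double total = 0.0;
  for (int a = 0; a < p; ++a)
    for (int b = a + 1; b < p; ++b)
      for (int c = b + 1; c < p; ++c)
        for (int d = c + 1; d < p; ++d) {
          int ia = present[a], ib = present[b], ic = present[c], id = present[d];
          int pc = pairing(Dc(ia, ib), Dc(ic, id), Dc(ia, ic), Dc(ib, id),
                           Dc(ia, id), Dc(ib, ic));
          if (pc == 0) continue;
          for (int g = 0; g < G; ++g) {
            const IntegerMatrix& D = gs[g];
            if (D(ia, ia) < 0 || D(ib, ib) < 0 || D(ic, ic) < 0 || D(id, id) < 0)
              continue;
            int pg = pairing(D(ia, ib), D(ic, id), D(ia, ic), D(ib, id),
                             D(ia, id), D(ib, ic));
            if (pg == pc) total += 1.0;
          }
        }
  return total;
}

// Unit-length path distances between the leaves (nodes 1..n_leaves) of a
// tree given as an undirected edge list over nodes 1..n_nodes.

// [[Rcpp::export]]
IntegerMatrix topo_dist_cpp(IntegerMatrix edges, int n_nodes, int n_leaves) {
  std::vector<std::vector<int>> adj(n_nodes);
  for (int e = 0; e < edges.nrow(); ++e) {
    int u = edges(e, 0) - 1, v = edges(e, 1) - 1;
    adj[u].push_back(v);
    adj[v].push_back(u);
  }
  IntegerMatrix D(n_leaves, n_leaves);
  std::vector<int> dist(n_nodes);
  std::vector<int> queue(n_nodes);
  for (int s = 0; s < n_leaves; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    int head = 0, tail = 0;
    dist[s] = 0;
    queue[tail++] = s;
    while (head < tail) {
      int u = queue[head++];
      for (int v : adj[u])
        if (dist[v] < 0) {
          dist[v] = dist[u] + 1;
          queue[tail++] = v;
        }
    }
    for (int t = 0; t < n_leaves; ++t) D(s, t) = dist[t];
  }
  return D;
}
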