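#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

// Exact combinatorial planarity testing by Demoucron-Malgrange-Pertuiset
// (DMP) edge embedding, applied per biconnected component. O(V*E) per
// component, which is ample for planar-filtered network construction where
// the embedded graph never exceeds 3V-6 edges.

namespace {

typedef std::pair<int, int> Edge;

inline long long ekey(int a, int b, int n) {
  if (a > b) std::swap(a, b);
  return (long long)a * n + b;
}

// Tarjan biconnected components (iterative). Fills comps with edge lists.
void biconnected_components(int n, const std::vector<Edge>& edges,
                            std::vector<std::vector<Edge> >& comps) {
  int m = (int)edges.size();
  std::vector<std::vector<std::pair<int, int> > > adj(n); // (neighbor, edge id)
  for (int e = 0; e < m; ++e) {
    adj[edges[e].first].push_back(std::make_pair(edges[e].second, e));
    adj[edges[e].second].push_back(std::make_pair(edges[e].first, e));
  }
  std::vector<int> disc(n, -1), low(n, 0), it(n, 0), parent_edge(n, -1);
  std::vector<int> stack_v, estack;
  int timer = 0;
  for (int s = 0; s < n; ++s) {
    if (disc[s] != -1 || adj[s].empty()) continue;
    stack_v.push_back(s);
    disc[s] = low[s] = timer++;
    while (!stack_v.empty()) {
      int u = stack_v.back();
      if (it[u] < (int)adj[u].size()) {
        int v = adj[u][it[u]].first;
        int eid = adj[u][it[u]].second;
        ++it[u];
        if (eid == parent_edge[u]) continue;
        if (disc[v] == -1) {
          estack.push_back(eid);
          parent_edge[v] = eid;
          disc[v] = low[v] = timer++;
          stack_v.push_back(v);
        } else if (disc[v] < disc[u]) { // back edge, pushed once
          estack.push_back(eid);
          if (disc[v] < low[u]) low[u] = disc[v];
        }
      } else {
        stack_v.pop_back();
        if (!stack_v.empty()) {
          int p = stack_v.back();
          if (low[u] < low[p]) low[p] = low[u];
          if (low[u] >= disc[p]) {
            comps.push_back(std::vector<Edge>());
            std::vector<Edge>& comp = comps.back();
            while (true) {
              int eid = estack.back();
              estack.pop_back();
              comp.push_back(edges[eid]);
              if (eid == parent_edge[u]) break;
            }
          }
        }
      }
    }
  }
}

// DMP planarity for one biconnected, simple component.
bool dmp_planar(const std::vector<Edge>& comp_edges) {
  // relabel vertices 0..k-1
  std::vector<int> verts;
  for (size_t i = 0; i < comp_edges.size(); ++i) {
    verts.push_back(comp_edges[i].first);
    verts.push_back(comp_edges[i].second);
  }
  std::sort(verts.begin(), verts.end());
  verts.erase(std::unique(verts.begin(), verts.end()), verts.end());
  int k = (int)verts.size();
  int m = (int)comp_edges.size();
  if (k <= 4) return true;           // every graph on <= 4 vertices is planar
  if (m > 3 * k - 6) return false;   // Euler bound

  std::vector<Edge> E(m);
  for (int e = 0; e < m; ++e) {
    int a = (int)(std::lower_bound(verts.begin(), verts.end(),
                                   comp_edges[e].first) - verts.begin());
    int b = (int)(std::lower_bound(verts.begin(), verts.end(),
                                   comp_edges[e].second) - verts.begin());
    E[e] = std::make_pair(a, b);
  }
  std::vector<std::vector<int> > adj(k);
  for (int e = 0; e < m; ++e) {
    adj[E[e].first].push_back(E[e].second);
    adj[E[e].second].push_back(E[e].first);
  }

  // find an initial cycle by DFS
  std::vector<int> par(k, -1), state(k, 0), order;
  std::vector<int> cyc;
  {
    std::vector<int> st;
    st.push_back(0);
    state[0] = 1;
    bool found = false;
    while (!st.empty() && !found) {
      int u = st.back();
      bool descended = false;
      for (size_t i = 0; i < adj[u].size(); ++i) {
        int v = adj[u][i];
        if (v == par[u]) continue;
        if (state[v] == 1) { // back edge into the stack -> cycle
          int w = u;
          cyc.push_back(v);
          while (w != v) { cyc.push_back(w); w = par[w]; }
          found = true;
          break;
        }
        if (state[v] == 0) {
          state[v] = 1;
          par[v] = u;
          st.push_back(v);
          descended = true;
          break;
        }
      }
      if (found) break;
      if (!descended) { state[u] = 2; st.pop_back(); }
    }
    if (!found) return true; // acyclic (cannot happen in biconnected k>=3)
  }

  std::vector<char> inH(k, 0);
  std::unordered_set<long long> emb; // embedded edges
  std::vector<std::vector<int> > faces;
  for (size_t i = 0; i < cyc.size(); ++i) {
    inH[cyc[i]] = 1;
    int a = cyc[i], b = cyc[(i + 1) % cyc.size()];
    emb.insert(ekey(a, b, k));
  }
  faces.push_back(cyc);
  faces.push_back(cyc);

  int n_embedded = (int)cyc.size();

  // fragment record: contacts + an embeddable path (contact..interior..contact)
  struct Fragment {
    std::vector<int> contacts;
    std::vector<int> path;
  };

  while (n_embedded < m) {
    std::vector<Fragment> frags;

    // chord fragments: non-embedded edges with both endpoints in H
    for (int e = 0; e < m; ++e) {
      int a = E[e].first, b = E[e].second;
      if (inH[a] && inH[b] && !emb.count(ekey(a, b, k))) {
        Fragment f;
        f.contacts.push_back(std::min(a, b));
        f.contacts.push_back(std::max(a, b));
        f.path.push_back(a);
        f.path.push_back(b);
        frags.push_back(f);
      }
    }
    // component fragments: connected components of G - V(H)
    std::vector<int> fid(k, -1);
    for (int s = 0; s < k; ++s) {
      if (inH[s] || fid[s] != -1) continue;
      int id = (int)frags.size();
      Fragment f;
      std::vector<int> members;
      std::vector<int> q;
      q.push_back(s);
      fid[s] = id;
      std::unordered_set<int> contacts;
      while (!q.empty()) {
        int u = q.back();
        q.pop_back();
        members.push_back(u);
        for (size_t i = 0; i < adj[u].size(); ++i) {
          int v = adj[u][i];
          if (inH[v]) contacts.insert(v);
          else if (fid[v] == -1) { fid[v] = id; q.push_back(v); }
        }
      }
      f.contacts.assign(contacts.begin(), contacts.end());
      std::sort(f.contacts.begin(), f.contacts.end());
      // path: from contact a through the fragment to a different contact b
      int a = f.contacts[0];
      // BFS from all fragment-neighbors of a
      std::vector<int> pre(k, -2);
      std::vector<int> bq;
      for (size_t i = 0; i < members.size(); ++i) pre[members[i]] = -2;
      int endv = -1, endc = -1;
      for (size_t i = 0; i < adj[a].size(); ++i) {
        int v = adj[a][i];
        if (!inH[v] && fid[v] == id && pre[v] == -2) { pre[v] = -1; bq.push_back(v); }
      }
      for (size_t qi = 0; qi < bq.size() && endv == -1; ++qi) {
        int u = bq[qi];
        for (size_t i = 0; i < adj[u].size(); ++i) {
          int v = adj[u][i];
          if (inH[v]) {
            if (v != a) { endv = u; endc = v; break; }
          } else if (pre[v] == -2) {
            pre[v] = u;
            bq.push_back(v);
          }
        }
      }
      // biconnected => a second contact is always reachable
      std::vector<int> rev;
      int w = endv;
      while (w != -1) { rev.push_back(w); w = pre[w]; }
      f.path.push_back(a);
      for (int i = (int)rev.size() - 1; i >= 0; --i) f.path.push_back(rev[i]);
      f.path.push_back(endc);
      frags.push_back(f);
    }

    if (frags.empty()) return true;

    // admissible faces per fragment; pick the fragment with the fewest
    int best = -1, best_cnt = -1, best_face = -1;
    for (size_t fi = 0; fi < frags.size(); ++fi) {
      int cnt = 0, first_face = -1;
      for (size_t ff = 0; ff < faces.size(); ++ff) {
        const std::vector<int>& bd = faces[ff];
        bool all = true;
        for (size_t ci = 0; ci < frags[fi].contacts.size(); ++ci) {
          if (std::find(bd.begin(), bd.end(), frags[fi].contacts[ci]) == bd.end()) {
            all = false;
            break;
          }
        }
        if (all) { ++cnt; if (first_face == -1) first_face = (int)ff; }
      }
      if (cnt == 0) return false;
      if (best == -1 || cnt < best_cnt) { best = (int)fi; best_cnt = cnt; best_face = first_face; }
      if (best_cnt == 1) break; // forced move
    }

    // embed frags[best].path into faces[best_face]
    const std::vector<int>& path = frags[best].path;
    std::vector<int> bd = faces[best_face];
    int a = path.front(), b = path.back();
    int ia = -1, ib = -1;
    for (size_t i = 0; i < bd.size(); ++i) {
      if (bd[i] == a) ia = (int)i;
      if (bd[i] == b) ib = (int)i;
    }
    int L = (int)bd.size();
    // face1: a..b along bd, then path interior reversed b->a
    std::vector<int> f1, f2;
    for (int i = ia; ; i = (i + 1) % L) { f1.push_back(bd[i]); if (i == ib) break; }
    for (int i = (int)path.size() - 2; i >= 1; --i) f1.push_back(path[i]);
    // face2: b..a along bd (the rest), then path interior a->b
    for (int i = ib; ; i = (i + 1) % L) { f2.push_back(bd[i]); if (i == ia) break; }
    for (int i = 1; i <= (int)path.size() - 2; ++i) f2.push_back(path[i]);
    faces[best_face] = f1;
    faces.push_back(f2);

    for (size_t i = 0; i + 1 < path.size(); ++i) {
      emb.insert(ekey(path[i], path[i + 1], k));
      ++n_embedded;
    }
    for (size_t i = 1; i + 1 < path.size(); ++i) inH[path[i]] = 1;
  }
  return true;
}

bool graph_is_planar(int n, const std::vector<Edge>& edges) {
  if ((int)edges.size() <= 8) return true; // K5 has 10 edges, K3,3 has 9
  std::vector<std::vector<Edge> > comps;
  biconnected_components(n, edges, comps);
  for (size_t i = 0; i < comps.size(); ++i) {
    if (!dmp_planar(comps[i])) return false;
  }
  return true;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".is_planar_cpp")]]
bool is_planar_cpp(IntegerMatrix edges, int n_nodes) {
  std::vector<Edge> E;
  E.reserve(edges.nrow());
  for (int i = 0; i < edges.nrow(); ++i) {
    int a = edges(i, 0) - 1, b = edges(i, 1) - 1;
    if (a == b) continue;
    E.push_back(std::make_pair(a, b));
  }
  return graph_is_planar(n_nodes, E);
}

// Greedy PMFG selection: edges come ranked strongest-first; keep an edge iff
// the accepted graph stays planar; stop once 3n-6 edges are accepted.
//' @noRd
// [[Rcpp::export(name = ".pmfg_select_cpp")]]
LogicalVector pmfg_select_cpp(IntegerMatrix edges, int n_nodes) {
  int m = edges.nrow();
  LogicalVector keep(m);
  std::vector<Edge> acc;
  int cap = n_nodes >= 3 ? 3 * n_nodes - 6 : n_nodes - 1;
  for (int i = 0; i < m; ++i) {
    if ((int)acc.size() >= cap) break;
    int a = edges(i, 0) - 1, b = edges(i, 1) - 1;
    if (a == b) continue;
    acc.push_back(std::make_pair(a, b));
    if (graph_is_planar(n_nodes, acc)) {
      keep[i] = true;
    } else {
      acc.pop_back();
    }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return keep;
}
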