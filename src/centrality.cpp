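#include <Rcpp.h>
#include <deque>
#include <vector>
using namespace Rcpp;

typedef std::vector<std::vector<int> > AdjList;

// Brandes (2001) accumulation for unweighted undirected graphs.
// bc[v] = sum over unordered pairs {s,t}, s!=v!=t, of sigma_st(v)/sigma_st.
static void brandes_core(const AdjList& nbr, std::vector<double>& bc) {
  const int n = (int)nbr.size();
  std::fill(bc.begin(), bc.end(), 0.0);
  std::vector<int> stack;
  stack.reserve(n);
  std::vector<std::vector<int> > pred(n);
  std::vector<double> sigma(n), delta(n);
  std::vector<int> dist(n);
  std::deque<int> q;

  for (int s = 0; s < n; ++s) {
    stack.clear();
    for (int i = 0; i < n; ++i) {
      pred[i].clear();
      sigma[i] = 0.0;
      dist[i] = -1;
    }
    sigma[s] = 1.0;
    dist[s] = 0;
    q.clear();
    q.push_back(s);
    while (!q.empty()) {
      int v = q.front();
      q.pop_front();
      stack.push_back(v);
      for (size_t j = 0; j < nbr[v].size(); ++j) {
        int w = nbr[v][j];
        if (dist[w] < 0) {
          dist[w] = dist[v] + 1;
          q.push_back(w);
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] += sigma[v];
          pred[w].push_back(v);
        }
      }
    }
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int i = (int)stack.size() - 1; i >= 0; --i) {
      int w = stack[i];
      for (size_t j = 0; j < pred[w].size(); ++j) {
        int v = pred[w][j];
        delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
      }
      if (w != s) bc[w] += delta[w];
    }
  }
  // each unordered pair was counted from both endpoints
  for (int i = 0; i < n; ++i) bc[i] /= 2.0;
}

static void bfs_dist(const AdjList& nbr, int s, std::vector<int>& dist) {
  std::fill(dist.begin(), dist.end(), -1);
  dist[s] = 0;
  std::deque<int> q;
  q.push_back(s);
  while (!q.empty()) {
    int v = q.front();
    q.pop_front();
    for (size_t j = 0; j < nbr[v].size(); ++j) {
      int w = nbr[v][j];
      if (dist[w] < 0) {
        dist[w] = dist[v] + 1;
        q.push_back(w);
      }
    }
  }
}

// Depth-first enumeration of every geodesic from u to t, pruned by BFS
// distance-to-t; each completed path bumps its interior vertices once.
static void dfs_enum(const AdjList& nbr, const std::vector<int>& dist_t, int u,
                     int t, std::vector<int>& path, long long& total,
                     std::vector<long long>& through) {
  if (u == t) {
    ++total;
    for (size_t i = 1; i + 1 < path.size(); ++i) ++through[path[i]];
    return;
  }
  for (size_t j = 0; j < nbr[u].size(); ++j) {
    int w = nbr[u][j];
    if (dist_t[w] == dist_t[u] - 1) {
      path.push_back(w);
      dfs_enum(nbr, dist_t, w, t, path, total, through);
      path.pop_back();
    }
  }
}

// Reference betweenness by explicit enumeration of all shortest paths.
static void enum_core(const AdjList& nbr, std::vector<double>& bc) {
  const int n = (int)nbr.size();
  std::fill(bc.begin(), bc.end(), 0.0);
  std::vector<int> dist(n);
  std::vector<long long> through(n);
  std::vector<int> path;
  for (int t = 1; t < n; ++t) {
    bfs_dist(nbr, t, dist);
    for (int s = 0; s < t; ++s) {
      if (dist[s] < 0) continue;  // unreachable pairs contribute nothing
      long long total = 0;
      std::fill(through.begin(), through.end(), 0);
      path.clear();
      path.push_back(s);
      dfs_enum(nbr, dist, s, t, path, total, through);
      for (int v = 0; v < n; ++v)
        if (through[v]) bc[v] += (double)through[v] / (double)total;
    }
  }
}

static AdjList adj_to_list(const IntegerMatrix& adj) {
  const int n = adj.nrow();
  AdjList nbr(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && adj(i, j) != 0) nbr[i].push_back(j);
  return nbr;
}

//' @name bc_brandes
//' @title Betweenness centrality via Brandes' algorithm (internal)
//' @param adj square symmetric binary adjacency matrix (integer)
//' @return numeric vector of raw betweenness values
//' @keywords internal
// [[Rcpp::export]]
NumericVector bc_brandes(IntegerMatrix adj) {
  AdjList nbr = adj_to_list(adj);
  std::vector<double> bc(adj.nrow());
  brandes_core(nbr, bc);
  return wrap(bc);
}

//' @name bc_enumerate
//' @title Betweenness centrality by exhaustive geodesic enumeration (internal)
//' @description Independent reference implementation used for validation:
//'   lists every shortest path between every reachable pair explicitly and
//'   counts pass-throughs. Exponentially slower than Brandes on dense graphs;
//'   only suitable for small or sparse graphs.
//' @param adj square symmetric binary adjacency matrix (integer)
//' @return numeric vector of raw betweenness values
//' @keywords internal
// [[Rcpp::export]]
NumericVector bc_enumerate(IntegerMatrix adj) {
  AdjList nbr = adj_to_list(adj);
  std::vector<double> bc(adj.nrow());
  enum_core(nbr, bc);
  return wrap(bc);
}

//' @name bc_agreement_sweep
//' @title Compare Brandes and enumeration betweenness over all graphs (internal)
//' @description Enumerates every labelled undirected graph on `n` nodes
//'   (all 2^(n(n-1)/2) edge subsets, connected and disconnected alike),
//'   computes betweenness by both routes and tracks the largest absolute
//'   disagreement.
//' @param n number of nodes (capped at 7; the sweep is exponential in n^2)
//' @return list with max_abs_err, n_graphs, n_connected
//' @keywords internal
// [[Rcpp::export]]
List bc_agreement_sweep(int n) {
  if (n < 2 || n > 7) stop("n must be between 2 and 7");
  const int m = n * (n - 1) / 2;
  std::vector<int> pi(m), pj(m);
  int e = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      pi[e] = i;
      pj[e] = j;
      ++e;
    }
  AdjList nbr(n);
  std::vector<double> bc1(n), bc2(n);
  std::vector<int> dist(n);
  double max_err = 0.0;
  long long n_conn = 0;
  const long long total = 1LL << m;
  for (long long mask = 0; mask < total; ++mask) {
    if ((mask & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    for (int i = 0; i < n; ++i) nbr[i].clear();
    for (int k = 0; k < m; ++k)
      if (mask & (1LL << k)) {
        nbr[pi[k]].push_back(pj[k]);
        nbr[pj[k]].push_back(pi[k]);
      }
    bfs_dist(nbr, 0, dist);
    bool conn = true;
    for (int i = 0; i < n; ++i)
      if (dist[i] < 0) {
        conn = false;
        break;
      }
    if (conn) ++n_conn;
    brandes_core(nbr, bc1);
    enum_core(nbr, bc2);
    for (int i = 0; i < n; ++i) {
      double d = std::abs(bc1[i] - bc2[i]);
      if (d > max_err) max_err = d;
    }
  }
  return List::create(Named("max_abs_err") = max_err,
                      Named("n_graphs") = (double)total,
                      Named("n_connected") = (double)n_conn);
}
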