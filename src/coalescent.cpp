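#include <Rcpp.h>
using namespace Rcpp;

// One Kingman coalescent tree for n lineages under piecewise-constant
// demography (epoch start times in units of 2N generations, relative sizes
// nu), with infinite-sites mutations dropped on the branches at rate
// theta/2 per unit branch length. Uses R's RNG so results are reproducible
// under set.seed(). Returns the 0/1 derived-allele matrix (n x S) and
// relative positions in (0,1).
// [[Rcpp::export]]
List coalescent_block_cpp(int n, NumericVector epoch_start,
                          NumericVector epoch_nu, double theta) {
  const int n_nodes = 2 * n - 1;
  const int n_ep = epoch_start.size();
  std::vector<int> parent(n_nodes, -1);
  std::vector<int> child1(n_nodes, -1), child2(n_nodes, -1);
  std::vector<double> node_time(n_nodes, 0.0);
  std::vector<int> act(n);
  for (int i = 0; i < n; ++i) act[i] = i;

  double t_cur = 0.0;
  int nxt = n;
  for (int k = n; k >= 2; --k) {
    const double rate = k * (k - 1.0) / 2.0;
    double E = R::exp_rand();
    for (;;) {
      int ep = n_ep - 1;
      for (int e = 0; e < n_ep - 1; ++e) {
        if (t_cur < epoch_start[e + 1]) { ep = e; break; }
      }
      const double nu = epoch_nu[ep];
      const double dt = E * nu / rate;
      if (ep == n_ep - 1 || t_cur + dt <= epoch_start[ep + 1]) {
        t_cur += dt;
        break;
      }
      E -= (epoch_start[ep + 1] - t_cur) * rate / nu;
      t_cur = epoch_start[ep + 1];
    }
    int i = (int)(R::unif_rand() * k);
    if (i >= k) i = k - 1;
    int j = (int)(R::unif_rand() * (k - 1));
    if (j >= k - 1) j = k - 2;
    if (j >= i) ++j;
    const int ci = act[i], cj = act[j];
    parent[ci] = nxt;
    parent[cj] = nxt;
    child1[nxt] = ci;
    child2[nxt] = cj;
    node_time[nxt] = t_cur;
    act[std::min(i, j)] = nxt;
    act[std::max(i, j)] = act[k - 1];
    ++nxt;
  }

  std::vector<double> cum_len(n_nodes, 0.0);
  double total = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    if (parent[v] >= 0) total += node_time[parent[v]] - node_time[v];
    cum_len[v] = total;
  }
  const int S = (int)R::rpois(theta / 2.0 * total);
  IntegerMatrix H(n, S);
  NumericVector pos(S);
  std::vector<int> stack;
  for (int s = 0; s < S; ++s) {
    const double u = R::unif_rand() * total;
    int br = (int)(std::lower_bound(cum_len.begin(), cum_len.end(), u) -
                   cum_len.begin());
    if (br >= n_nodes) br = n_nodes - 1;
    // mark all leaves below branch br
    stack.clear();
    stack.push_back(br);
    while (!stack.empty()) {
      const int v = stack.back();
      stack.pop_back();
      if (v < n) {
        H(v, s) = 1;
      } else {
        stack.push_back(child1[v]);
        stack.push_back(child2[v]);
      }
    }
    pos[s] = R::unif_rand();
  }
  return List::create(_["haplotypes"] = H, _["rel_pos"] = pos);
}
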