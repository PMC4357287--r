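#include <Rcpp.h>
using namespace Rcpp;

// Brownian-motion log-likelihood with the root profiled out (GLS), by
// Gaussian elimination on the tree. Edges must be in postorder; `edge` is
// the two-column (parent, child) matrix with 1-based node indices, tips
// 1..n, root n+1. `scaled_len` holds the per-edge variance contributions
// (rate x length). `x` is ordered by tip index.
// [[Rcpp::export]]
List cpp_bm_profile_lnL(IntegerMatrix edge, int n, int nnode,
                        NumericVector scaled_len, NumericVector x) {
  int ntot = n + nnode;
  std::vector<double> m(ntot), v(ntot, 0.0);
  std::vector<bool> has(ntot, false);
  for (int i = 0; i < n; ++i) { m[i] = x[i]; }
  double ll = 0.0;
  int ne = edge.nrow();
  for (int e = 0; e < ne; ++e) {
    int par = edge(e, 0) - 1, chi = edge(e, 1) - 1;
    double mv = v[chi] + scaled_len[e];
    double mc = m[chi];
    if (!has[par]) { m[par] = mc; v[par] = mv; has[par] = true; }
    else {
      double tot = v[par] + mv;
      if (tot <= 0) {
        if (std::abs(m[par] - mc) > 1e-12)
          stop("singular covariance: zero-length path separates distinct values");
        continue;
      }
      double d = m[par] - mc;
      ll += -0.5 * (std::log(2.0 * M_PI * tot) + d * d / tot);
      m[par] = (m[par] * mv + mc * v[par]) / tot;
      v[par] = v[par] * mv / tot;
    }
  }
  int root = n; // 0-based index of node n+1
  if (v[root] <= 0) stop("singular covariance at root");
  ll += -0.5 * std::log(2.0 * M_PI * v[root]);
  return List::create(_["lnL"] = ll, _["root"] = m[root],
                      _["root_var"] = v[root]);
}

// One Gibbs sweep over the latent liabilities of a threshold character:
// full conditionals under precision Ci / v1r with mean vector mu, each
// truncated to the side given by the observed binary state. Updates `l`
// in place (the caller passes a dedicated copy) and uses R's RNG.
// [[Rcpp::export]]
NumericVector cpp_liability_sweep(NumericMatrix Ci, NumericVector mu,
                                  IntegerVector state, NumericVector l,
                                  double v1r) {
  int n = l.size();
  RNGScope scope;
  std::vector<double> dev(n);
  for (int i = 0; i < n; ++i) dev[i] = l[i] - mu[i];
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += Ci(i, j) * dev[j];
    double dii = Ci(i, i);
    double cm = mu[i] - (s - dii * dev[i]) / dii;
    double sd = std::sqrt(v1r / dii);
    double u = R::runif(0.0, 1.0);
    double p0 = R::pnorm(0.0, cm, sd, 1, 0);
    double nl;
    if (state[i] == 1) nl = R::qnorm(p0 + u * (1.0 - p0), cm, sd, 1, 0);
    else nl = R::qnorm(u * p0, cm, sd, 1, 0);
    if (!R_finite(nl)) nl = (state[i] == 1) ? 1e-6 : -1e-6;
    l[i] = nl;
    dev[i] = nl - mu[i];
  }
  return l;
}
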