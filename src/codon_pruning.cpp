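// Felsenstein pruning for codon site-class models.  The rate matrix
// eigensystems are prepared in R (one per omega class); this kernel builds
// the per-edge transition matrices and accumulates conditional likelihoods
// over a postorder edge list, with per-site rescaling to avoid underflow.

#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// tips: N x S integer matrix of 0-based state indices (-1 = gap/missing)
// edge: E x 2 (1-based ape node ids), in postorder
// Returns per class a vector of per-site log-likelihoods (including the
// stationary distribution at the root).
// [[Rcpp::export(name = ".codon_class_loglik_cpp")]]
Rcpp::List codon_class_loglik_cpp(const Rcpp::IntegerMatrix tips,
                                  const Rcpp::IntegerMatrix edge,
                                  const Rcpp::NumericVector edge_len,
                                  const Rcpp::List eigenlist,
                                  const Rcpp::NumericVector pi,
                                  const int n_node) {
  const int n_tip = tips.nrow();
  const int S = tips.ncol();
  const int E = edge.nrow();
  const int n_class = eigenlist.size();
  const vec piv = Rcpp::as<vec>(pi);
  const int K = piv.n_elem;

  Rcpp::List out(n_class);
  for (int c = 0; c < n_class; ++c) {
    Rcpp::List es = eigenlist[c];
    const mat U = Rcpp::as<mat>(es["U"]);
    const mat Uinv = Rcpp::as<mat>(es["Uinv"]);
    const vec lambda = Rcpp::as<vec>(es["lambda"]);

    // conditional likelihoods per node (lazily initialised), plus log-scale
    std::vector<mat> L(n_tip + n_node);
    std::vector<bool> seen(n_tip + n_node, false);
    rowvec logscale(S, fill::zeros);

    // transition matrices cached per unique branch length
    std::map<double, mat> Pcache;
    for (int e = 0; e < E; ++e) {
      const int parent = edge(e, 0) - 1;
      const int child = edge(e, 1) - 1;
      const double t = edge_len[e];
      auto it = Pcache.find(t);
      if (it == Pcache.end())
        it = Pcache.emplace(t, U * diagmat(exp(lambda * t)) * Uinv).first;
      const mat& P = it->second;

      mat Lc;
      if (child < n_tip) {
        Lc.zeros(K, S);
        for (int s = 0; s < S; ++s) {
          const int st = tips(child, s);
          if (st < 0) Lc.col(s).ones();
          else Lc(st, s) = 1.0;
        }
      } else {
        Lc = L[child];
        L[child].reset();
      }
      mat V = P * Lc;  // K x S
      // guard tiny negatives from round-off
      V.transform([](double x) { return x < 0 ? 0.0 : x; });
      if (!seen[parent]) {
        L[parent] = V;
        seen[parent] = true;
      } else {
        L[parent] %= V;
        // rescale per site when combining (only once per completed node)
        for (int s = 0; s < S; ++s) {
          double m = L[parent].col(s).max();
          if (m > 0 && m < 1e-150) {
            L[parent].col(s) /= m;
            logscale[s] += std::log(m);
          }
        }
      }
    }
    const int root = edge(E - 1, 0) - 1;
    rowvec rootlik = piv.t() * L[root];
    rowvec ll(S);
    for (int s = 0; s < S; ++s)
      ll[s] = (rootlik[s] > 0 ? std::log(rootlik[s]) : -1e300) + logscale[s];
    out[c] = Rcpp::NumericVector(ll.begin(), ll.end());
  }
  return out;
}
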