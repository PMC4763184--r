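#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Moment-matched (Liu-Tang-Zhang, modified) upper tail of Q = sum_k lambda_k chi2_1.
// Used as the fast inner approximation during backward elimination and as the
// fallback when the exact mixture tail fails to converge.
static double liu_tail_moments(double q, double c1, double c2, double c3,
                               double c4) {
  if (c2 <= 0.0) return (q > c1) ? 0.0 : 1.0;
  const double s1 = c3 / std::pow(c2, 1.5);
  const double s2 = c4 / (c2 * c2);
  double a, delta, l;
  if (s1 * s1 > s2) {
    a = 1.0 / (s1 - std::sqrt(s1 * s1 - s2));
    delta = s1 * a * a * a - a * a;
    l = a * a - 2.0 * delta;
  } else {
    a = 1.0 / std::sqrt(s2);
    delta = 0.0;
    l = 1.0 / s2;
  }
  if (l < 0.05) l = 0.05;  // guard pathological moment fits
  const double mux = l + delta;
  const double sx = std::sqrt(2.0) * a;
  const double t = (q - c1) / std::sqrt(2.0 * c2);
  const double x = t * sx + mux;
  if (x <= 0.0) return 1.0;
  return R::pnchisq(x, l, delta, 0, 0);
}

// [[Rcpp::export]]
double liu_tail_cpp(double q, const arma::vec &lambda) {
  return liu_tail_moments(q, arma::accu(lambda),
                          arma::accu(arma::square(lambda)),
                          arma::accu(arma::pow(lambda, 3)),
                          arma::accu(arma::pow(lambda, 4)));
}

// Inner region-test p-value on a variant subset, from precomputed per-variant
// scores U and their null covariance V. method: 0 = SKAT, 1 = BURDEN.
static double subset_pvalue(const arma::vec &U, const arma::mat &V,
                            const arma::uvec &idx, int method) {
  if (method == 1) {
    const double s = arma::accu(U(idx));
    const double v = arma::accu(V.submat(idx, idx));
    if (v <= 1e-300) return 1.0;
    return R::pchisq(s * s / v, 1.0, 0, 0);
  }
  // Liu tail from the spectral moments c_k = sum(lambda^k) = tr(V_sub^k),
  // computed from the submatrix directly (no eigendecomposition needed)
  const arma::mat Vs = V.submat(idx, idx);
  const double c1 = arma::trace(Vs);
  if (c1 <= 1e-300) return 1.0;
  const double c2 = arma::accu(arma::square(Vs));
  const arma::mat V2 = Vs * Vs;
  const double c3 = arma::accu(V2 % Vs);
  const double c4 = arma::accu(arma::square(V2));
  const double Q = arma::accu(arma::square(U(idx)));
  return liu_tail_moments(Q, c1, c2, c3, c4);
}

// [[Rcpp::export]]
double subset_pvalue_cpp(const arma::vec &U, const arma::mat &V,
                         const arma::uvec &idx1, int method) {
  return subset_pvalue(U, V, idx1 - 1, method);
}

static arma::uvec greedy_core(const arma::vec &U, const arma::mat &V,
                              arma::uvec idx, int method, double eps_improve) {
  double pcur = subset_pvalue(U, V, idx, method);
  while (idx.n_elem > 1) {
    int best = -1;
    double pbest = pcur;
    for (arma::uword k = 0; k < idx.n_elem; ++k) {
      arma::uvec sub = idx;
      sub.shed_row(k);
      const double p = subset_pvalue(U, V, sub, method);
      // strict improvement; ties keep the earliest (smallest-index) removal
      if (p < pbest - eps_improve && p < pbest) {
        pbest = p;
        best = (int)k;
      }
    }
    if (best < 0) break;
    idx.shed_row((arma::uword)best);
    pcur = pbest;
  }
  return idx;
}

// [[Rcpp::export]]
arma::uvec greedy_eliminate_cpp(const arma::vec &U, const arma::mat &V,
                                const arma::uvec &idx1, int method,
                                double eps_improve) {
  arma::uvec out = greedy_core(U, V, arma::sort(idx1 - 1), method, eps_improve);
  return out + 1;
}

// Return counts over B random subsamples. subsets: B x r matrix of 1-based
// variant indices (rows need not be sorted; sorted here for deterministic
// tie-breaking by variant index).
// [[Rcpp::export]]
IntegerVector be_counts_cpp(const arma::vec &U, const arma::mat &V,
                            const IntegerMatrix &subsets, int method,
                            double eps_improve) {
  const int B = subsets.nrow(), r = subsets.ncol();
  IntegerVector counts(U.n_elem);
  for (int b = 0; b < B; ++b) {
    arma::uvec idx(r);
    for (int j = 0; j < r; ++j) idx(j) = (arma::uword)(subsets(b, j) - 1);
    idx = arma::sort(idx);
    arma::uvec surv = greedy_core(U, V, idx, method, eps_improve);
    for (arma::uword j = 0; j < surv.n_elem; ++j) counts[surv(j)] += 1;
    if (b % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return counts;
}
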