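#include <Rcpp.h>
using namespace Rcpp;

// Per-individual EM for supervised admixture projection.
//
// G: n x M dosage matrix (0/1/2, NA = missing), P: K x M allele
// frequencies already clamped into [eps, 1 - eps]. Each row of G is an
// independent optimisation of the admixture log-likelihood over the
// simplex; the update is
//   q_k <- q_k / (2 M_obs) * sum_j [ g_j p_kj / f_j +
//                                    (2 - g_j)(1 - p_kj) / (1 - f_j) ]
// with f_j = sum_k q_k p_kj, iterated until the log-likelihood improves
// by less than tol. The binomial coefficient is omitted (constant in q).
// Each pass evaluates the current q's log-likelihood and accumulates its
// update in one sweep over the observed sites.
// [[Rcpp::export(name = ".em_fit_q_cpp")]]
List em_fit_q_cpp(NumericMatrix G, NumericMatrix P, double tol,
                  int max_iter, double eps) {
  const int n = G.nrow(), M = G.ncol(), K = P.nrow();
  NumericMatrix Q(n, K);
  NumericVector loglik(n);
  IntegerVector n_iter(n);
  LogicalVector converged(n);
  List traces(n);

  std::vector<double> ps;  // site-major copy of P at observed sites
  std::vector<int> gi;     // observed dosages
  std::vector<double> q(K), qn(K);

  for (int i = 0; i < n; ++i) {
    ps.clear();
    gi.clear();
    for (int j = 0; j < M; ++j) {
      const double g = G(i, j);
      if (NumericMatrix::is_na(g)) continue;
      gi.push_back((int) g);
      for (int k = 0; k < K; ++k) ps.push_back(P(k, j));
    }
    const int m = (int) gi.size();
    if (m == 0) stop("all genotypes missing for row %d", i + 1);

    std::fill(q.begin(), q.end(), 1.0 / K);
    std::vector<double> tr;
    tr.reserve(256);
    double ll_prev = 0.0;
    bool cv = false;
    int iters = 0;

    for (int it = 0;; ++it) {
      double ll = 0.0;
      std::fill(qn.begin(), qn.end(), 0.0);
      const double *pj = ps.data();
      for (int a = 0; a < m; ++a, pj += K) {
        double f = 0.0;
        for (int k = 0; k < K; ++k) f += q[k] * pj[k];
        if (f < eps) f = eps;
        else if (f > 1.0 - eps) f = 1.0 - eps;
        switch (gi[a]) {
        case 0: {
          ll += 2.0 * std::log1p(-f);
          const double c2 = 2.0 / (1.0 - f);
          for (int k = 0; k < K; ++k) qn[k] += (1.0 - pj[k]) * c2;
          break;
        }
        case 1: {
          ll += std::log(f) + std::log1p(-f);
          const double c1 = 1.0 / f, c2 = 1.0 / (1.0 - f);
          for (int k = 0; k < K; ++k) {
            qn[k] += pj[k] * c1 + (1.0 - pj[k]) * c2;
          }
          break;
        }
        default: {
          ll += 2.0 * std::log(f);
          const double c1 = 2.0 / f;
          for (int k = 0; k < K; ++k) qn[k] += pj[k] * c1;
        }
        }
      }
      tr.push_back(ll);
      if (it > 0 && std::fabs(ll - ll_prev) < tol) {
        cv = true;
        iters = it;
        break;
      }
      ll_prev = ll;
      if (it == max_iter) {
        iters = max_iter;
        break;
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        qn[k] *= q[k] / (2.0 * m);
        s += qn[k];
      }
      for (int k = 0; k < K; ++k) q[k] = qn[k] / s;
    }

    for (int k = 0; k < K; ++k) Q(i, k) = q[k];
    loglik[i] = tr.back();
    n_iter[i] = iters;
    converged[i] = cv;
    traces[i] = NumericVector(tr.begin(), tr.end());
  }
  return List::create(_["q"] = Q, _["loglik"] = loglik,
                      _["n_iter"] = n_iter, _["converged"] = converged,
                      _["traces"] = traces);
}
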