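#include <Rcpp.h>
using namespace Rcpp;

// Trial-level likelihood sums for continuous-confidence models.
//
// Each trial belongs to a group (recall: outcome 0/1; recognition: one of
// the four stimulus x response cells). The R side discretises the group's
// joint density of (predicted confidence t, selection event) onto nodes
// t_j with weights W_j, so that for an interior reported confidence r
//
//   L(r) = sum_j W_j * phi_sigma(r - t_j) + Mlow * phi_sigma(r - 0)
//                                         + Mhigh * phi_sigma(r - 1)
//
// where Mlow/Mhigh are probability masses lying below/above the node grid.
// Censored reports (exactly 0 or 1) have per-group masses L0/L1 computed
// upstream. Gradients with respect to each group's four natural parameters
// (a, b, c, d) use node-level ratio vectors: dW_j/dnat_m = W_j * R_j[m].
//
// Nodes within each group must be sorted by t; only nodes with
// |r - t| <= window contribute (the N(0, sigma^2) kernel is negligible
// beyond ~12 sigma).
// [[Rcpp::export]]
List cpp_cont_loglik(NumericVector conf, IntegerVector grp,
                     List t_nodes, List w_nodes, List ratio_mats,
                     NumericVector L0, NumericVector L1,
                     NumericMatrix G0, NumericMatrix G1,
                     NumericVector Mlow, NumericVector Mhigh,
                     NumericMatrix Glow, NumericMatrix Ghigh,
                     double sigma, bool want_grad) {
  const int n = conf.size();
  const int G = t_nodes.size();
  const double window = 12.0 * sigma;
  const double inv_s = 1.0 / sigma;
  const double norm_c = 1.0 / (sigma * std::sqrt(2.0 * M_PI));
  const double tiny = 1e-300;

  std::vector<NumericVector> tv(G), wv(G);
  std::vector<NumericMatrix> rv(G);
  for (int g = 0; g < G; ++g) {
    tv[g] = as<NumericVector>(t_nodes[g]);
    wv[g] = as<NumericVector>(w_nodes[g]);
    if (want_grad) rv[g] = as<NumericMatrix>(ratio_mats[g]);
  }

  double ll = 0.0;
  NumericVector grad(want_grad ? 4 * G : 0);

  for (int t = 0; t < n; ++t) {
    const int g = grp[t];
    const double r = conf[t];
    double L;
    double dL[4] = {0.0, 0.0, 0.0, 0.0};

    if (r <= 0.0) {
      L = L0[g];
      if (want_grad) for (int m = 0; m < 4; ++m) dL[m] = G0(m, g);
    } else if (r >= 1.0) {
      L = L1[g];
      if (want_grad) for (int m = 0; m < 4; ++m) dL[m] = G1(m, g);
    } else {
      const NumericVector& tj = tv[g];
      const NumericVector& wj = wv[g];
      const int K = tj.size();
      // window [r - window, r + window] by binary search
      int lo = std::lower_bound(tj.begin(), tj.end(), r - window) - tj.begin();
      int hi = std::upper_bound(tj.begin(), tj.end(), r + window) - tj.begin();
      L = 0.0;
      if (want_grad) {
        const NumericMatrix& R = rv[g];
        for (int j = lo; j < hi; ++j) {
          const double u = (r - tj[j]) * inv_s;
          const double k = norm_c * std::exp(-0.5 * u * u);
          const double wk = wj[j] * k;
          L += wk;
          dL[0] += wk * R(j, 0);
          dL[1] += wk * R(j, 1);
          dL[2] += wk * R(j, 2);
          dL[3] += wk * R(j, 3);
        }
      } else {
        for (int j = lo; j < hi; ++j) {
          const double u = (r - tj[j]) * inv_s;
          L += wj[j] * std::exp(-0.5 * u * u);
        }
        L *= norm_c;
      }
      if (Mlow[g] > 0.0) {
        const double k0 = norm_c * std::exp(-0.5 * (r * inv_s) * (r * inv_s));
        L += Mlow[g] * k0;
        if (want_grad) for (int m = 0; m < 4; ++m) dL[m] += Glow(m, g) * k0;
      }
      if (Mhigh[g] > 0.0) {
        const double u1 = (r - 1.0) * inv_s;
        const double k1 = norm_c * std::exp(-0.5 * u1 * u1);
        L += Mhigh[g] * k1;
        if (want_grad) for (int m = 0; m < 4; ++m) dL[m] += Ghigh(m, g) * k1;
      }
    }

    const double Ls = (L > tiny) ? L : tiny;
    ll += std::log(Ls);
    if (want_grad && L > tiny)
      for (int m = 0; m < 4; ++m) grad[4 * g + m] += dL[m] / Ls;
  }

  if (want_grad) return List::create(_["loglik"] = ll, _["grad"] = grad);
  return List::create(_["loglik"] = ll);
}
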