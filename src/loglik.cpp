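#include <Rcpp.h>
#include <cmath>
#include <vector>

// Trial-loop log-likelihood replay shared by all seven models. Model
// codes: 0 control, 1 cbl_c, 2 cbl_r, 3 cbl_cr, 4 cbl_c_r, 5 tbeta_cbl,
// 6 f_cbl. Items are 1-based indices. For tbeta_cbl the inverse
// temperature uses presentation counts inclusive of the current trial.

// [[Rcpp::export]]
double cbl_loglik_cpp(int model, Rcpp::NumericVector par,
                      Rcpp::IntegerVector left, Rcpp::IntegerVector right,
                      Rcpp::IntegerVector chosen, int n_items,
                      double prob_floor) {
  const int T = left.size();
  std::vector<double> V(n_items, model == 0 ? 0.0 : 0.5);
  std::vector<int> pres(n_items, 0), chos(n_items, 0);

  double a_c = 0, a_r = 0, beta = 0, cexp = 0, aF = 0;
  switch (model) {
  case 1: a_c = par[0]; beta = par[1]; break;
  case 2: a_r = par[0]; beta = par[1]; break;
  case 3: a_c = a_r = par[0]; beta = par[1]; break;
  case 4: a_c = par[0]; a_r = par[1]; beta = par[2]; break;
  case 5: a_c = a_r = par[0]; cexp = par[1]; break;
  case 6: a_c = a_r = par[0]; beta = par[1]; aF = par[2]; break;
  default: break;
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    const int L = left[t] - 1, R = right[t] - 1, C = chosen[t] - 1;
    const int O = (C == L) ? R : L;
    double p;
    if (model == 0) {
      const double vC = pres[C] > 0 ? (double)chos[C] / pres[C] : 0.0;
      const double vO = pres[O] > 0 ? (double)chos[O] / pres[O] : 0.0;
      p = (vC + 1.0) / (vC + vO + 2.0);
    } else {
      double b = beta;
      if (model == 5) {
        const double base = ((pres[L] + 1) + (pres[R] + 1)) / 2.0 * 0.1;
        b = std::pow(base, cexp);
      }
      p = 1.0 / (1.0 + std::exp(-b * (V[C] - V[O])));
    }
    ll += std::log(p > prob_floor ? p : prob_floor);

    ++pres[L]; ++pres[R]; ++chos[C];
    if (model == 0) {
      V[C] = (double)chos[C] / pres[C];
      V[O] = (double)chos[O] / pres[O];
    } else {
      V[C] += a_c * (1.0 - V[C]);
      V[O] += a_r * (0.0 - V[O]);
      if (model == 6) {
        for (int i = 0; i < n_items; ++i)
          if (i != L && i != R) V[i] *= (1.0 - aF);
      }
    }
  }
  return ll;
}
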