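#include <Rcpp.h>
using namespace Rcpp;

// log(w * exp(L) + (1 - w)), stable for large |L|.
static inline double log_wexp(double L, double w) {
  double m = L > 0 ? L : 0;
  return std::log(w * std::exp(L - m) + (1 - w) * std::exp(-m)) + m;
}

// Reliability-weighting sigmoid F(L, w) in log-odds space, w on the
// true scale [0.5, 1].
static inline double Fsig(double L, double w) {
  return log_wexp(L, w) - log_wexp(L, 1 - w);
}

// Mean squared error between observed logit confidences and an observer
// model's predictions, for use inside the multistart optimizer.
// theta holds the free parameters on the rescaled [0,1] scale:
// model 1 = WB (theta = w_p, w_s), 2 = CII, 3 = CINI (theta = w_p, w_s,
// a_p, a_s). Must agree with the R reference predict_confidence().
// [[Rcpp::export]]
double cf_mse_objective(NumericVector theta, NumericVector L_p,
                        NumericVector L_s, NumericVector L_c, int model) {
  const double w_p = 0.5 + 0.5 * theta[0];
  const double w_s = 0.5 + 0.5 * theta[1];
  const double a_p = (model > 1) ? 60.0 * theta[2] : 0.0;
  const double a_s = (model > 1) ? 60.0 * theta[3] : 0.0;
  const int n = L_p.size();
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double pred;
    if (model == 1) {
      pred = Fsig(L_p[i], w_p) + Fsig(L_s[i], w_s);
    } else if (model == 2) {
      double I = Fsig(a_p * L_p[i], w_p) + Fsig(a_s * L_s[i], w_s);
      pred = Fsig(L_p[i] + I, w_p) + Fsig(L_s[i] + I, w_s);
    } else {
      pred = Fsig(L_p[i] + Fsig(a_p * L_p[i], w_p), w_p) +
             Fsig(L_s[i] + Fsig(a_s * L_s[i], w_s), w_s);
    }
    double r = L_c[i] - pred;
    acc += r * r;
  }
  return acc / n;
}
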