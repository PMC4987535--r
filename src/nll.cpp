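#include <Rcpp.h>
using namespace Rcpp;

// Negative log-likelihood of a choice history under the hybrid
// model-free / model-based learner.
//
// Codings: a1 in {0 = A, 1 = B}; s2 in {0 = blue, 1 = purple};
// a2 in {0, 1}; commonA is the state index of symbol A's common state
// (symbol B's common state is the other one).
//
// par holds 8 values: alpha1, alpha2, beta1, beta2, lambda, p_stick, w, v.
// The 5-parameter model is obtained by passing alpha1 == alpha2 and
// beta1 == beta2; condition 1 ignores v (cue weight).
//
// Replays the history: per trial, stage-1 probabilities come from the
// hybrid values of the pre-trial state (softmax with stickiness bonus for
// repeating the previous first-stage choice); stage-2 probabilities are a
// plain softmax over the reached state's values. Updates (in order:
// stage-1 SARSA-lambda with pre-update q2, stage-2 delta rule, transition
// count increment) then advance the state.
// [[Rcpp::export]]
double nll_hybrid_cpp(NumericVector par,
                      IntegerVector a1, IntegerVector s2, IntegerVector a2,
                      IntegerVector r,
                      NumericVector cdA, NumericVector cdB,
                      int condition, int commonA) {
  const double alpha1 = par[0], alpha2 = par[1];
  const double beta1 = par[2], beta2 = par[3];
  const double lambda = par[4], p_stick = par[5];
  const double w = par[6], v = par[7];
  const int n = a1.size();

  double q2[2][2] = {{0.0, 0.0}, {0.0, 0.0}}; // [state][symbol]
  double q1mf[2] = {0.0, 0.0};
  double ntr[2][2] = {{0.0, 0.0}, {0.0, 0.0}}; // [symbol][state]
  int prev = -1;
  const int common[2] = {commonA, 1 - commonA};

  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    const double vmax[2] = {std::max(q2[0][0], q2[0][1]),
                            std::max(q2[1][0], q2[1][1])};
    double x[2];
    for (int a = 0; a < 2; ++a) {
      const double pblue = (ntr[a][0] + 1.0) / (ntr[a][0] + ntr[a][1] + 2.0);
      const double qmb = pblue * vmax[0] + (1.0 - pblue) * vmax[1];
      double qh;
      if (condition == 1) {
        qh = w * qmb + (1.0 - w) * q1mf[a];
      } else {
        const double cd = (a == 0) ? cdA[t] : cdB[t];
        const double dq = cd * (vmax[common[a]] - vmax[1 - common[a]]);
        qh = w * qmb + v * dq + (1.0 - w - v) * q1mf[a];
      }
      x[a] = beta1 * qh + ((a == prev) ? p_stick : 0.0);
    }
    const double m1 = std::max(x[0], x[1]);
    const double lse1 = m1 + std::log(std::exp(x[0] - m1) +
                                      std::exp(x[1] - m1));
    nll -= x[a1[t]] - lse1;

    const int s = s2[t];
    const double y0 = beta2 * q2[s][0], y1 = beta2 * q2[s][1];
    const double m2 = std::max(y0, y1);
    const double lse2 = m2 + std::log(std::exp(y0 - m2) + std::exp(y1 - m2));
    nll -= ((a2[t] == 0) ? y0 : y1) - lse2;

    // updates: stage-1 MF first (pre-update q2), then stage-2, then counts
    const double q2sa = q2[s][a2[t]];
    const int a = a1[t];
    q1mf[a] += alpha1 * (q2sa - q1mf[a]) +
               alpha1 * lambda * ((double)r[t] - q2sa);
    q2[s][a2[t]] += alpha2 * ((double)r[t] - q2sa);
    ntr[a][s] += 1.0;
    prev = a;
  }
  return nll;
}
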