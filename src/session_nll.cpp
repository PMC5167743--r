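#include <Rcpp.h>
using namespace Rcpp;

// Negative log-likelihood of one two-step session under the hybrid
// model-based/model-free learner.
//
// Coding: actions and second-stage states are 1-based on the R side and
// converted here; action j leads commonly to state j. Invalid trials
// contribute no likelihood and trigger no value update. The perseveration
// bonus applies at stage 1 only. Softmax terms use max-subtraction so that
// large beta * Q never overflows.
// [[Rcpp::export]]
double cpp_session_nll(IntegerVector a1, IntegerVector s2, IntegerVector a2,
                       IntegerVector r, LogicalVector valid,
                       double alpha1, double alpha2, double lam, double omega,
                       double beta1, double beta2, double rho,
                       double p_common) {
  const int n = a1.size();
  double q1[2] = {0.0, 0.0};
  double q2[2][2] = {{0.0, 0.0}, {0.0, 0.0}};
  int last_a1 = -1;
  double nll = 0.0;

  for (int t = 0; t < n; ++t) {
    if (!valid[t]) continue;
    const int c1 = a1[t] - 1, st = s2[t] - 1, c2 = a2[t] - 1;
    const double rew = (double) r[t];

    // model-based first-stage values: one-step planning over the two states
    const double m0 = std::max(q2[0][0], q2[0][1]);
    const double m1 = std::max(q2[1][0], q2[1][1]);
    const double qmb0 = p_common * m0 + (1.0 - p_common) * m1;
    const double qmb1 = (1.0 - p_common) * m0 + p_common * m1;

    double v0 = omega * qmb0 + (1.0 - omega) * q1[0];
    double v1 = omega * qmb1 + (1.0 - omega) * q1[1];
    if (last_a1 == 0) v0 += rho;
    else if (last_a1 == 1) v1 += rho;

    double z0 = beta1 * v0, z1 = beta1 * v1;
    double zmax = std::max(z0, z1);
    double lse = zmax + std::log(std::exp(z0 - zmax) + std::exp(z1 - zmax));
    nll -= (c1 == 0 ? z0 : z1) - lse;

    z0 = beta2 * q2[st][0];
    z1 = beta2 * q2[st][1];
    zmax = std::max(z0, z1);
    lse = zmax + std::log(std::exp(z0 - zmax) + std::exp(z1 - zmax));
    nll -= (c2 == 0 ? z0 : z1) - lse;

    // SARSA(lambda) updates: delta1 with the pre-update stage-2 value
    const double delta1 = q2[st][c2] - q1[c1];
    const double delta2 = rew - q2[st][c2];
    q2[st][c2] += alpha2 * delta2;
    q1[c1] += alpha1 * delta1;
    q1[c1] += alpha1 * lam * delta2;
    last_a1 = c1;
  }
  return nll;
}
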