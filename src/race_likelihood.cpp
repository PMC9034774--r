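// Fast kernels for the ex-Gaussian race-model likelihood.
// All distribution math is done in log space; the normal log-CDF uses
// erfc with an asymptotic lower-tail expansion so extreme sigma/tau
// ratios stay finite.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double log_phi(double x) {
  if (x < -37.5) {
    double x2 = x * x;
    return -0.5 * x2 - 0.5 * std::log(2.0 * M_PI) - std::log(-x) +
      std::log1p(-1.0 / x2);
  }
  return std::log(0.5 * std::erfc(-x * M_SQRT1_2));
}

static inline double phi_bar(double x) {          // upper tail P(Z > x)
  return 0.5 * std::erfc(x * M_SQRT1_2);
}

// log ex-Gaussian density at t
static inline double ld_exg(double t, double mu, double sg, double ta) {
  double z = (t - mu) / sg;
  return -std::log(ta) + (mu - t) / ta + sg * sg / (2.0 * ta * ta) +
    log_phi(z - sg / ta);
}

// log ex-Gaussian survival at t
static inline double ls_exg(double t, double mu, double sg, double ta) {
  double z = (t - mu) / sg;
  double term = std::exp((mu - t) / ta + sg * sg / (2.0 * ta * ta) +
                         log_phi(z - sg / ta));
  double s = phi_bar(z) + term;
  if (s < 0.0) s = 0.0;
  if (s > 1.0) s = 1.0;
  return std::log(s);
}

// ex-Gaussian survival (probability scale), clamped to [0, 1]
static inline double s_exg(double t, double mu, double sg, double ta) {
  return std::exp(ls_exg(t, mu, sg, ta));
}

// Summed log-likelihood contributions of one stacked response block.
// rt: m observed RTs; ssd: m delays (ignored unless with_stop); pt: m
// 1-based participant indices; parameter planes are N x C (participant x
// chain); returns a C x N matrix of per-chain, per-participant sums.
// [[Rcpp::export]]
NumericMatrix resp_block_cpp(NumericVector rt, NumericVector ssd,
                             IntegerVector pt,
                             NumericMatrix MUr, NumericMatrix SGr, NumericMatrix TAr,
                             NumericMatrix MUo, NumericMatrix SGo, NumericMatrix TAo,
                             NumericMatrix MUs, NumericMatrix SGs, NumericMatrix TAs,
                             NumericMatrix PTF, NumericMatrix PGF,
                             bool with_stop) {
  const int m = rt.size(), N = MUr.nrow(), C = MUr.ncol();
  NumericMatrix out(C, N);
  for (int k = 0; k < m; ++k) {
    const int i = pt[k] - 1;
    const double t = rt[k];
    for (int c = 0; c < C; ++c) {
      double v = ld_exg(t, MUr(i, c), SGr(i, c), TAr(i, c)) +
        ls_exg(t, MUo(i, c), SGo(i, c), TAo(i, c)) +
        std::log1p(-PGF(i, c));
      if (with_stop) {
        double d = t - ssd[k];
        double ss = (d <= 0.0) ? 1.0 : s_exg(d, MUs(i, c), SGs(i, c), TAs(i, c));
        double ptf = PTF(i, c);
        v += std::log(ptf + (1.0 - ptf) * ss);
      }
      out(c, i) += v;
    }
  }
  return out;
}

// P(stop racer finishes before both go racers | all started) for stacked
// (participant, ssd) rows, by two-panel Gauss-Legendre quadrature matched
// to the ex-Gaussian stop density: the Gaussian bump (mu +/- 8 sigma) and
// the exponential tail (12 tau beyond it). nodes/weights are on [-1, 1].
// [[Rcpp::export]]
NumericMatrix stop_success_cpp(NumericVector ssd, IntegerVector pt,
                               NumericMatrix MU1, NumericMatrix SG1, NumericMatrix TA1,
                               NumericMatrix MU2, NumericMatrix SG2, NumericMatrix TA2,
                               NumericMatrix MUs, NumericMatrix SGs, NumericMatrix TAs,
                               NumericVector nodes, NumericVector weights) {
  const int R = ssd.size(), C = MUs.ncol(), nn = nodes.size();
  NumericMatrix out(R, C);
  for (int r = 0; r < R; ++r) {
    const int i = pt[r] - 1;
    const double d = ssd[r];
    for (int c = 0; c < C; ++c) {
      const double mu = MUs(i, c), sg = SGs(i, c), ta = TAs(i, c);
      const double b_lo = d + mu - 8.0 * sg;
      const double b_hi = d + mu + 8.0 * sg;
      const double t_hi = b_hi + 12.0 * ta;
      double acc = 0.0;
      for (int panel = 0; panel < 2; ++panel) {
        const double lo = panel == 0 ? b_lo : b_hi;
        const double hi = panel == 0 ? b_hi : t_hi;
        const double half = 0.5 * (hi - lo), mid = 0.5 * (hi + lo);
        double sum = 0.0;
        for (int q = 0; q < nn; ++q) {
          const double s = mid + half * nodes[q];
          const double f = std::exp(
            ld_exg(s - d, mu, sg, ta) +
              ls_exg(s, MU1(i, c), SG1(i, c), TA1(i, c)) +
              ls_exg(s, MU2(i, c), SG2(i, c), TA2(i, c)));
          sum += weights[q] * f;
        }
        acc += half * sum;
      }
      if (acc < 0.0) acc = 0.0;
      if (acc > 1.0) acc = 1.0;
      out(r, c) = acc;
    }
  }
  return out;
}
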