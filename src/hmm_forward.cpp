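#include <Rcpp.h>
using namespace Rcpp;

// Ordered three-state HMM with Gaussian emissions on log daily speed.
// Allowed moves: 1->1, 1->2, 2->2, 2->3, 3->3; the chain starts in state 1.
// Missing observations (NA) contribute transition-only steps.

static inline double lse3(double a, double b, double c) {
  double m = std::max(a, std::max(b, c));
  if (!std::isfinite(m)) return m;
  return m + std::log(std::exp(a - m) + std::exp(b - m) + std::exp(c - m));
}

static inline double ldnorm(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -0.5 * z * z - std::log(sd) - 0.9189385332046727;
}

// forward recursion in log space; alpha is overwritten in place
static void forward_pass(const NumericVector& y, const NumericVector& beta,
                         const NumericVector& sigma, double q1, double q2,
                         NumericMatrix& lalpha) {
  int T = y.size();
  const double NEG = R_NegInf;
  double l11 = std::log(1.0 - q1), l12 = std::log(q1);
  double l22 = std::log(1.0 - q2), l23 = std::log(q2);
  for (int k = 0; k < 3; ++k) lalpha(0, k) = (k == 0) ? 0.0 : NEG;
  if (!NumericVector::is_na(y[0])) lalpha(0, 0) += ldnorm(y[0], beta[0], sigma[0]);
  for (int t = 1; t < T; ++t) {
    double a1 = lalpha(t - 1, 0), a2 = lalpha(t - 1, 1), a3 = lalpha(t - 1, 2);
    double n1 = a1 + l11;
    double n2 = lse3(a1 + l12, a2 + l22, NEG);
    double n3 = lse3(a2 + l23, a3, NEG);
    if (!NumericVector::is_na(y[t])) {
      n1 += ldnorm(y[t], beta[0], sigma[0]);
      n2 += ldnorm(y[t], beta[1], sigma[1]);
      n3 += ldnorm(y[t], beta[2], sigma[2]);
    }
    lalpha(t, 0) = n1; lalpha(t, 1) = n2; lalpha(t, 2) = n3;
  }
}

// [[Rcpp::export]]
double hmm_forward_cpp(NumericVector y, NumericVector beta, NumericVector sigma,
                       double q1, double q2) {
  int T = y.size();
  NumericMatrix lalpha(T, 3);
  forward_pass(y, beta, sigma, q1, q2, lalpha);
  return lse3(lalpha(T - 1, 0), lalpha(T - 1, 1), lalpha(T - 1, 2));
}

// [[Rcpp::export]]
NumericMatrix hmm_smooth_cpp(NumericVector y, NumericVector beta,
                             NumericVector sigma, double q1, double q2) {
  int T = y.size();
  NumericMatrix lalpha(T, 3);
  forward_pass(y, beta, sigma, q1, q2, lalpha);
  const double NEG = R_NegInf;
  double l11 = std::log(1.0 - q1), l12 = std::log(q1);
  double l22 = std::log(1.0 - q2), l23 = std::log(q2);
  NumericMatrix lbeta(T, 3), post(T, 3);
  for (int k = 0; k < 3; ++k) lbeta(T - 1, k) = 0.0;
  for (int t = T - 2; t >= 0; --t) {
    double e1 = 0.0, e2 = 0.0, e3 = 0.0;
    if (!NumericVector::is_na(y[t + 1])) {
      e1 = ldnorm(y[t + 1], beta[0], sigma[0]);
      e2 = ldnorm(y[t + 1], beta[1], sigma[1]);
      e3 = ldnorm(y[t + 1], beta[2], sigma[2]);
    }
    lbeta(t, 0) = lse3(l11 + e1 + lbeta(t + 1, 0), l12 + e2 + lbeta(t + 1, 1), NEG);
    lbeta(t, 1) = lse3(l22 + e2 + lbeta(t + 1, 1), l23 + e3 + lbeta(t + 1, 2), NEG);
    lbeta(t, 2) = e3 + lbeta(t + 1, 2);
  }
  for (int t = 0; t < T; ++t) {
    double g1 = lalpha(t, 0) + lbeta(t, 0);
    double g2 = lalpha(t, 1) + lbeta(t, 1);
    double g3 = lalpha(t, 2) + lbeta(t, 2);
    double z = lse3(g1, g2, g3);
    post(t, 0) = std::exp(g1 - z);
    post(t, 1) = std::exp(g2 - z);
    post(t, 2) = std::exp(g3 - z);
  }
  return post;
}

// forward-filtering backward-sampling of one state path; u holds T
// uniform(0,1) draws supplied by the caller (R RNG)
// [[Rcpp::export]]
IntegerVector hmm_ffbs_cpp(NumericVector y, NumericVector beta,
                           NumericVector sigma, double q1, double q2,
                           NumericVector u) {
  int T = y.size();
  NumericMatrix lalpha(T, 3);
  forward_pass(y, beta, sigma, q1, q2, lalpha);
  IntegerVector path(T);
  double l11 = std::log(1.0 - q1), l12 = std::log(q1);
  double l22 = std::log(1.0 - q2), l23 = std::log(q2);
  // sample final state
  {
    double z = lse3(lalpha(T - 1, 0), lalpha(T - 1, 1), lalpha(T - 1, 2));
    double p1 = std::exp(lalpha(T - 1, 0) - z);
    double p2 = std::exp(lalpha(T - 1, 1) - z);
    double r = u[T - 1];
    path[T - 1] = (r < p1) ? 1 : (r < p1 + p2 ? 2 : 3);
  }
  for (int t = T - 2; t >= 0; --t) {
    int nxt = path[t + 1];
    double w1 = R_NegInf, w2 = R_NegInf, w3 = R_NegInf;
    if (nxt == 1) {
      w1 = lalpha(t, 0) + l11;
    } else if (nxt == 2) {
      w1 = lalpha(t, 0) + l12;
      w2 = lalpha(t, 1) + l22;
    } else {
      w2 = lalpha(t, 1) + l23;
      w3 = lalpha(t, 2);
    }
    double z = lse3(w1, w2, w3);
    double p1 = std::exp(w1 - z), p2 = std::exp(w2 - z);
    double r = u[t];
    path[t] = (r < p1) ? 1 : (r < p1 + p2 ? 2 : 3);
  }
  return path;
}
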