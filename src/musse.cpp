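// MuSSE (multiple state speciation and extinction) likelihood core.
//
// Along every branch the coupled ODEs for the extinction probabilities E_i
// and the data densities D_i are integrated backward in time:
//
//   dE_i/dt = mu_i - (lambda_i + mu_i + sum_{j!=i} q_ij) E_i
//             + lambda_i E_i^2 + sum_{j!=i} q_ij E_j
//   dD_i/dt = -(lambda_i + mu_i + sum_{j!=i} q_ij) D_i
//             + sum_{j!=i} q_ij D_j + 2 lambda_i E_i D_i
//
// Tip conditions: D_i = rho_i * 1[state == i], E_i = 1 - rho_i. At internal
// nodes D_i <- D_left,i * D_right,i * lambda_i. D is renormalized after
// every branch with the factor accumulated in a running log-compensation.
// Integration: adaptive Cash-Karp Runge-Kutta 4(5).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct MussePars {
  int k;
  std::vector<double> lambda, mu, qout;
  std::vector<double> q; // k*k, row-major, off-diagonals
};

static inline void derivs(const MussePars& p, const double* y, double* dy) {
  const int k = p.k;
  const double* E = y;
  const double* D = y + k;
  for (int i = 0; i < k; ++i) {
    double sumqE = 0.0, sumqD = 0.0;
    for (int j = 0; j < k; ++j) {
      if (j == i) continue;
      const double qij = p.q[i * k + j];
      sumqE += qij * E[j];
      sumqD += qij * D[j];
    }
    const double tot = p.lambda[i] + p.mu[i] + p.qout[i];
    dy[i] = p.mu[i] - tot * E[i] + p.lambda[i] * E[i] * E[i] + sumqE;
    dy[k + i] = -tot * D[i] + sumqD + 2.0 * p.lambda[i] * E[i] * D[i];
  }
}

// Cash-Karp RK45 step; returns max scaled error
static double ck_step(const MussePars& p, const double* y, double h,
                      double* yout, double rtol, double atol) {
  static const double b21 = 1.0 / 5.0;
  static const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
  static const double b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0;
  static const double b51 = -11.0 / 54.0, b52 = 5.0 / 2.0,
                      b53 = -70.0 / 27.0, b54 = 35.0 / 27.0;
  static const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
                      b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
                      b65 = 253.0 / 4096.0;
  static const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0,
                      c4 = 125.0 / 594.0, c6 = 512.0 / 1771.0;
  static const double dc1 = c1 - 2825.0 / 27648.0,
                      dc3 = c3 - 18575.0 / 48384.0,
                      dc4 = c4 - 13525.0 / 55296.0,
                      dc5 = -277.0 / 14336.0, dc6 = c6 - 1.0 / 4.0;
  const int n = 2 * p.k;
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), yt(n);

  derivs(p, y, k1.data());
  for (int i = 0; i < n; ++i) yt[i] = y[i] + h * b21 * k1[i];
  derivs(p, yt.data(), k2.data());
  for (int i = 0; i < n; ++i) yt[i] = y[i] + h * (b31 * k1[i] + b32 * k2[i]);
  derivs(p, yt.data(), k3.data());
  for (int i = 0; i < n; ++i)
    yt[i] = y[i] + h * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
  derivs(p, yt.data(), k4.data());
  for (int i = 0; i < n; ++i)
    yt[i] = y[i] + h * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i] + b54 * k4[i]);
  derivs(p, yt.data(), k5.data());
  for (int i = 0; i < n; ++i)
    yt[i] = y[i] + h * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i] +
                        b64 * k4[i] + b65 * k5[i]);
  derivs(p, yt.data(), k6.data());

  double errmax = 0.0;
  for (int i = 0; i < n; ++i) {
    yout[i] = y[i] + h * (c1 * k1[i] + c3 * k3[i] + c4 * k4[i] + c6 * k6[i]);
    const double erri = h * (dc1 * k1[i] + dc3 * k3[i] + dc4 * k4[i] +
                             dc5 * k5[i] + dc6 * k6[i]);
    const double sc = atol + rtol * std::max(std::fabs(y[i]),
                                             std::fabs(yout[i]));
    errmax = std::max(errmax, std::fabs(erri) / sc);
  }
  return errmax;
}

static void integrate_branch(const MussePars& p, std::vector<double>& y,
                             double len, double rtol, double atol,
                             int branch_id) {
  if (len <= 0.0) return;
  double t = 0.0;
  double h = len / 10.0;
  const int n = 2 * p.k;
  std::vector<double> ytmp(n);
  int steps = 0;
  while (t < len) {
    if (t + h > len) h = len - t;
    const double err = ck_step(p, y.data(), h, ytmp.data(), rtol, atol);
    if (err <= 1.0) {
      t += h;
      y = ytmp;
      h *= std::min(5.0, 0.9 * std::pow(std::max(err, 1e-12), -0.2));
    } else {
      h *= std::max(0.1, 0.9 * std::pow(err, -0.25));
    }
    if (++steps > 1000000)
      stop("ODE integration failed on branch %d (too many steps)", branch_id);
    if (h < 1e-14 * len)
      stop("ODE integration failed on branch %d (step underflow)", branch_id);
  }
  // E must stay a probability; clamp round-off, abort on real excursions
  for (int i = 0; i < p.k; ++i) {
    if (y[i] < -1e-6 || y[i] > 1.0 + 1e-6)
      stop("E left [0,1] on branch %d", branch_id);
    y[i] = std::min(1.0, std::max(0.0, y[i]));
    if (y[p.k + i] < 0.0) y[p.k + i] = 0.0;
  }
}

static MussePars make_pars(NumericVector lambda, NumericVector mu,
                           NumericMatrix Q) {
  MussePars p;
  p.k = lambda.size();
  p.lambda.assign(lambda.begin(), lambda.end());
  p.mu.assign(mu.begin(), mu.end());
  p.q.assign(p.k * p.k, 0.0);
  p.qout.assign(p.k, 0.0);
  for (int i = 0; i < p.k; ++i)
    for (int j = 0; j < p.k; ++j)
      if (i != j) {
        p.q[i * p.k + j] = Q(i, j);
        p.qout[i] += Q(i, j);
      }
  return p;
}

// [[Rcpp::export]]
double musse_loglik_cpp(IntegerMatrix edge, NumericVector edge_length,
                        int n_tip, IntegerVector tip_state,
                        NumericVector lambda, NumericVector mu,
                        NumericMatrix Q, NumericVector rho, int root_mode,
                        NumericVector root_prior, double rtol, double atol) {
  const MussePars p = make_pars(lambda, mu, Q);
  const int k = p.k;
  const int n_edge = edge.nrow();
  const int n_node = n_tip + n_edge / 2 + 1; // binary tree; +1 slack below
  const int total = std::max(n_node, n_tip) + n_edge + 2;

  std::vector<std::vector<double> > D(total, std::vector<double>(k, 0.0));
  std::vector<std::vector<double> > E(total, std::vector<double>(k, 0.0));
  std::vector<int> seen(total, 0);

  for (int t = 0; t < n_tip; ++t) {
    const int s = tip_state[t] - 1;
    for (int i = 0; i < k; ++i) {
      D[t][i] = (i == s) ? rho[i] : 0.0;
      E[t][i] = 1.0 - rho[i];
    }
    seen[t] = 2;
  }

  double logcomp = 0.0;
  std::vector<double> y(2 * k);
  for (int e = 0; e < n_edge; ++e) {
    const int ch = edge(e, 1) - 1;
    const int par = edge(e, 0) - 1;
    if (seen[ch] < 2) stop("postorder violated at edge %d", e + 1);
    for (int i = 0; i < k; ++i) {
      y[i] = E[ch][i];
      y[k + i] = D[ch][i];
    }
    integrate_branch(p, y, edge_length[e], rtol, atol, e + 1);
    double s = 0.0;
    for (int i = 0; i < k; ++i) s += y[k + i];
    if (!(s > 0.0) || !std::isfinite(s)) return R_NegInf;
    logcomp += std::log(s);
    if (seen[par] == 0) {
      for (int i = 0; i < k; ++i) {
        E[par][i] = y[i];
        D[par][i] = y[k + i] / s;
      }
      seen[par] = 1;
    } else {
      double s2 = 0.0;
      for (int i = 0; i < k; ++i) {
        E[par][i] = 0.5 * (E[par][i] + y[i]);
        D[par][i] *= (y[k + i] / s) * p.lambda[i];
        s2 += D[par][i];
      }
      if (!(s2 > 0.0)) return R_NegInf;
      logcomp += std::log(s2);
      for (int i = 0; i < k; ++i) D[par][i] /= s2;
      seen[par] = 2;
    }
  }

  const int root = n_tip; // ape convention: root is node n_tip + 1
  double val = 0.0, sumD = 0.0;
  for (int i = 0; i < k; ++i) sumD += D[root][i];
  if (!(sumD > 0.0)) return R_NegInf;
  if (root_mode == 0) { // FitzJohn weighting w_i = D_i / sum(D)
    for (int i = 0; i < k; ++i) val += D[root][i] * D[root][i] / sumD;
  } else if (root_mode == 1) { // flat
    val = sumD / k;
  } else { // given prior
    for (int i = 0; i < k; ++i) val += root_prior[i] * D[root][i];
  }
  if (!(val > 0.0)) return R_NegInf;
  return std::log(val) + logcomp;
}

// Dense trajectory of (E, D) along one branch, for validation against an
// independent ODE solver and for monotonicity checks on E.
// [[Rcpp::export]]
NumericMatrix musse_branch_cpp(NumericVector y0, double t_total,
                               NumericVector lambda, NumericVector mu,
                               NumericMatrix Q, int n_out, double rtol,
                               double atol) {
  const MussePars p = make_pars(lambda, mu, Q);
  const int n = 2 * p.k;
  NumericMatrix out(n_out + 1, n + 1);
  std::vector<double> y(y0.begin(), y0.end());
  out(0, 0) = 0.0;
  for (int j = 0; j < n; ++j) out(0, j + 1) = y[j];
  const double dt = t_total / n_out;
  for (int m = 1; m <= n_out; ++m) {
    integrate_branch(p, y, dt, rtol, atol, m);
    out(m, 0) = m * dt;
    for (int j = 0; j < n; ++j) out(m, j + 1) = y[j];
  }
  return out;
}
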