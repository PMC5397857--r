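#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Euler-Maruyama integration of
//   dtheta_j = omega_j + S * sum_k A_jk sin(theta_k - theta_j - beta) + xi_j
// with Gaussian white noise xi (mean noise_mean, SD noise_sd, sqrt(dt)
// scaling). A_jk is the coupling from k to j. Phases are unwrapped.
// Every store_every-th state is kept (plus the initial state); returns an
// N x (nsteps / store_every + 1) matrix.
// [[Rcpp::export]]
arma::mat kuramoto_offset_cpp(const arma::mat& A, const arma::vec& omega,
                              double S, double beta, double noise_sd,
                              double noise_mean, double dt, int nsteps,
                              const arma::vec& theta0, int store_every = 1) {
  const int N = A.n_rows;
  arma::mat out(N, nsteps / store_every + 1);
  arma::vec th = theta0;
  out.col(0) = th;
  const double sqdt = std::sqrt(dt);
  RNGScope scope;
  for (int t = 0; t < nsteps; ++t) {
    // sum_k A_jk sin(th_k - th_j - beta)
    //   = cos(th_j + beta) * (A sin th)_j - sin(th_j + beta) * (A cos th)_j
    arma::vec s = arma::sin(th), c = arma::cos(th);
    arma::vec As = A * s, Ac = A * c;
    arma::vec thb = th + beta;
    arma::vec coup = arma::cos(thb) % As - arma::sin(thb) % Ac;
    for (int j = 0; j < N; ++j) {
      double step = dt * (omega[j] + S * coup[j] + noise_mean);
      if (noise_sd > 0.0) step += sqdt * noise_sd * R::rnorm(0.0, 1.0);
      th[j] += step;
      if (!std::isfinite(th[j]))
        stop("non-finite phase for node %d at step %d", j + 1, t + 1);
    }
    if ((t + 1) % store_every == 0) out.col((t + 1) / store_every) = th;
  }
  return out;
}

// Same model with explicit per-edge transmission delays (in integer steps,
// matrix D aligned with A). theta_k(t - tau) is read from the stored
// history; for t - tau < 0 the history is extrapolated backwards at the
// natural frequency: theta_k(-u) = theta_k(0) - omega_k * u * dt.
// [[Rcpp::export]]
arma::mat kuramoto_delay_cpp(const arma::mat& A, const arma::imat& D,
                             const arma::vec& omega, double S, double noise_sd,
                             double noise_mean, double dt, int nsteps,
                             const arma::vec& theta0) {
  const int N = A.n_rows;
  arma::mat out(N, nsteps + 1);
  out.col(0) = theta0;
  const double sqdt = std::sqrt(dt);
  // edge list of nonzero couplings: k -> j
  std::vector<int> ej, ek, ed;
  std::vector<double> ew;
  for (int j = 0; j < N; ++j)
    for (int k = 0; k < N; ++k)
      if (A(j, k) != 0.0) {
        ej.push_back(j); ek.push_back(k);
        ed.push_back(D(j, k)); ew.push_back(A(j, k));
      }
  RNGScope scope;
  for (int t = 0; t < nsteps; ++t) {
    arma::vec drift = omega;
    for (size_t e = 0; e < ej.size(); ++e) {
      const int j = ej[e], k = ek[e], lag = t - ed[e];
      const double thk = (lag >= 0) ? out(k, lag)
                                    : out(k, 0) + omega[k] * lag * dt;
      drift[j] += S * ew[e] * std::sin(thk - out(j, t));
    }
    for (int j = 0; j < N; ++j) {
      double step = dt * (drift[j] + noise_mean);
      if (noise_sd > 0.0) step += sqdt * noise_sd * R::rnorm(0.0, 1.0);
      const double val = out(j, t) + step;
      if (!std::isfinite(val))
        stop("non-finite phase for node %d at step %d", j + 1, t + 1);
      out(j, t + 1) = val;
    }
  }
  return out;
}

static inline double wrap_pm_pi(double d) {
  d -= 2.0 * M_PI * std::floor((d + M_PI) / (2.0 * M_PI)); // [-pi, pi)
  if (d >= M_PI) d -= 2.0 * M_PI; // guard rounding at the upper edge
  if (d == -M_PI) d = M_PI;       // convention: (-pi, pi]
  return d;
}

// Pairwise directed phase lag index: mean over samples of
// sign(wrap(theta_i - theta_j)), differences wrapped to (-pi, pi] first.
// Antisymmetric with zero diagonal.
// [[Rcpp::export]]
arma::mat dpli_matrix_cpp(const arma::mat& phases) {
  const int N = phases.n_rows, T = phases.n_cols;
  arma::mat Dm(N, N, arma::fill::zeros);
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      double acc = 0.0;
      for (int t = 0; t < T; ++t) {
        const double d = wrap_pm_pi(phases(i, t) - phases(j, t));
        acc += (d > 0.0) - (d < 0.0);
      }
      const double v = acc / T;
      Dm(i, j) = v;
      Dm(j, i) = -v;
    }
  return Dm;
}
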