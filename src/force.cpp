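// FORCE-trained recurrent network: Euler simulation and per-timestep
// recursive-least-squares training. All randomness is drawn from the R RNG
// so results are reproducible under set.seed().

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
using namespace Rcpp;

static inline arma::vec sigma_act(const arma::vec& x, double beta, double theta) {
  return 1.0 / (1.0 + arma::exp(-beta * (x - theta)));
}

static arma::vec rnorm_vec(int n, double sd) {
  arma::vec v(n);
  for (int i = 0; i < n; ++i) v[i] = ::norm_rand() * sd;
  return v;
}

// Euler integration of tau x' = -x + J r + Wstim I_stim + Wcue I_cue + noise.
// Returns the activity matrix r (n x T).
// [[Rcpp::export]]
arma::mat cpp_rnn_simulate(const arma::mat& J, const arma::vec& wstim,
                           const arma::vec& wcue, const arma::vec& istim,
                           const arma::vec& icue, double dt, double tau,
                           double beta, double theta, double noise_sd,
                           const arma::vec& x0) {
  GetRNGstate();
  const int n = J.n_rows, T = istim.n_elem;
  arma::mat R(n, T);
  arma::vec x = x0;
  arma::vec r = sigma_act(x, beta, theta);
  arma::vec z(n);
  const double a = dt / tau;
  const double one = 1.0, zero = 0.0;
  const int ione = 1;
  for (int t = 0; t < T; ++t) {
    F77_CALL(dgemv)("N", &n, &n, &one, J.memptr(), &n, r.memptr(), &ione,
                    &zero, z.memptr(), &ione FCONE);
    z += wstim * istim[t] + wcue * icue[t];
    if (noise_sd > 0) z += rnorm_vec(n, noise_sd);
    x += a * (z - x);
    r = sigma_act(x, beta, theta);
    if (!x.is_finite()) {
      PutRNGstate();
      stop("non-finite network state at step %d", t + 1);
    }
    R.col(t) = r;
  }
  PutRNGstate();
  return R;
}

// One FORCE training episode on target currents f (n x T): per-timestep
// state update, error e = z - f, rank-one RLS update of J and P.
// J and P are modified in place; returns the episode MSE.
// [[Rcpp::export]]
double cpp_force_episode(arma::mat& J, arma::mat& P, const arma::vec& wstim,
                         const arma::vec& wcue, const arma::vec& istim,
                         const arma::vec& icue, const arma::mat& f,
                         double alpha_learn, double dt, double tau,
                         double beta, double theta, double noise_sd,
                         const arma::vec& x0, int update_every = 1) {
  GetRNGstate();
  const int n = J.n_rows, T = f.n_cols;
  arma::vec x = x0;
  arma::vec r = sigma_act(x, beta, theta);
  arma::vec z(n), e(n), Pr(n);
  const double a = dt / tau;
  const double one = 1.0, zero = 0.0;
  const int ione = 1;
  double mse = 0.0;
  for (int t = 0; t < T; ++t) {
    // z = J r + inputs (+ noise)
    F77_CALL(dgemv)("N", &n, &n, &one, J.memptr(), &n, r.memptr(), &ione,
                    &zero, z.memptr(), &ione FCONE);
    z += wstim * istim[t] + wcue * icue[t];
    if (noise_sd > 0) z += rnorm_vec(n, noise_sd);
    x += a * (z - x);
    r = sigma_act(x, beta, theta);
    e = z - f.col(t);
    if (t % update_every == 0) {
      // Pr = P r; rank-one RLS updates of J and P, in place
      F77_CALL(dsymv)("U", &n, &one, P.memptr(), &n, r.memptr(), &ione,
                      &zero, Pr.memptr(), &ione FCONE);
      double denom = 1.0 + arma::dot(r, Pr);
      double cJ = -alpha_learn / denom;
      F77_CALL(dger)(&n, &n, &cJ, e.memptr(), &ione, Pr.memptr(), &ione,
                     J.memptr(), &n);
      double cP = -1.0 / denom;
      F77_CALL(dsyr)("U", &n, &cP, Pr.memptr(), &ione, P.memptr(), &n FCONE);
    }
    mse += arma::mean(arma::square(e));
    if (!x.is_finite()) {
      PutRNGstate();
      stop("FORCE training diverged at step %d", t + 1);
    }
  }
  // dsyr touched only the upper triangle; restore symmetry
  P = arma::symmatu(P);
  if (!P.is_finite()) { PutRNGstate(); stop("FORCE training diverged (P)"); }
  PutRNGstate();
  return mse / T;
}
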