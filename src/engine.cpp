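// Langevin (BBK) integrator over the elastic network and the Maxwell-demon
// transition loop. Units: Angstrom, fs, Da; energies enter in kcal/mol and
// are converted with KCAL2INT. Random numbers come from R's generator so
// set.seed() on the R side makes every run bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double KB_KCAL = 0.0019872041;   // kcal mol^-1 K^-1
static const double KCAL2INT = 4.184e-4;      // kcal/mol -> Da A^2 fs^-2

// spring forces, internal units (Da A fs^-2); V = sum K (d - d0)^2
// raw-pointer kernel: this is the hot loop of every simulation
static void net_forces(const arma::mat& x, const arma::imat& pairs,
                       const arma::vec& K, const arma::vec& d0,
                       arma::mat& F) {
  F.zeros();
  const int m = pairs.n_rows;
  const int n = x.n_rows;
  const double* X = x.memptr();          // column-major: X[c*n + row]
  double* Fp = F.memptr();
  const arma::sword* pi = pairs.colptr(0);
  const arma::sword* pj = pairs.colptr(1);
  const double* Kp = K.memptr();
  const double* D0 = d0.memptr();
  for (int p = 0; p < m; ++p) {
    const int i = pi[p] - 1, j = pj[p] - 1;
    const double dx = X[j] - X[i];
    const double dy = X[n + j] - X[n + i];
    const double dz = X[2 * n + j] - X[2 * n + i];
    const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d <= 0.0) stop("coincident bonded pair during simulation");
    const double coef = 2.0 * Kp[p] * (d - D0[p]) / d * KCAL2INT;
    Fp[i] += coef * dx;           Fp[j] -= coef * dx;
    Fp[n + i] += coef * dy;       Fp[n + j] -= coef * dy;
    Fp[2 * n + i] += coef * dz;   Fp[2 * n + j] -= coef * dz;
  }
}

static void gauss_fill(arma::mat& R, double sigma) {
  for (arma::uword k = 0; k < R.n_elem; ++k) R(k) = sigma * norm_rand();
}

static void sanity(const arma::mat& x, const arma::mat& v, int step) {
  if (!x.is_finite() || !v.is_finite() ||
      arma::abs(x).max() > 1e6 || arma::abs(v).max() > 1e3)
    stop("numerical blow-up at step %d", step);
}

// One BBK stretch of n_steps. F_cur / R_cur carry state across calls.
static void bbk_run(arma::mat& x, arma::mat& v, arma::mat& F_cur,
                    arma::mat& R_cur, const arma::imat& pairs,
                    const arma::vec& K, const arma::vec& d0,
                    int n_steps, double dt, double gamma, double mass,
                    double sigmaF, double& ke_accum, int step0) {
  const double a1 = 1.0 - 0.5 * gamma * dt;
  const double a2 = 1.0 / (1.0 + 0.5 * gamma * dt);
  const double h = 0.5 * dt / mass;
  for (int s = 0; s < n_steps; ++s) {
    v = a1 * v + h * (F_cur + R_cur);
    x += dt * v;
    net_forces(x, pairs, K, d0, F_cur);
    gauss_fill(R_cur, sigmaF);
    v = a2 * (v + h * (F_cur + R_cur));
    ke_accum += 0.5 * mass * arma::accu(v % v);
    if ((s & 1023) == 0) sanity(x, v, step0 + s);
  }
}

static double kabsch_rmsd(const arma::mat& P0, const arma::mat& Q0) {
  arma::mat P = P0, Q = Q0;
  P.each_row() -= arma::mean(P, 0);
  Q.each_row() -= arma::mean(Q, 0);
  arma::mat H = P.t() * Q, U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) stop("svd failure in rmsd");
  double d = arma::det(V * U.t()) < 0 ? -1.0 : 1.0;
  arma::mat R = U * arma::diagmat(arma::vec({1.0, 1.0, d})) * V.t();
  arma::mat dev = P * R - Q;
  return std::sqrt(arma::accu(dev % dev) / P.n_rows);
}

static double progress_var(const arma::mat& x, const arma::imat& gp,
                           const arma::vec& dt_target) {
  double g = 0.0;
  const int n = x.n_rows;
  const double* X = x.memptr();
  const arma::sword* pi = gp.colptr(0);
  const arma::sword* pj = gp.colptr(1);
  const double* T = dt_target.memptr();
  for (arma::uword p = 0; p < gp.n_rows; ++p) {
    const int i = pi[p] - 1, j = pj[p] - 1;
    const double dx = X[j] - X[i];
    const double dy = X[n + j] - X[n + i];
    const double dz = X[2 * n + j] - X[2 * n + i];
    const double diff = std::sqrt(dx * dx + dy * dy + dz * dz) - T[p];
    g += diff * diff;
  }
  return g;
}

// [[Rcpp::export]]
List cpp_run_langevin(arma::mat coords, arma::mat vel, arma::imat pairs,
                      arma::vec K, arma::vec d0, int n_steps, double dt,
                      double gamma, double temperature, double mass,
                      int stride, bool remove_com) {
  RNGScope rng;
  const int n = coords.n_rows;
  const double kT = KB_KCAL * temperature * KCAL2INT;
  const double sigmaF = std::sqrt(2.0 * gamma * mass * kT / dt);

  arma::mat F(n, 3), R(n, 3);
  net_forces(coords, pairs, K, d0, F);
  gauss_fill(R, sigmaF);

  const int n_out = n_steps / stride;
  arma::cube frames(n, 3, n_out);
  arma::vec ke_frame(n_out), tk_frame(n_out);
  double ke_total = 0.0;
  int out = 0;
  for (int blk = 0; blk < n_out; ++blk) {
    double ke_blk = 0.0;
    bbk_run(coords, vel, F, R, pairs, K, d0, stride, dt, gamma, mass,
            sigmaF, ke_blk, blk * stride);
    ke_total += ke_blk;
    if (remove_com)
      coords.each_row() -= arma::mean(coords, 0);  // molecule stays at origin
    frames.slice(out) = coords;
    ke_frame(out) = 0.5 * mass * arma::accu(vel % vel) / KCAL2INT;
    tk_frame(out) = (mass * arma::accu(vel % vel) / KCAL2INT) /
                    (3.0 * n * KB_KCAL);
    ++out;
  }
  // leftover steps (n_steps not a multiple of stride)
  int rest = n_steps - n_out * stride;
  if (rest > 0) {
    double ke_blk = 0.0;
    bbk_run(coords, vel, F, R, pairs, K, d0, rest, dt, gamma, mass,
            sigmaF, ke_blk, n_out * stride);
    ke_total += ke_blk;
  }
  // <KE> = (3/2) N kB T  =>  T = 2 <KE_int> / (3 N kB_int)
  const double tkin = (2.0 * (ke_total / n_steps)) /
                      (3.0 * n * KB_KCAL * KCAL2INT);
  return List::create(_["coords"] = coords, _["velocities"] = vel,
                      _["frames"] = frames, _["ke_frame"] = ke_frame,
                      _["temp_frame"] = tk_frame,
                      _["mean_kinetic_temperature"] = tkin);
}

// [[Rcpp::export]]
List cpp_run_transition(arma::mat coords, arma::imat pairs, arma::vec K,
                        arma::vec d0, arma::imat gamma_pairs,
                        arma::vec gamma_target_d, arma::uvec target_idx,
                        arma::mat target_coords, int k_unbiased,
                        int max_cycles, double conv_rmsd, double dt,
                        double gamma, double temperature, double mass) {
  RNGScope rng;
  const int n = coords.n_rows;
  const double kT = KB_KCAL * temperature * KCAL2INT;
  const double sigmaF = std::sqrt(2.0 * gamma * mass * kT / dt);
  const double vsig = std::sqrt(kT / mass);

  arma::mat vel(n, 3);
  gauss_fill(vel, vsig);                       // Maxwell-Boltzmann start

  arma::mat F(n, 3), R(n, 3);
  net_forces(coords, pairs, K, d0, F);
  gauss_fill(R, sigmaF);

  arma::uvec tidx = target_idx - 1;
  double g_prev = progress_var(coords, gamma_pairs, gamma_target_d);
  double r_now = kabsch_rmsd(coords.rows(tidx), target_coords);

  std::vector<arma::mat> frames;
  std::vector<double> g_series, r_series;
  frames.push_back(coords);
  g_series.push_back(g_prev);
  r_series.push_back(r_now);

  bool converged = r_now <= conv_rmsd;
  int n_rej = 0, cycle = 0;
  arma::mat cp_x = coords, cp_v = vel, cp_F = F;

  while (!converged && cycle < max_cycles) {
    ++cycle;
    double ke_dummy = 0.0;
    bbk_run(coords, vel, F, R, pairs, K, d0, k_unbiased, dt, gamma, mass,
            sigmaF, ke_dummy, cycle * k_unbiased);
    const double g_now = progress_var(coords, gamma_pairs, gamma_target_d);
    if (g_now < g_prev) {                      // demon accepts
      g_prev = g_now;
      cp_x = coords; cp_v = vel; cp_F = F;
      r_now = kabsch_rmsd(coords.rows(tidx), target_coords);
      frames.push_back(coords);
      g_series.push_back(g_now);
      r_series.push_back(r_now);
      if (r_now <= conv_rmsd) converged = true;
    } else {                                   // revert, RNG stream continues
      ++n_rej;
      coords = cp_x; vel = cp_v; F = cp_F;
    }
  }

  const int nf = frames.size();
  arma::cube fr(n, 3, nf);
  for (int k = 0; k < nf; ++k) fr.slice(k) = frames[k];
  return List::create(_["frames"] = fr,
                      _["gamma_series"] = arma::vec(g_series),
                      _["rmsd_to_target"] = arma::vec(r_series),
                      _["converged"] = converged,
                      _["n_rejections"] = n_rej,
                      _["cycles_run"] = cycle);
}
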