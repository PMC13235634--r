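// Overdamped Langevin stepper for the thermophoresis stand-in model.
// Ito convention for the position-dependent noise amplitude: the noise
// prefactor is evaluated at the pre-step position.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline double lin_interp(const NumericVector& xg, const NumericVector& yg,
                                double x) {
  const int n = xg.size();
  const double dx = (xg[n - 1] - xg[0]) / (n - 1);
  double u = (x - xg[0]) / dx;
  if (u <= 0.0) return yg[0];
  if (u >= n - 1) return yg[n - 1];
  const int i = static_cast<int>(u);
  const double f = u - i;
  return yg[i] * (1.0 - f) + yg[i + 1] * f;
}

// [[Rcpp::export]]
List langevin_step_cpp(NumericVector z0, NumericVector theta0,
                       NumericVector zgrid, NumericVector dF,
                       NumericVector Tgrid,
                       double gamma, double dt, int n_steps,
                       double kB, double z_star, double z_lo, double z_hi,
                       double z_commit,
                       double theta_tau, double theta_sd,
                       double theta_mean_up, double theta_mean_down,
                       int stride) {
  RNGScope scope;  // use R's RNG so set.seed() controls everything
  const int np = z0.size();
  std::vector<double> z(z0.begin(), z0.end());
  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<int> side(np);  // committed side: -1, +1 (0 = undecided)
  for (int p = 0; p < np; ++p)
    side[p] = (z[p] > z_star) ? 1 : -1;

  const int n_stored = n_steps / stride + 1;
  NumericMatrix zout(n_stored, np), thout(n_stored, np);
  IntegerVector stored_steps(n_stored);
  std::vector<int> cr_step, cr_particle, cr_dir;
  std::vector<double> occ(np, 0.0);

  int row = 0;
  for (int p = 0; p < np; ++p) { zout(0, p) = z[p]; thout(0, p) = th[p]; }
  stored_steps[0] = 0;
  row = 1;

  const double th_relax = dt / theta_tau;
  const double th_noise = theta_sd * std::sqrt(2.0 * dt / theta_tau);

  for (int s = 1; s <= n_steps; ++s) {
    for (int p = 0; p < np; ++p) {
      const double f = lin_interp(zgrid, dF, z[p]);
      const double T = lin_interp(zgrid, Tgrid, z[p]);
      const double amp = std::sqrt(2.0 * kB * T * dt / gamma);
      z[p] += -f / gamma * dt + amp * norm_rand();
      if (z[p] < z_lo || z[p] > z_hi)
        stop("particle %d diverged (z = %.3f nm) at step %d", p + 1, z[p], s);
      // well-to-well crossing with commitment hysteresis
      if (side[p] <= 0 && z[p] > z_star + z_commit) {
        if (side[p] == -1) {
          cr_step.push_back(s); cr_particle.push_back(p + 1); cr_dir.push_back(+1);
        }
        side[p] = 1;
      } else if (side[p] >= 0 && z[p] < z_star - z_commit) {
        if (side[p] == 1) {
          cr_step.push_back(s); cr_particle.push_back(p + 1); cr_dir.push_back(-1);
        }
        side[p] = -1;
      }
      if (z[p] > z_star) occ[p] += 1.0;
      const double mean = (z[p] > z_star) ? theta_mean_up : theta_mean_down;
      th[p] += (mean - th[p]) * th_relax + th_noise * norm_rand();
    }
    if (s % stride == 0 && row < n_stored) {
      for (int p = 0; p < np; ++p) { zout(row, p) = z[p]; thout(row, p) = th[p]; }
      stored_steps[row] = s;
      ++row;
    }
  }

  NumericVector occ_p(np);
  double occ_all = 0.0;
  for (int p = 0; p < np; ++p) {
    occ_p[p] = occ[p] / n_steps;
    occ_all += occ_p[p];
  }
  occ_all /= np;

  return List::create(
    _["z"] = zout, _["theta"] = thout,
    _["stored_steps"] = stored_steps,
    _["occupancy_hot"] = occ_all,
    _["occupancy_by_particle"] = occ_p,
    _["crossing_step"] = IntegerVector(cr_step.begin(), cr_step.end()),
    _["crossing_particle"] = IntegerVector(cr_particle.begin(), cr_particle.end()),
    _["crossing_direction"] = IntegerVector(cr_dir.begin(), cr_dir.end()));
}
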