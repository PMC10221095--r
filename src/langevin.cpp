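#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Overdamped Langevin integrator for an elastic-network bead model with an
// optional pulling force on one steered bead.
//
// load_mode: 0 none, 1 ramp (moving-spring, constant velocity),
//            2 clamp (constant force).
// Units: coordinates A, time ns, energies kcal/mol, forces kcal/(mol A);
// gamma in kcal mol^-1 ns A^-2 so that dx = F/gamma * dt + sqrt(2 kBT dt/gamma) xi.
// Draws come from R's RNG so set.seed() controls reproducibility.
// Breakable springs are removed permanently once stretched past
// break_factor * r0 (break_factor <= 0 disables breakage).
// [[Rcpp::export]]
List cpp_langevin(NumericMatrix coords,
                  IntegerMatrix spring_ij,
                  NumericVector spring_r0,
                  NumericVector spring_k,
                  LogicalVector spring_breakable,
                  double break_factor,
                  IntegerVector fixed,
                  int steered,
                  NumericVector direction,
                  int load_mode,
                  double k_spring,
                  double v_pull,
                  double clamp_force,
                  double gamma,
                  double kBT,
                  double dt,
                  int n_steps,
                  int sample_every,
                  bool rigid_steered,
                  bool stop_at_force,
                  double stop_force) {
  const int nb = coords.nrow();
  const int ns = spring_ij.nrow();
  std::vector<double> x(nb), y(nb), z(nb);
  for (int i = 0; i < nb; ++i) { x[i] = coords(i,0); y[i] = coords(i,1); z[i] = coords(i,2); }
  std::vector<bool> is_fixed(nb, false);
  for (int i = 0; i < fixed.size(); ++i) is_fixed[fixed[i]] = true;
  if (rigid_steered && steered >= 0) is_fixed[steered] = true;
  std::vector<bool> alive(ns, true);

  const double dx_ = direction[0], dy_ = direction[1], dz_ = direction[2];
  double s0 = 0.0;  // initial projection of steered bead on the pulling axis
  if (steered >= 0) s0 = x[steered]*dx_ + y[steered]*dy_ + z[steered]*dz_;

  const double noise = std::sqrt(2.0 * kBT * dt / gamma);
  const int n_samples = n_steps / sample_every + 1;
  NumericMatrix out_xyz(n_samples, nb * 3);
  NumericVector out_t(n_samples), out_force(n_samples),
                out_dummy(n_samples), out_steered(n_samples);
  std::vector<double> fx(nb), fy(nb), fz(nb);

  int sample = 0, trigger_step = -1, steps_done = 0;
  bool triggered = false;

  RNGScope scope;

  for (int step = 0; step <= n_steps; ++step) {
    // forces
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    for (int s = 0; s < ns; ++s) {
      if (!alive[s]) continue;
      const int i = spring_ij(s,0), j = spring_ij(s,1);
      const double ddx = x[j]-x[i], ddy = y[j]-y[i], ddz = z[j]-z[i];
      const double r = std::sqrt(ddx*ddx + ddy*ddy + ddz*ddz);
      if (r < 1e-12) continue;
      if (break_factor > 0 && spring_breakable[s] && r > break_factor * spring_r0[s]) {
        alive[s] = false;
        continue;
      }
      const double f = spring_k[s] * (r - spring_r0[s]) / r;
      fx[i] += f*ddx; fy[i] += f*ddy; fz[i] += f*ddz;
      fx[j] -= f*ddx; fy[j] -= f*ddy; fz[j] -= f*ddz;
    }

    // pulling force on the steered bead (signed projection along direction)
    double t = step * dt, fpull = 0.0, dummy = NA_REAL, sproj = NA_REAL;
    if (steered >= 0) {
      sproj = x[steered]*dx_ + y[steered]*dy_ + z[steered]*dz_;
      if (load_mode == 1) {
        dummy = s0 + v_pull * t;
        fpull = k_spring * (dummy - sproj);
      } else if (load_mode == 2) {
        fpull = clamp_force;
      }
      fx[steered] += fpull * dx_;
      fy[steered] += fpull * dy_;
      fz[steered] += fpull * dz_;
    }

    if (step % sample_every == 0 && sample < n_samples) {
      for (int i = 0; i < nb; ++i) {
        out_xyz(sample, i)        = x[i];
        out_xyz(sample, nb + i)   = y[i];
        out_xyz(sample, 2*nb + i) = z[i];
      }
      out_t[sample] = t;
      out_force[sample] = fpull;
      out_dummy[sample] = dummy;
      out_steered[sample] = sproj;
      ++sample;
    }

    steps_done = step;
    if (stop_at_force && load_mode == 1 && fpull >= stop_force) {
      triggered = true;
      trigger_step = step;
      break;
    }
    if (step == n_steps) break;

    // overdamped update
    for (int i = 0; i < nb; ++i) {
      if (is_fixed[i]) continue;
      x[i] += fx[i] / gamma * dt + noise * R::norm_rand();
      y[i] += fy[i] / gamma * dt + noise * R::norm_rand();
      z[i] += fz[i] / gamma * dt + noise * R::norm_rand();
    }
  }

  NumericMatrix final_xyz(nb, 3);
  for (int i = 0; i < nb; ++i) {
    final_xyz(i,0) = x[i]; final_xyz(i,1) = y[i]; final_xyz(i,2) = z[i];
  }
  LogicalVector alive_out(ns);
  for (int s = 0; s < ns; ++s) alive_out[s] = alive[s];

  return List::create(_["xyz"] = out_xyz,
                      _["times"] = out_t,
                      _["force"] = out_force,
                      _["dummy"] = out_dummy,
                      _["steered_proj"] = out_steered,
                      _["n_sampled"] = sample,
                      _["steps_done"] = steps_done,
                      _["triggered"] = triggered,
                      _["trigger_step"] = trigger_step,
                      _["final_xyz"] = final_xyz,
                      _["spring_alive"] = alive_out);
}
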