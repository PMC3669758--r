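#include <Rcpp.h>
using namespace Rcpp;

// Damped mass-spring relaxation with position Verlet, run to kinetic-energy
// convergence. Semantics mirror the R-level compute_forces()/integrate_step()
// pair exactly (a test asserts agreement): Hooke springs (j = 0 denotes the
// fixed virtual center node), viscous damping -c v with the Verlet velocity
// estimate (x - x_prev)/dt, pinned nodes position-constrained and moved
// linearly from their start to their target over the first schedule_steps
// steps, then held. Convergence is declared when total kinetic energy drops
// below n * ke_tol_per_node after the schedule has completed.
// [[Rcpp::export(name = ".relax_verlet")]]
List relax_verlet(NumericMatrix positions,
                  IntegerVector spring_i, IntegerVector spring_j,
                  NumericVector L0, NumericVector K,
                  NumericVector center,
                  double mass, double damping, double dt,
                  IntegerVector pinned,
                  NumericMatrix pin_from, NumericMatrix pin_to,
                  int schedule_steps, int max_steps,
                  double ke_tol_per_node) {
  const int n = positions.nrow();
  const int ns = spring_i.size();
  std::vector<double> x(3 * n), xprev(3 * n), f(3 * n);
  for (int v = 0; v < n; ++v)
    for (int d = 0; d < 3; ++d)
      x[3 * v + d] = xprev[3 * v + d] = positions(v, d);

  std::vector<char> is_pinned(n, 0);
  for (int p = 0; p < pinned.size(); ++p) is_pinned[pinned[p] - 1] = 1;

  const double dt2 = dt * dt;
  double ke = R_PosInf;
  int step = 0;
  bool first = true;

  for (step = 1; step <= max_steps; ++step) {
    // schedule pinned positions
    if (pinned.size() > 0) {
      double t = schedule_steps > 0 ?
        std::min(1.0, (double)step / (double)schedule_steps) : 1.0;
      for (int p = 0; p < pinned.size(); ++p) {
        int v = pinned[p] - 1;
        for (int d = 0; d < 3; ++d) {
          double tgt = pin_from(p, d) + t * (pin_to(p, d) - pin_from(p, d));
          x[3 * v + d] = tgt;
          xprev[3 * v + d] = tgt;
        }
      }
    }
    // spring forces
    std::fill(f.begin(), f.end(), 0.0);
    for (int s = 0; s < ns; ++s) {
      int i = spring_i[s] - 1;
      int j = spring_j[s] - 1;  // -1 => virtual center
      double dx[3];
      for (int d = 0; d < 3; ++d)
        dx[d] = x[3 * i + d] - (j >= 0 ? x[3 * j + d] : center[d]);
      double len = std::sqrt(dx[0]*dx[0] + dx[1]*dx[1] + dx[2]*dx[2]);
      double safe = len > 1e-300 ? len : 1e-300;
      double fm = -K[s] * (len - L0[s]) / safe;
      for (int d = 0; d < 3; ++d) {
        double fd = fm * dx[d];
        f[3 * i + d] += fd;
        if (j >= 0) f[3 * j + d] -= fd;
      }
    }
    // damping with Verlet velocity estimate + integration
    ke = 0.0;
    for (int v = 0; v < n; ++v) {
      if (is_pinned[v]) continue;
      for (int d = 0; d < 3; ++d) {
        double vest = (x[3 * v + d] - xprev[3 * v + d]) / dt;
        double acc = (f[3 * v + d] - damping * vest) / mass;
        double xn = first ? x[3 * v + d] + 0.5 * acc * dt2
                          : 2.0 * x[3 * v + d] - xprev[3 * v + d] + acc * dt2;
        double vel = (xn - xprev[3 * v + d]) / (2.0 * dt);
        ke += 0.5 * mass * vel * vel;
        xprev[3 * v + d] = x[3 * v + d];
        x[3 * v + d] = xn;
      }
      if (!R_finite(x[3 * v])) stop("integration diverged; reduce dt");
    }
    first = false;
    if (step > schedule_steps && ke < n * ke_tol_per_node) break;
  }

  NumericMatrix out(n, 3);
  for (int v = 0; v < n; ++v)
    for (int d = 0; d < 3; ++d) out(v, d) = x[3 * v + d];
  return List::create(_["positions"] = out,
                      _["steps"] = std::min(step, max_steps),
                      _["kinetic_energy"] = ke,
                      _["converged"] = ke < n * ke_tol_per_node);
}
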