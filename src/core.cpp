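#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Nearest-surface distance and inward normal for a point strictly inside
// an axis-aligned ellipsoid of revolution (semi-axes lx, ly = lz).
// Mirrors the pure-R reference in R/eggshell.R: axial symmetry reduces the
// problem to the (x, t) half-plane, t = sqrt(y^2 + z^2); the perpendicular
// foot parameter mu solves a convex decreasing 1-D equation by Newton
// iteration from mu = 0 with a bisection guard.
static void shell_foot(double lx, double ly, const double* p,
                       double* a_out, double* n_out) {
  double x = p[0];
  double t2 = p[1] * p[1] + p[2] * p[2];
  double t = std::sqrt(t2);
  if (lx == ly) {                       // sphere
    double r = std::sqrt(x * x + t2);
    if (r == 0.0) {
      *a_out = lx; n_out[0] = 1.0; n_out[1] = 0.0; n_out[2] = 0.0;
      return;
    }
    *a_out = lx - r;
    n_out[0] = -p[0] / r; n_out[1] = -p[1] / r; n_out[2] = -p[2] / r;
    return;
  }
  if (t < 1e-12 * ly) {                 // on the major axis
    double xc = (lx * lx - ly * ly) / lx;
    if (std::fabs(x) >= xc) {
      double s = (x >= 0) ? 1.0 : -1.0;
      *a_out = lx - std::fabs(x);
      n_out[0] = -s; n_out[1] = 0.0; n_out[2] = 0.0;
      return;
    }
    double xf = lx * lx * x / (lx * lx - ly * ly);
    double tf = ly * std::sqrt(1.0 - xf * xf / (lx * lx));
    double a = std::sqrt((x - xf) * (x - xf) + tf * tf);
    *a_out = a;
    n_out[0] = (x - xf) / a; n_out[1] = -tf / a; n_out[2] = 0.0;
    return;
  }
  double px2 = (lx * x) * (lx * x);
  double pt2 = (ly * t) * (ly * t);
  double mu = 0.0, lo = -ly * ly;
  for (int k = 0; k < 200; ++k) {
    double qa = lx * lx + mu, qb = ly * ly + mu;
    double f = px2 / (qa * qa) + pt2 / (qb * qb) - 1.0;
    if (std::fabs(f) < 1e-12) break;
    double df = -2.0 * (px2 / (qa * qa * qa) + pt2 / (qb * qb * qb));
    double mu_new = mu - f / df;
    if (mu_new <= lo) mu_new = 0.5 * (mu + lo);
    if (std::fabs(mu_new - mu) < 1e-12 * ly * ly) { mu = mu_new; break; }
    mu = mu_new;
  }
  double xf = lx * lx * x / (lx * lx + mu);
  double tf = ly * ly * t / (ly * ly + mu);
  double fx = xf, fy = tf * p[1] / t, fz = tf * p[2] / t;
  double dx = p[0] - fx, dy = p[1] - fy, dz = p[2] - fz;
  double a = std::sqrt(dx * dx + dy * dy + dz * dz);
  *a_out = a;
  n_out[0] = dx / a; n_out[1] = dy / a; n_out[2] = dz / a;
}

// Signed magnitude of the pairwise force (positive = repulsion); the
// piecewise-linear law of R/forces.R.
static double pair_mag(double d, double Ri, double Rj, double alpha,
                       double F0) {
  double rsum = Ri + Rj;
  double rmin = (Ri < Rj) ? Ri : Rj;
  double dzero = alpha * rsum;
  double mid = 0.5 * (1.0 + alpha) * rsum;
  if (d <= rmin) return F0;
  if (d <= mid) return F0 * (dzero - d) / (dzero - rmin);
  if (d <= rsum) {
    double fmid = F0 * (dzero - mid) / (dzero - rmin);
    return fmid * (rsum - d) / (rsum - mid);
  }
  return 0.0;
}

// Euler-Maruyama integration of n_steps with fixed cell roster.
// Consumes 3 * n normal draws per step from the R RNG (cell-major, xyz)
// when noise_sd > 0, matching the R reference stepper exactly.
// [[Rcpp::export]]
NumericMatrix integrate_segment_cpp(NumericMatrix pos, NumericVector radius,
                                    NumericMatrix alpha, double lx, double ly,
                                    double F0, double shell_gain,
                                    double noise_sd, double dt, int n_steps) {
  int n = pos.nrow();
  NumericMatrix cur(clone(pos));
  std::vector<double> force(3 * n);
  for (int s = 0; s < n_steps; ++s) {
    std::fill(force.begin(), force.end(), 0.0);
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = cur(j, 0) - cur(i, 0);
        double dy = cur(j, 1) - cur(i, 1);
        double dz = cur(j, 2) - cur(i, 2);
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (d == 0.0) stop("coincident cell centres");
        double mag = pair_mag(d, radius[i], radius[j], alpha(i, j), F0);
        if (mag != 0.0) {
          double fx = -mag * dx / d, fy = -mag * dy / d, fz = -mag * dz / d;
          force[3 * i] += fx; force[3 * i + 1] += fy; force[3 * i + 2] += fz;
          force[3 * j] -= fx; force[3 * j + 1] -= fy; force[3 * j + 2] -= fz;
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      double p[3] = {cur(i, 0), cur(i, 1), cur(i, 2)};
      // cheap lower bound on the shell distance skips the foot solve when
      // the cell cannot touch the shell: a >= (1 - rho) * ly
      double rho = std::sqrt(p[0] * p[0] / (lx * lx) +
                             (p[1] * p[1] + p[2] * p[2]) / (ly * ly));
      if ((1.0 - rho) * ly <= radius[i]) {
        double a, nrm[3];
        shell_foot(lx, ly, p, &a, nrm);
        if (a <= radius[i]) {
          double k = shell_gain * (radius[i] - a) / radius[i];
          force[3 * i] += k * nrm[0];
          force[3 * i + 1] += k * nrm[1];
          force[3 * i + 2] += k * nrm[2];
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      for (int c = 0; c < 3; ++c)
        cur(i, c) += force[3 * i + c] * dt;
    }
    if (noise_sd > 0.0) {
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c)
          cur(i, c) += noise_sd * norm_rand();
    }
    for (int i = 0; i < n; ++i) {       // clamp strictly inside the shell
      double rho = std::sqrt(cur(i, 0) * cur(i, 0) / (lx * lx) +
                             (cur(i, 1) * cur(i, 1) +
                              cur(i, 2) * cur(i, 2)) / (ly * ly));
      if (rho >= 0.99) {
        double f = 0.99 / rho;
        cur(i, 0) *= f; cur(i, 1) *= f; cur(i, 2) *= f;
      }
    }
  }
  return cur;
}
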