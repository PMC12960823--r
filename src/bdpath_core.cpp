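#include <Rcpp.h>
using namespace Rcpp;

// Pairs (i < j, 1-based) with distance strictly below cutoff.
// Quadratic scan with coordinate pre-rejection; fast enough for the system
// sizes this package targets (tens of thousands of beads).
// [[Rcpp::export]]
List cpp_pairs_within_cutoff(NumericMatrix xyz, double cutoff) {
  const int n = xyz.nrow();
  const double rc2 = cutoff * cutoff;
  std::vector<int> vi, vj;
  std::vector<double> vd;
  for (int a = 0; a < n; ++a) {
    const double xa = xyz(a, 0), ya = xyz(a, 1), za = xyz(a, 2);
    for (int b = a + 1; b < n; ++b) {
      const double dx = xyz(b, 0) - xa;
      if (dx > cutoff || dx < -cutoff) continue;
      const double dy = xyz(b, 1) - ya;
      if (dy > cutoff || dy < -cutoff) continue;
      const double dz = xyz(b, 2) - za;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < rc2) {
        vi.push_back(a + 1);
        vj.push_back(b + 1);
        vd.push_back(std::sqrt(d2));
      }
    }
  }
  return List::create(_["i"] = wrap(vi), _["j"] = wrap(vj),
                      _["d"] = wrap(vd));
}

// Overdamped Brownian segment: nsteps of
//   r += mu * F(r) + noise_sd * eta,   eta ~ N(0, 1) per coordinate,
// with harmonic pair forces over the spring list. Noise is drawn from R's
// RNG as one rnorm(3N) block per step in x-column, y-column, z-column order,
// matching the layout matrix(rnorm(3*N), N, 3) used by the pure-R stepper,
// so both engines produce bit-identical trajectories at a fixed seed.
// [[Rcpp::export]]
NumericMatrix cpp_bd_segment(NumericMatrix xyz, IntegerVector pi,
                             IntegerVector pj, NumericVector pk,
                             NumericVector pd0, double mu, double noise_sd,
                             int nsteps) {
  const int n = xyz.nrow();
  const int np = pi.size();
  NumericMatrix pos = clone(xyz);
  std::vector<double> fx(n), fy(n), fz(n);
  for (int s = 0; s < nsteps; ++s) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    for (int p = 0; p < np; ++p) {
      const int a = pi[p] - 1, b = pj[p] - 1;
      const double dx = pos(b, 0) - pos(a, 0);
      const double dy = pos(b, 1) - pos(a, 1);
      const double dz = pos(b, 2) - pos(a, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d <= 0.0)
        stop("coincident beads in pair (%d,%d)", pi[p], pj[p]);
      const double c = pk[p] * (d - pd0[p]) / d;
      fx[a] += c * dx; fy[a] += c * dy; fz[a] += c * dz;
      fx[b] -= c * dx; fy[b] -= c * dy; fz[b] -= c * dz;
    }
    NumericVector eta = rnorm(3 * n);
    for (int a = 0; a < n; ++a) {
      pos(a, 0) += mu * fx[a] + noise_sd * eta[a];
      pos(a, 1) += mu * fy[a] + noise_sd * eta[n + a];
      pos(a, 2) += mu * fz[a] + noise_sd * eta[2 * n + a];
      if (!std::isfinite(pos(a, 0)) || !std::isfinite(pos(a, 1)) ||
          !std::isfinite(pos(a, 2)))
        stop("non-finite position at bead %d", a + 1);
    }
  }
  return pos;
}

static void harmonic_forces(const NumericMatrix& pos, const IntegerVector& pi,
                            const IntegerVector& pj, const NumericVector& pk,
                            const NumericVector& pd0, std::vector<double>& fx,
                            std::vector<double>& fy, std::vector<double>& fz) {
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  const int np = pi.size();
  for (int p = 0; p < np; ++p) {
    const int a = pi[p] - 1, b = pj[p] - 1;
    const double dx = pos(b, 0) - pos(a, 0);
    const double dy = pos(b, 1) - pos(a, 1);
    const double dz = pos(b, 2) - pos(a, 2);
    const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d <= 0.0)
      stop("coincident beads in pair (%d,%d)", pi[p], pj[p]);
    const double c = pk[p] * (d - pd0[p]) / d;
    fx[a] += c * dx; fy[a] += c * dy; fz[a] += c * dz;
    fx[b] -= c * dx; fy[b] -= c * dy; fz[b] -= c * dz;
  }
}

static double gamma_of(const NumericMatrix& xyz, const IntegerVector& ti,
                       const IntegerVector& tj, const NumericVector& td) {
  const int np = ti.size();
  double g = 0.0;
  for (int p = 0; p < np; ++p) {
    const int a = ti[p] - 1, b = tj[p] - 1;
    const double dx = xyz(b, 0) - xyz(a, 0);
    const double dy = xyz(b, 1) - xyz(a, 1);
    const double dz = xyz(b, 2) - xyz(a, 2);
    const double diff = std::sqrt(dx * dx + dy * dy + dz * dz) - td[p];
    g += diff * diff;
  }
  return g;
}

// Importance-sampling inner loop: repeat { k BD steps from the last accepted
// coordinates; evaluate Gamma; accept on strict decrease } until one
// acceptance or `max_trials` checkpoints. Per-checkpoint Gamma values are
// returned for logging. Noise comes from R's RNG, one rnorm(3N) block per
// step (rejected segments consume their draws, matching the pure-R engine).
// [[Rcpp::export]]
List cpp_run_until_accept(NumericMatrix xyz, IntegerVector pi,
                          IntegerVector pj, NumericVector pk,
                          NumericVector pd0, IntegerVector ti,
                          IntegerVector tj, NumericVector td, double mu,
                          double noise_sd, int k, double gamma_prev,
                          int max_trials) {
  const int n = xyz.nrow();
  NumericMatrix base = clone(xyz);
  NumericMatrix prop(n, 3);
  std::vector<double> fx(n), fy(n), fz(n);
  std::vector<double> gammas;
  gammas.reserve(64);
  bool accepted = false;
  int trials = 0;
  double gamma_new = gamma_prev;
  while (trials < max_trials) {
    ++trials;
    for (int a = 0; a < n; ++a) {
      prop(a, 0) = base(a, 0); prop(a, 1) = base(a, 1);
      prop(a, 2) = base(a, 2);
    }
    for (int s = 0; s < k; ++s) {
      harmonic_forces(prop, pi, pj, pk, pd0, fx, fy, fz);
      NumericVector eta = rnorm(3 * n);
      for (int a = 0; a < n; ++a) {
        prop(a, 0) += mu * fx[a] + noise_sd * eta[a];
        prop(a, 1) += mu * fy[a] + noise_sd * eta[n + a];
        prop(a, 2) += mu * fz[a] + noise_sd * eta[2 * n + a];
        if (!std::isfinite(prop(a, 0)) || !std::isfinite(prop(a, 1)) ||
            !std::isfinite(prop(a, 2)))
          stop("non-finite position at bead %d", a + 1);
      }
    }
    const double g = gamma_of(prop, ti, tj, td);
    gammas.push_back(g);
    if (g < gamma_prev) {
      accepted = true;
      gamma_new = g;
      break;
    }
  }
  return List::create(_["positions"] = accepted ? prop : base,
                      _["accepted"] = accepted, _["trials"] = trials,
                      _["gammas"] = wrap(gammas),
                      _["gamma_new"] = gamma_new);
}

// Squared-pairwise-distance progress variable over the biased pair set:
// sum over pairs of (d_current - d_target)^2.
// [[Rcpp::export]]
double cpp_progress_variable(NumericMatrix xyz, IntegerVector pi,
                             IntegerVector pj, NumericVector dt) {
  const int np = pi.size();
  double g = 0.0;
  for (int p = 0; p < np; ++p) {
    const int a = pi[p] - 1, b = pj[p] - 1;
    const double dx = xyz(b, 0) - xyz(a, 0);
    const double dy = xyz(b, 1) - xyz(a, 1);
    const double dz = xyz(b, 2) - xyz(a, 2);
    const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    const double diff = d - dt[p];
    g += diff * diff;
  }
  return g;
}
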