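// Langevin dynamics of a 1-D chain of coupled oscillators with screened
// Coulomb repulsion between charged sites. BAOAB splitting; Gaussian kicks
// from an explicit Box-Muller transform over mt19937_64 uniforms so a seed
// fixes the trajectory bit-for-bit on a given platform.

#include <Rcpp.h>
#include <random>
#include <cmath>

using namespace Rcpp;

namespace {

struct Gauss {
  std::mt19937_64 eng;
  bool have_spare = false;
  double spare = 0.0;
  explicit Gauss(uint64_t seed) : eng(seed) {}
  double unif() {
    // 53-bit uniform in (0, 1]
    return ((eng() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
  double operator()() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

// forces: site springs (per-site stiffness, optionally a Gaussian well),
// harmonic nearest-neighbour links, screened Coulomb between charged sites
void forces(const std::vector<double>& x, std::vector<double>& f,
            const NumericVector& k_site, double x_scale, int site_form,
            double k_link, const NumericVector& q, double d0,
            double lambda, double kc) {
  const int n = x.size();
  for (int i = 0; i < n; ++i) {
    if (site_form == 1) {
      const double s = x[i] / x_scale;
      f[i] = -k_site[i] * x[i] * std::exp(-s * s);
    } else {
      f[i] = -k_site[i] * x[i];
    }
  }
  for (int i = 0; i + 1 < n; ++i) {
    const double du = x[i + 1] - x[i];
    const double fl = k_link * du;
    f[i] += fl;
    f[i + 1] -= fl;
  }
  for (int i = 0; i < n; ++i) {
    if (q[i] == 0.0) continue;
    for (int j = i + 1; j < n; ++j) {
      if (q[j] == 0.0) continue;
      double r = d0 * (j - i) + x[j] - x[i];
      if (r < 0.05 * d0) r = 0.05 * d0;
      const double expd = std::exp(-r / lambda);
      // -dV/dr with V = kc qi qj exp(-r/lambda)/r
      const double fr = kc * q[i] * q[j] * expd * (1.0 / (lambda * r) + 1.0 / (r * r));
      f[j] += fr;
      f[i] -= fr;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix langevin_chain(NumericVector x0, NumericVector v0,
                             NumericVector masses, NumericVector k_site,
                             double x_scale, int site_form, double k_link,
                             NumericVector charges, double d0, double lambda,
                             double kc, double friction, double kBT,
                             int steps, double dt, int record_every,
                             double seed) {
  const int n = x0.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> f(n, 0.0);
  Gauss g(static_cast<uint64_t>(seed));

  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  const int n_rec = steps / record_every;
  NumericMatrix out(n_rec, n);

  forces(x, f, k_site, x_scale, site_form, k_link, charges, d0, lambda, kc);
  int rec = 0;
  for (int s = 1; s <= steps; ++s) {
    for (int i = 0; i < n; ++i) v[i] += 0.5 * dt * f[i] / masses[i];
    for (int i = 0; i < n; ++i) x[i] += 0.5 * dt * v[i];
    for (int i = 0; i < n; ++i) {
      const double sigma = std::sqrt(kBT / masses[i]);
      v[i] = c1 * v[i] + c2 * sigma * (kBT > 0.0 ? g() : 0.0);
    }
    for (int i = 0; i < n; ++i) x[i] += 0.5 * dt * v[i];
    forces(x, f, k_site, x_scale, site_form, k_link, charges, d0, lambda, kc);
    for (int i = 0; i < n; ++i) v[i] += 0.5 * dt * f[i] / masses[i];
    if (s % record_every == 0 && rec < n_rec) {
      for (int i = 0; i < n; ++i) out(rec, i) = x[i];
      ++rec;
    }
  }
  return out;
}
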