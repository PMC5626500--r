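#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

// Noisy leaky integrate-and-fire rate coder for mossy-fiber spike trains.
// dV/dt = -(V - E)/tau + beta*mu(t) + sigma(t)*xi(t), with xi ~ N(0,1)
// redrawn every `noise_update_ms` and held constant in between.
// mu = g*N*nu; sigma = g*N*sqrt(nu) ("gN_sqrt_nu", fluctuation-driven
// default) or g*sqrt(N*nu) ("g_sqrt_Nnu"). nu is supplied per (group, ms).
//
// [[Rcpp::export]]
List cpp_mf_lif(NumericMatrix nu, IntegerVector group_of_fiber, List p,
                double dt_ms, double seed) {
  const double tau = as<double>(p["tau_ms"]);
  const double E = as<double>(p["e_mv"]);
  const double th = as<double>(p["threshold_mv"]);
  const double refrac = as<double>(p["refractory_ms"]);
  const double N = as<double>(p["n"]);
  const double g = as<double>(p["g_uv_per_ms"]) * 1e-3;  // mV/ms
  const double beta = as<double>(p["beta"]);
  const double noise_upd = as<double>(p["noise_update_ms"]);
  const std::string sf = as<std::string>(p["sigma_form"]);
  // "gN_sqrt_nu" (default), "g_sqrt_Nnu" (shot-noise reading), or "none"
  const int sform = sf == "gN_sqrt_nu" ? 0 : (sf == "g_sqrt_Nnu" ? 1 : 2);

  const int n_groups = nu.nrow();
  const int n_ms = nu.ncol();
  const int n_fib = group_of_fiber.size();
  const int steps_per_ms = (int)std::round(1.0 / dt_ms);
  const int noise_steps = std::max(1, (int)std::round(noise_upd / dt_ms));
  const int n_steps = n_ms * steps_per_ms;

  // per-(group, ms) drift and noise amplitude
  std::vector<double> drift((size_t)n_groups * n_ms), sig((size_t)n_groups * n_ms);
  for (int gi = 0; gi < n_groups; ++gi)
    for (int m = 0; m < n_ms; ++m) {
      double v = nu(gi, m);
      if (v < 0) v = 0;
      drift[(size_t)gi * n_ms + m] = beta * g * N * v;
      sig[(size_t)gi * n_ms + m] =
          sform == 0 ? g * N * std::sqrt(v)
                     : (sform == 1 ? g * std::sqrt(N * v) : 0.0);
    }

  std::vector<int> out_f;
  std::vector<double> out_t;
  for (int f = 0; f < n_fib; ++f) {
    Rng rng(splitmix64((uint64_t)seed + 0x11D0ULL) ^ (uint64_t)(f + 1));
    const size_t base = (size_t)(group_of_fiber[f] - 1) * n_ms;
    double V = E, xi = 0, refleft = 0;
    for (int s = 0; s < n_steps; ++s) {
      if (s % noise_steps == 0) xi = rng.rnorm();
      if (refleft > 0) { refleft -= dt_ms; if (refleft <= 0) V = E; continue; }
      int m = s / steps_per_ms;
      V += dt_ms * (-(V - E) / tau + drift[base + m] + sig[base + m] * xi);
      if (V >= th) {
        out_f.push_back(f + 1);
        out_t.push_back((s + 1) * dt_ms);
        refleft = refrac;
      }
    }
  }
  return List::create(_["fiber"] = wrap(out_f), _["t_ms"] = wrap(out_t));
}
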