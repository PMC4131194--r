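#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of the exponential integrate-and-fire membrane
// equation
//   C dV/dt = -g_l (V - e_l) + g_l * delta_t * exp((V - v_t) / delta_t) + I(t)
// Units: V mV, I pA, C pF, g nS, t ms. delta_t == 0 selects the
// leaky-integrate-and-fire limit (hard threshold at v_t). A spike is emitted
// when V reaches v_peak (or v_t in the LIF limit): the sample is pinned to
// v_peak, V resets to v_reset and holds there for the refractory period.
// noise_sd adds white current noise (pA, scaled by 1/sqrt(dt)) via the R RNG.
// [[Rcpp::export]]
List eif_integrate(NumericVector I, double dt, double c_m, double g_l,
                   double e_l, double v_t, double delta_t, double v_reset,
                   double v_peak, double refractory, double v0,
                   double noise_sd) {
  const int n = I.size();
  NumericVector V(n);
  std::vector<double> spikes;
  double v = v0;
  int hold = 0;
  const int hold_n = (int)std::ceil(refractory / dt);
  const bool lif = (delta_t <= 0.0);
  const double thr = lif ? v_t : v_peak;
  for (int i = 0; i < n; ++i) {
    if (hold > 0) {
      --hold;
      v = v_reset;
      V[i] = v;
      continue;
    }
    double dv = -g_l * (v - e_l) + I[i];
    if (!lif) {
      double arg = (v - v_t) / delta_t;
      if (arg > 30.0) arg = 30.0;  // bounded: blow-up counts as a spike below
      dv += g_l * delta_t * std::exp(arg);
    }
    if (noise_sd > 0.0) dv += noise_sd / std::sqrt(dt) * norm_rand();
    v += dt * dv / c_m;
    if (!R_finite(v))
      stop("integration blew up without spike detection: step too large");
    if (v >= thr) {
      spikes.push_back(i * dt);
      V[i] = v_peak;
      v = v_reset;
      hold = hold_n;
    } else {
      V[i] = v;
    }
  }
  return List::create(_["voltage"] = V, _["spike_times_ms"] = wrap(spikes));
}
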