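// Leaky integrate-and-fire E-I network with instantaneous synapses.
//
// Forward-Euler update exactly as printed for the model:
//   V = V + dt * (-(V - E) + I * R) / tau,   tau = R * C.
// On threshold crossing the unit registers a spike, resets to V_reset, and
// its postsynaptic partners receive an instantaneous PSP jump (delivered at
// the next step, i.e., with one integration-step delay; dt = 0.5 ms). PSP
// magnitudes are frozen per ordered pair (drawn uniformly in [0, PSP] in R).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List sim_lif_cpp(NumericVector I0,        // basal drive per cell (nA)
                 NumericVector gain,      // stimulus gain per cell
                 NumericVector stim,      // on the integration grid (may be empty)
                 NumericMatrix Wt,        // n_post x n_pre PSP jumps (mV)
                 NumericVector v_init,
                 double dt, int n_steps,
                 double R, double tau, double E,
                 double v_thresh, double v_reset) {
  const int n = I0.size();
  std::vector<double> v(v_init.begin(), v_init.end());
  std::vector<double> psp_pending(n, 0.0), psp_next(n, 0.0);
  std::vector<int> spike_cell;
  std::vector<double> spike_time;
  const bool has_stim = stim.size() > 0;

  for (int step = 0; step < n_steps; ++step) {
    double st = has_stim ? stim[step] : 0.0;
    for (int i = 0; i < n; ++i) {
      double I = I0[i] + gain[i] * st;
      v[i] += dt * (-(v[i] - E) + I * R) / tau;
      v[i] += psp_pending[i];
      psp_pending[i] = 0.0;
    }
    for (int i = 0; i < n; ++i) {
      if (v[i] >= v_thresh) {
        spike_cell.push_back(i + 1);
        spike_time.push_back((step + 1) * dt / 1000.0);
        v[i] = v_reset;
        const double* col = &Wt(0, i);
        for (int j = 0; j < n; ++j) psp_next[j] += col[j];
      }
    }
    for (int i = 0; i < n; ++i) {
      psp_pending[i] += psp_next[i];
      psp_next[i] = 0.0;
    }
  }
  return List::create(_["spike_cell"] = wrap(spike_cell),
                      _["spike_time"] = wrap(spike_time));
}
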