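// Leaky integrate-and-fire predictive-coding network, forward Euler at dt.
//
// Neurons are indexed stream-major: id = stream * 6 + role with roles
// 0 = I (sensory input), 1 = P (prediction), 2 = PE+, 3 = PE-,
// 4 = I+ (interneuron gating PE+), 5 = I- (interneuron gating PE-).
// Synapses carry an exponentially decaying current that jumps by w on each
// delivered (delayed) presynaptic spike. Analog drives: I_stim to I and
// I_pred = P_strength * stim_amplitude to P for the first stim_duration ms
// of every trial. P_strength (per stream, clipped to [0,1]) moves by
// +p_increment per PE+ spike and -p_decrement per PE- spike of its stream.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List lif_simulate_cpp(IntegerVector labels,      // per item: 0=A, 1=B, 2=O
                      double soa, double dt,
                      double tau_m, double rm_mohm, double v_thresh,
                      double v_reset, double t_ref,
                      int n_streams,
                      NumericMatrix rf_gain,     // n_streams x 2 (A, B)
                      double stim_amplitude, double stim_duration,
                      double s_gain_a, double s_gain_b,
                      double p_increment, double p_decrement,
                      IntegerVector syn_pre, IntegerVector syn_post,
                      NumericVector syn_w, NumericVector syn_delay,
                      NumericVector syn_tau, IntegerVector syn_inh,
                      int record_every, double p_init = 0.0) {
  const int n_items = labels.size();
  const int n_neur = n_streams * 6;
  const int n_syn = syn_pre.size();
  const int steps_per_trial = (int)(soa / dt + 0.5);
  const long n_steps = (long)steps_per_trial * n_items;
  const int stim_steps = (int)(stim_duration / dt + 0.5);
  const double rm = rm_mohm * 1000.0;  // mV per uA

  std::vector<double> V(n_neur, v_reset);
  std::vector<double> refrac_until(n_neur, -1.0);
  std::vector<std::vector<double>> spikes(n_neur);
  std::vector<double> p_strength(n_streams, p_init);

  // per-synapse state: current + delay ring buffer of pending weight
  std::vector<double> Isyn(n_syn, 0.0);
  std::vector<double> decay(n_syn);
  std::vector<int> dsteps(n_syn);
  int max_d = 1;
  for (int s = 0; s < n_syn; ++s) {
    decay[s] = 1.0 - dt / syn_tau[s];
    dsteps[s] = (int)(syn_delay[s] / dt + 0.5);
    if (dsteps[s] < 1) dsteps[s] = 1;
    if (dsteps[s] + 1 > max_d) max_d = dsteps[s] + 1;
  }
  // shared ring: pending[slot][syn]
  std::vector<std::vector<double>> pending(max_d, std::vector<double>(n_syn, 0.0));
  // outgoing synapse index per neuron
  std::vector<std::vector<int>> outgoing(n_neur);
  for (int s = 0; s < n_syn; ++s) outgoing[syn_pre[s]].push_back(s);

  // p_strength trace
  const long n_rec = n_steps / record_every + 1;
  NumericMatrix p_trace(n_rec, n_streams);
  NumericVector p_times(n_rec);
  long irec = 0;
  for (int k = 0; k < n_streams; ++k) p_trace(0, k) = p_init;
  p_times[0] = 0.0;
  irec = 1;

  std::vector<double> Iexc(n_neur), Iinh(n_neur);

  for (long n = 0; n < n_steps; ++n) {
    const double t = n * dt;
    const int slot = (int)(n % max_d);
    const int item = (int)(n / steps_per_trial);
    const int within = (int)(n % steps_per_trial);
    const int lab = labels[item];

    // deliver pending spikes scheduled for this step
    for (int s = 0; s < n_syn; ++s) {
      if (pending[slot][s] != 0.0) {
        Isyn[s] += pending[slot][s];
        pending[slot][s] = 0.0;
      }
    }

    // sum synaptic currents per neuron
    std::fill(Iexc.begin(), Iexc.end(), 0.0);
    std::fill(Iinh.begin(), Iinh.end(), 0.0);
    for (int s = 0; s < n_syn; ++s) {
      if (syn_inh[s]) Iinh[syn_post[s]] += Isyn[s];
      else            Iexc[syn_post[s]] += Isyn[s];
    }

    // integrate and detect spikes
    for (int i = 0; i < n_neur; ++i) {
      if (t < refrac_until[i]) { V[i] = v_reset; continue; }
      double Istim = 0.0, Ipred = 0.0;
      if (within < stim_steps) {
        const int stream = i / 6, role = i % 6;
        if (role == 0 && lab != 2) {
          const double adapt = (lab == 0) ? s_gain_a : s_gain_b;
          Istim = rf_gain(stream, lab) * stim_amplitude * adapt;
        } else if (role == 1) {
          Ipred = p_strength[stream] * stim_amplitude;
        }
      }
      const double Itot = Iexc[i] - Iinh[i] + Ipred + Istim;
      V[i] += dt / tau_m * (-V[i] + rm * Itot);
      if (!R_finite(V[i]))
        stop("non-finite membrane potential at t = %f ms (neuron %d)", t, i);
      if (V[i] > v_thresh) {
        const double ts = t + dt;
        spikes[i].push_back(ts);
        V[i] = v_reset;
        refrac_until[i] = ts + t_ref;
        for (size_t k = 0; k < outgoing[i].size(); ++k) {
          const int s = outgoing[i][k];
          pending[(n + dsteps[s]) % max_d][s] += syn_w[s];
        }
        const int stream = i / 6, role = i % 6;
        if (role == 2) {
          p_strength[stream] += p_increment;
          if (p_strength[stream] > 1.0) p_strength[stream] = 1.0;
        } else if (role == 3) {
          p_strength[stream] -= p_decrement;
          if (p_strength[stream] < 0.0) p_strength[stream] = 0.0;
        }
      }
    }

    // decay synaptic currents
    for (int s = 0; s < n_syn; ++s) Isyn[s] *= decay[s];

    if ((n + 1) % record_every == 0 && irec < n_rec) {
      for (int k = 0; k < n_streams; ++k) p_trace(irec, k) = p_strength[k];
      p_times[irec] = (n + 1) * dt;
      ++irec;
    }
  }

  List spk(n_neur);
  for (int i = 0; i < n_neur; ++i) spk[i] = NumericVector(spikes[i].begin(), spikes[i].end());
  return List::create(_["spikes"] = spk,
                      _["p_trace"] = p_trace,
                      _["p_times"] = p_times,
                      _["p_final"] = NumericVector(p_strength.begin(), p_strength.end()));
}
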