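#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Forward-Euler integration of a conductance-based LIF motor-neuron pool,
// optionally coupled to a layer of Renshaw interneurons.
//
// Units: potentials mV, conductances mS, currents uA (mS*mV), time s,
// capacitance mS*s. Membrane equation per motor neuron:
//   C dv/dt = -v/R + max(ge*S*(Ee - v) - Irheo, 0) + gi*S*(Ei - v)
// so excitation depolarizes toward Ee, inhibition toward Ei, the leak decays
// to the 0 mV rest, and the rheobase offset gates the excitatory current.
// After a threshold crossing the potential is reset and clamped to 0 mV for
// the refractory period. Renshaw cells follow dv/dt = (I - v)/tau with
// instantaneous EPSP jumps from delayed motor-neuron spikes; their spikes
// deliver delayed, exponentially decaying inhibitory conductance to their
// target motor neurons. Both synaptic directions share the same conduction
// delay, implemented as circular buffers of integer steps.
//
// All stochastic inputs are precomputed in R and passed as matrices sampled
// at fs_input (zero-order hold), keeping this core fully deterministic.

// [[Rcpp::export]]
List simulate_lif_cpp(NumericVector R_mem, NumericVector C_mem,
                      NumericVector S_fac, NumericVector I_rheo,
                      NumericVector T_refr,
                      NumericMatrix gamma_e, NumericMatrix gamma_i,
                      double fs_input, double duration, double dt,
                      double e_excit, double e_inhib, double v_thresh,
                      Nullable<List> renshaw) {
  const int n = R_mem.size();
  const int n_steps = (int)std::round(duration / dt);
  const int t_in = gamma_e.ncol();
  if (gamma_e.nrow() != n || gamma_i.nrow() != n)
    stop("Input matrices must have one row per neuron.");

  std::vector<double> v(n, 0.0), refr_until(n, -1.0), g_ren(n, 0.0);
  std::vector<std::vector<double>> spikes(n);

  bool has_rc = renshaw.isNotNull();
  int m = 0, delay_steps = 1;
  double rc_tau = 0, rc_vth = 0, rc_trefr = 0, epsp = 0, ipsp = 0;
  double syn_decay = 1.0;
  NumericMatrix rc_noise;
  std::vector<std::vector<int>> adj_mn2rc, adj_rc2mn;
  std::vector<double> v_rc, rc_refr_until, epsp_now;
  std::vector<std::vector<double>> rc_spikes;
  // circular delay buffers indexed by step % delay_steps; slot k is read
  // (and zeroed) at the top of a step and refilled by spikes of that step,
  // so refills are delivered exactly delay_steps later
  std::vector<std::vector<double>> epsp_buf, ipsp_buf;

  if (has_rc) {
    List rc(renshaw);
    m = as<int>(rc["m"]);
    rc_tau = as<double>(rc["tau"]);
    rc_vth = as<double>(rc["v_thresh"]);
    rc_trefr = as<double>(rc["t_refr"]);
    epsp = as<double>(rc["epsp_mv"]);
    ipsp = as<double>(rc["ipsp_ms"]);
    double delay = as<double>(rc["delay"]);
    double tau_syn = as<double>(rc["tau_syn"]);
    rc_noise = as<NumericMatrix>(rc["noise"]);
    delay_steps = std::max(1, (int)std::round(delay / dt));
    syn_decay = std::exp(-dt / tau_syn);
    List a1 = rc["adj_mn2rc"], a2 = rc["adj_rc2mn"];
    adj_mn2rc.resize(n);
    for (int j = 0; j < n; ++j) {
      IntegerVector tgt = a1[j];
      adj_mn2rc[j].assign(tgt.begin(), tgt.end());
    }
    adj_rc2mn.resize(m);
    for (int c = 0; c < m; ++c) {
      IntegerVector tgt = a2[c];
      adj_rc2mn[c].assign(tgt.begin(), tgt.end());
    }
    v_rc.assign(m, 0.0);
    rc_refr_until.assign(m, -1.0);
    rc_spikes.resize(m);
    epsp_now.assign(m, 0.0);
    epsp_buf.assign(delay_steps, std::vector<double>(m, 0.0));
    ipsp_buf.assign(delay_steps, std::vector<double>(n, 0.0));
  }

  const double blowup = 10.0 * v_thresh;

  // hoisted raw pointers: identical arithmetic, no accessor overhead
  const double* R_p = REAL(R_mem);
  const double* C_p = REAL(C_mem);
  const double* S_p = REAL(S_fac);
  const double* Ir_p = REAL(I_rheo);
  const double* Tr_p = REAL(T_refr);
  const double* ge_base = REAL(gamma_e);
  const double* gi_base = REAL(gamma_i);

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    int idx = (int)(t * fs_input);
    if (idx >= t_in) idx = t_in - 1;
    const int slot = step % delay_steps;
    const double* ge_col = ge_base + (size_t)idx * n;
    const double* gi_col = gi_base + (size_t)idx * n;

    if (has_rc) {
      // consume matured deliveries before any spike of this step refills
      std::vector<double>& ib = ipsp_buf[slot];
      for (int j = 0; j < n; ++j) {
        g_ren[j] = g_ren[j] * syn_decay + ib[j];
        ib[j] = 0.0;
      }
      std::vector<double>& eb = epsp_buf[slot];
      for (int c = 0; c < m; ++c) {
        epsp_now[c] = eb[c];
        eb[c] = 0.0;
      }
    }

    for (int j = 0; j < n; ++j) {
      if (t < refr_until[j]) { v[j] = 0.0; continue; }
      double ge = ge_col[j];
      if (ge < 0) ge = 0;
      double gi = gi_col[j] + g_ren[j];
      if (gi < 0) gi = 0;
      double i_ex = ge * S_p[j] * (e_excit - v[j]) - Ir_p[j];
      if (i_ex < 0) i_ex = 0;
      double dv = (-v[j] / R_p[j] + i_ex + gi * S_p[j] * (e_inhib - v[j]))
                  / C_p[j] * dt;
      v[j] += dv;
      if (!std::isfinite(v[j]) || std::fabs(v[j]) > blowup)
        stop("Membrane potential diverged at t = %f s; decrease dt (= %g s).",
             t, dt);
      if (v[j] >= v_thresh) {
        spikes[j].push_back(t);
        v[j] = 0.0;
        refr_until[j] = t + Tr_p[j];
        if (has_rc) {
          std::vector<double>& fut = epsp_buf[slot];
          for (int c : adj_mn2rc[j]) fut[c] += epsp;
        }
      }
    }

    if (has_rc) {
      for (int c = 0; c < m; ++c) {
        if (t < rc_refr_until[c]) { v_rc[c] = 0.0; continue; }
        v_rc[c] += (rc_noise(c, idx) - v_rc[c]) / rc_tau * dt + epsp_now[c];
        if (v_rc[c] >= rc_vth) {
          rc_spikes[c].push_back(t);
          v_rc[c] = 0.0;
          rc_refr_until[c] = t + rc_trefr;
          std::vector<double>& fut = ipsp_buf[slot];
          for (int jj : adj_rc2mn[c]) fut[jj] += ipsp;
        }
      }
    }
  }

  List mn_out(n);
  for (int j = 0; j < n; ++j)
    mn_out[j] = NumericVector(spikes[j].begin(), spikes[j].end());
  List rc_out(m);
  for (int c = 0; c < m; ++c)
    rc_out[c] = NumericVector(rc_spikes[c].begin(), rc_spikes[c].end());
  return List::create(_["mn_spikes"] = mn_out, _["rc_spikes"] = rc_out);
}
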