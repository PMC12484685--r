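#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of a leaky integrate-and-fire E/I network with
// presynaptic-spike-triggered depression (multiplicative) and facilitation
// (additive) on excitatory synapses, double-exponential synaptic kernels and
// an optional external kick to a subset of excitatory neurons.
//
// Neurons are indexed 0..NE-1 (excitatory) and NE..NE+NI-1 (inhibitory).
// Adjacency is in compressed form by presynaptic neuron, split by
// postsynaptic class.  STP factors are kept per presynaptic excitatory
// neuron and postsynaptic class, updated lazily (exact exponential decay to
// 1 between spikes).
//
// Synaptic input currents are realised as pairs of exponential accumulators
// (decay tau_d and tau_r per presynaptic class); the current contributed by
// a spike of weight w is w * (e^{-t/tau_d} - e^{-t/tau_r}) / (tau_d - tau_r),
// which integrates to w.
// [[Rcpp::export]]
List lif_sim_cpp(int NE, int NI,
                 IntegerVector adjE_ptr, IntegerVector adjE_idx,
                 IntegerVector adjI_ptr, IntegerVector adjI_idx,
                 NumericVector mu,
                 double tau_e, double tau_i, double v_th, double v_re,
                 double tau_ref, double sigma_e, double sigma_i,
                 double tr_e, double td_e, double tr_i, double td_i,
                 double j_ee, double j_ei, double j_ie, double j_ii,
                 double d_ee, double f_ee, double d_ie, double f_ie,
                 double tau_dep, double tau_fac,
                 IntegerVector kick_idx, NumericVector kick_amp,
                 double kick_on, double kick_off,
                 double T, double dt,
                 IntegerVector record_idx, int record_stride,
                 NumericVector v0, double max_mean_rate_hz = 150.0) {
  const int N = NE + NI;
  const int nsteps = (int)std::round(T / dt);
  const size_t max_spikes =
      (size_t)((double)N * (T / 1000.0) * max_mean_rate_hz) + 1000;

  std::vector<double> V(v0.begin(), v0.end());
  std::vector<double> refrac_until(N, -1.0);
  // synaptic filter states per neuron: E input (aE fast-decay td, bE rise tr)
  std::vector<double> aE(N, 0.0), bE(N, 0.0), aI(N, 0.0), bI(N, 0.0);
  // STP factors per presynaptic excitatory neuron, per postsynaptic class
  std::vector<double> Dee(NE, 1.0), Fee(NE, 1.0), Die(NE, 1.0), Fie(NE, 1.0);
  std::vector<double> stp_t(NE, 0.0);

  const double decE_a = std::exp(-dt / td_e), decE_b = std::exp(-dt / tr_e);
  const double decI_a = std::exp(-dt / td_i), decI_b = std::exp(-dt / tr_i);
  const double normE = 1.0 / (td_e - tr_e), normI = 1.0 / (td_i - tr_i);
  const double sq_dt = std::sqrt(dt);

  std::vector<double> kick(N, 0.0);
  for (int k = 0; k < kick_idx.size(); ++k) kick[kick_idx[k]] = kick_amp[k];

  std::vector<int> sp_id;
  std::vector<double> sp_t;
  sp_id.reserve(1 << 16);
  sp_t.reserve(1 << 16);

  const int nrec = record_idx.size();
  const int nrec_t = nrec > 0 ? nsteps / record_stride + 1 : 0;
  NumericMatrix rec_e(nrec_t, nrec), rec_i(nrec_t, nrec);
  NumericVector rec_t(nrec_t);
  int ri = 0;

  for (int s = 0; s < nsteps; ++s) {
    double t = s * dt;
    bool kicking = (t >= kick_on && t < kick_off);

    if (nrec > 0 && s % record_stride == 0 && ri < nrec_t) {
      rec_t[ri] = t;
      for (int k = 0; k < nrec; ++k) {
        int i = record_idx[k];
        rec_e(ri, k) = (aE[i] - bE[i]) * normE;
        rec_i(ri, k) = (aI[i] - bI[i]) * normI;
      }
      ++ri;
    }

    // membrane update
    for (int i = 0; i < N; ++i) {
      double Ie = (aE[i] - bE[i]) * normE;
      double Ii = (aI[i] - bI[i]) * normI;
      if (t < refrac_until[i]) {
        V[i] = v_re;
      } else {
        bool exc = i < NE;
        double tau_m = exc ? tau_e : tau_i;
        double sig = exc ? sigma_e : sigma_i;
        double drive = Ie + Ii;
        if (kicking && kick[i] != 0.0) drive += kick[i];
        V[i] += dt * ((mu[i] - V[i]) / tau_m + drive) + sig * sq_dt * norm_rand();
        if (!R_finite(V[i]))
          stop("membrane potential diverged at t = %f ms (neuron %d)", t, i + 1);
      }
    }

    // filter decay
    for (int i = 0; i < N; ++i) {
      aE[i] *= decE_a; bE[i] *= decE_b;
      aI[i] *= decI_a; bI[i] *= decI_b;
    }

    // threshold crossings and spike propagation
    for (int i = 0; i < N; ++i) {
      if (V[i] < v_th || t < refrac_until[i]) continue;
      V[i] = v_re;
      refrac_until[i] = t + dt + tau_ref;
      sp_id.push_back(i + 1);
      sp_t.push_back(t + dt);
      if (sp_id.size() > max_spikes)
        stop("runaway activity: mean rate exceeded %.0f Hz by t = %.0f ms",
             max_mean_rate_hz, t);

      if (i < NE) {
        // lazy STP decay to now, use pre-update factors for this spike
        double el = (t + dt) - stp_t[i];
        double eD = std::exp(-el / tau_dep), eF = std::exp(-el / tau_fac);
        Dee[i] = 1.0 + (Dee[i] - 1.0) * eD;
        Fee[i] = 1.0 + (Fee[i] - 1.0) * eF;
        Die[i] = 1.0 + (Die[i] - 1.0) * eD;
        Fie[i] = 1.0 + (Fie[i] - 1.0) * eF;
        stp_t[i] = t + dt;
        double wE = j_ee * Dee[i] * Fee[i];
        double wI = j_ie * Die[i] * Fie[i];
        Dee[i] *= d_ee; Fee[i] += f_ee;
        Die[i] *= d_ie; Fie[i] += f_ie;
        for (int p = adjE_ptr[i]; p < adjE_ptr[i + 1]; ++p) {
          int tgt = adjE_idx[p];
          aE[tgt] += wE; bE[tgt] += wE;
        }
        for (int p = adjI_ptr[i]; p < adjI_ptr[i + 1]; ++p) {
          int tgt = adjI_idx[p];
          aE[tgt] += wI; bE[tgt] += wI;
        }
      } else {
        for (int p = adjE_ptr[i]; p < adjE_ptr[i + 1]; ++p) {
          int tgt = adjE_idx[p];
          aI[tgt] += j_ei; bI[tgt] += j_ei;
        }
        for (int p = adjI_ptr[i]; p < adjI_ptr[i + 1]; ++p) {
          int tgt = adjI_idx[p];
          aI[tgt] += j_ii; bI[tgt] += j_ii;
        }
      }
    }
  }

  List rec = R_NilValue;
  if (nrec > 0)
    rec = List::create(_["t"] = rec_t, _["i_exc"] = rec_e, _["i_inh"] = rec_i);
  return List::create(_["id"] = wrap(sp_id), _["time"] = wrap(sp_t),
                      _["currents"] = rec,
                      _["v_final"] = wrap(V));
}
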