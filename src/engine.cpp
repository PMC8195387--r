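// Conductance-based leaky integrate-and-fire network engine.
//
// Integrates a sparse E/I network over a fixed-connectivity interval:
// exponential decay for synaptic conductances, forward Euler for the
// membrane potential, per-neuron Poisson external drive, symmetric
// inhibitory STDP on IE synapses, per-neuron calcium traces, and optional
// accumulation of continuous synaptic-element counts under per-neuron
// Gaussian growth curves. Connectivity changes (structural plasticity)
// happen between calls, in R.
//
// Units: time ms, voltage mV, conductance nS, capacitance pF, current pA.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List engine_run(List state, List net, List prm, double duration_ms) {
  // --- state (copied; returned updated) ---
  NumericVector V = clone(as<NumericVector>(state["V"]));
  NumericVector ge = clone(as<NumericVector>(state["ge"]));
  NumericVector gi = clone(as<NumericVector>(state["gi"]));
  NumericVector ref = clone(as<NumericVector>(state["ref"]));
  NumericVector ca = clone(as<NumericVector>(state["ca"]));
  NumericVector xtr = clone(as<NumericVector>(state["xtr"]));
  NumericVector next_ext = clone(as<NumericVector>(state["next_ext"]));
  NumericMatrix z = clone(as<NumericMatrix>(state["z"]));
  double t0 = as<double>(state["t"]);

  const int n = V.size();

  // --- network (weights copied: IE synapses are plastic) ---
  IntegerVector is_exc = net["is_exc"];
  IntegerVector ext_on = net["ext_on"];
  NumericVector Ie = net["Ie"];
  NumericVector g_ext = net["g_ext"];
  IntegerVector src_ptr = net["src_ptr"]; // 0-based CSR, length n+1
  IntegerVector tgt = net["tgt"];         // 0-based targets
  NumericVector w = clone(as<NumericVector>(net["w"]));
  IntegerVector cls = net["cls"];         // 0 EE, 1 EI, 2 IE, 3 II
  IntegerVector ie_ptr = net["ie_ptr"];   // 0-based, incoming IE per neuron
  IntegerVector ie_idx = net["ie_idx"];   // synapse indices
  IntegerVector syn_src = net["syn_src"]; // 0-based source per synapse

  // --- parameters ---
  const double dt = as<double>(prm["dt"]);           // ms
  const double Cm = as<double>(prm["C"]);            // pF
  const double gL = as<double>(prm["g_L"]);          // nS
  const double EL = as<double>(prm["E_L"]);          // mV
  const double Ee = as<double>(prm["E_exc"]);
  const double Ei = as<double>(prm["E_inh"]);
  const double Vth = as<double>(prm["V_th"]);
  const double Vre = as<double>(prm["V_reset"]);
  const double tref = as<double>(prm["t_ref"]);      // ms
  const double de = std::exp(-dt / as<double>(prm["tau_exc"]));
  const double di = std::exp(-dt / as<double>(prm["tau_inh"]));
  const double beta = as<double>(prm["beta_ca"]);
  const double dca = std::exp(-dt / as<double>(prm["tau_ca"])); // tau_ca ms
  const double rate_ext = as<double>(prm["rate_ext"]); // events per ms
  const int istdp_on = as<int>(prm["istdp_on"]);
  const double dstdp = std::exp(-dt / as<double>(prm["tau_stdp"]));
  const double alpha = as<double>(prm["alpha"]);
  const double eta_w = as<double>(prm["eta_w"]);     // nS per trace unit
  const int growth_on = as<int>(prm["growth_on"]);
  const double growth_dt = as<double>(prm["growth_dt"]); // ms
  const int record_spikes = as<int>(prm["record_spikes"]);

  // per-neuron growth curves, one per pool (axonal, post-E, post-I);
  // nu in elements per ms
  NumericMatrix nu = prm["nu"];
  NumericMatrix xi = prm["xi"];
  NumericMatrix zeta = prm["zeta"];
  NumericMatrix om = prm["om"];
  IntegerMatrix gconst = prm["gconst"];

  const int nsteps = (int)std::lround(duration_ms / dt);
  const int growth_every = std::max(1, (int)std::lround(growth_dt / dt));

  std::vector<int> sp_id;
  std::vector<double> sp_t;
  IntegerVector spike_count(n);
  std::vector<int> spiking;
  spiking.reserve(256);

  RNGScope rngScope;

  // schedule first external events for neurons lacking one
  for (int i = 0; i < n; ++i) {
    if (ext_on[i] && !R_finite(next_ext[i])) {
      next_ext[i] = t0 + R::rexp(1.0 / rate_ext);
    } else if (!ext_on[i]) {
      next_ext[i] = R_PosInf;
    }
  }

  for (int s = 0; s < nsteps; ++s) {
    const double t = t0 + (s + 1) * dt;
    spiking.clear();

    for (int i = 0; i < n; ++i) {
      // external Poisson events (excitatory conductance kicks)
      while (next_ext[i] <= t) {
        ge[i] += g_ext[i];
        next_ext[i] += R::rexp(1.0 / rate_ext);
      }
      if (ref[i] > 0.0) {
        ref[i] -= dt;
        V[i] = Vre;
      } else {
        const double dV = (-gL * (V[i] - EL) - ge[i] * (V[i] - Ee)
                           - gi[i] * (V[i] - Ei) + Ie[i]) * (dt / Cm);
        V[i] += dV;
        if (V[i] >= Vth) {
          spiking.push_back(i);
          V[i] = Vre;
          ref[i] = tref;
          ca[i] += beta;
          ++spike_count[i];
          if (record_spikes) { sp_id.push_back(i + 1); sp_t.push_back(t); }
        }
      }
      ge[i] *= de;
      gi[i] *= di;
      ca[i] *= dca;
      xtr[i] *= dstdp;
    }

    // deliver spikes (effective one-step transmission delay) and apply
    // the symmetric inhibitory STDP rule to IE synapses
    for (size_t k = 0; k < spiking.size(); ++k) {
      const int i = spiking[k];
      if (istdp_on && is_exc[i]) {
        // post-side potentiation of incoming IE synapses
        for (int q = ie_ptr[i]; q < ie_ptr[i + 1]; ++q) {
          const int j = ie_idx[q];
          w[j] += eta_w * xtr[syn_src[j]];
        }
      }
      const int exc = is_exc[i];
      for (int q = src_ptr[i]; q < src_ptr[i + 1]; ++q) {
        const int tg = tgt[q];
        if (istdp_on && cls[q] == 2) {
          // pre-side update: depression below target trace, potentiation
          // above it
          w[q] += eta_w * (xtr[tg] - alpha);
          if (w[q] < 0.0) w[q] = 0.0;
        }
        if (exc) ge[tg] += w[q]; else gi[tg] += w[q];
      }
      xtr[i] += 1.0;
    }

    if (growth_on && ((s + 1) % growth_every == 0)) {
      for (int i = 0; i < n; ++i) {
        const double c = ca[i];
        for (int k = 0; k < 3; ++k) {
          const double nuk = nu(i, k);
          if (nuk == 0.0) continue;
          double rate;
          if (gconst(i, k)) {
            rate = nuk;
          } else {
            const double u = (c - xi(i, k)) / zeta(i, k);
            rate = nuk * (2.0 * std::exp(-u * u) - om(i, k));
          }
          double znew = z(i, k) + rate * growth_dt;
          z(i, k) = znew > 0.0 ? znew : 0.0;
        }
      }
    }

    if ((s & 1023) == 0) {
      for (int i = 0; i < n; ++i) {
        if (!R_finite(V[i])) {
          stop("non-finite membrane potential at t = %f ms (neuron %d)",
               t, i + 1);
        }
      }
    }
  }

  return List::create(
    _["V"] = V, _["ge"] = ge, _["gi"] = gi, _["ref"] = ref, _["ca"] = ca,
    _["xtr"] = xtr, _["next_ext"] = next_ext, _["z"] = z,
    _["t"] = t0 + nsteps * dt, _["w"] = w,
    _["spike_id"] = wrap(sp_id), _["spike_t"] = wrap(sp_t),
    _["spike_count"] = spike_count);
}

// Minimum-image torus distances from one point to many; used by the
// structural update when the full kernel matrix is too large to cache.
// [[Rcpp::export]]
NumericVector torus_dist_point(double ax, double ay, NumericVector bx,
                               NumericVector by, NumericVector extent) {
  const int n = bx.size();
  NumericVector out(n);
  const double exx = extent[0], exy = extent[1];
  for (int i = 0; i < n; ++i) {
    double dx = std::fabs(ax - bx[i]);
    double dy = std::fabs(ay - by[i]);
    if (exx - dx < dx) dx = exx - dx;
    if (exy - dy < dy) dy = exy - dy;
    out[i] = std::sqrt(dx * dx + dy * dy);
  }
  return out;
}
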