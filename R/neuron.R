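#' Conductance-based integrate-and-fire neuron parameters
#'
#' Defaults are the standard cortical point-neuron values used throughout
#' the package: 200 pF capacitance, 10 nS leak at -60 mV, reversal
#' potentials 0 / -80 mV for excitation / inhibition, -50 mV threshold with
#' reset to -60 mV and a 5 ms refractory period, exponential synaptic
#' conductances with 5 / 10 ms decay, and a calcium trace incremented by
#' 0.1 per spike decaying with a 50 s time constant.
#'
#' @param C Membrane capacitance (pF).
#' @param g_L Leak conductance (nS).
#' @param E_L Leak reversal potential (mV).
#' @param E_exc,E_inh Synaptic reversal potentials (mV).
#' @param V_th Spike threshold (mV).
#' @param V_reset Post-spike reset potential (mV).
#' @param t_ref Absolute refractory period (ms).
#' @param tau_exc,tau_inh Synaptic conductance decay constants (ms).
#' @param beta_ca Calcium increment per spike (dimensionless).
#' @param tau_ca Calcium decay time constant (s).
#' @return A named list of class `neuron_params`.
#' @export
neuron_params <- function(C = 200, g_L = 10, E_L = -60, E_exc = 0,
                          E_inh = -80, V_th = -50, V_reset = -60,
                          t_ref = 5, tau_exc = 5, tau_inh = 10,
                          beta_ca = 0.1, tau_ca = 50) {
  stopifnot(E_inh < E_L, E_L <= V_reset, V_reset < V_th, V_th < E_exc,
            C > 0, g_L > 0, t_ref >= 0, tau_exc > 0, tau_inh > 0,
            tau_ca > 0)
  out <- list(C = C, g_L = g_L, E_L = E_L, E_exc = E_exc, E_inh = E_inh,
              V_th = V_th, V_reset = V_reset, t_ref = t_ref,
              tau_exc = tau_exc, tau_inh = tau_inh, beta_ca = beta_ca,
              tau_ca = tau_ca)
  class(out) <- "neuron_params"
  out
}

#' Single forward-Euler membrane step
#'
#' Reference implementation of one integration step for a single neuron:
#' conductances decay exponentially, the membrane potential follows
#' \deqn{C \, dV/dt = -g_L (V - E_L) - g_{exc}(V - E_{exc})
#'       - g_{inh}(V - E_{inh}) + I_e,}
#' and a threshold crossing emits a spike, resets `V` and starts the
#' refractory clock. The network engine implements the same scheme in
#' compiled code; this R version is the readable single-neuron surface.
#'
#' @param state List with `V` (mV), `g_exc`, `g_inh` (nS),
#'   `refractory_remaining` (ms).
#' @param params A [neuron_params()].
#' @param dt Step duration (ms), small relative to all time constants.
#' @param I_e External current (pA).
#' @return List with updated `state` and logical `spiked`.
#' @export
step_membrane <- function(state, params, dt = 0.1, I_e = 0) {
  stopifnot(dt > 0)
  if (!all(is.finite(c(state$V, state$g_exc, state$g_inh)))) {
    stop("non-finite neuron state")
  }
  spiked <- FALSE
  if (state$refractory_remaining > 0) {
    state$refractory_remaining <- state$refractory_remaining - dt
    state$V <- params$V_reset
  } else {
    dV <- (-params$g_L * (state$V - params$E_L) -
             state$g_exc * (state$V - params$E_exc) -
             state$g_inh * (state$V - params$E_inh) + I_e) * dt / params$C
    state$V <- state$V + dV
    if (state$V >= params$V_th) {
      spiked <- TRUE
      state$V <- params$V_reset
      state$refractory_remaining <- params$t_ref
    }
  }
  state$g_exc <- state$g_exc * exp(-dt / params$tau_exc)
  state$g_inh <- state$g_inh * exp(-dt / params$tau_inh)
  list(state = state, spiked = spiked)
}

#' Symmetric inhibitory STDP update for one IE synapse
#'
#' The homeostatic rule that balances the network: at a pre-synaptic
#' (inhibitory) spike the conductance changes by
#' `eta * gbar * (x_post - alpha)` (depression when the target has been
#' quiet, potentiation when active); at a post-synaptic spike it grows by
#' `eta * gbar * x_pre`. Traces `x` are incremented by one at their own
#' neuron's spikes and decay with `tau_stdp`. Conductances are clipped at
#' zero from below. With `alpha = 0.12` and `tau_stdp = 20` ms the rule
#' steers excitatory targets toward `alpha / (2 tau_stdp) = 3` Hz.
#'
#' @param g Current conductance (nS).
#' @param event `"pre"` or `"post"`.
#' @param x_pre,x_post Trace values of the inhibitory source and
#'   excitatory target at the moment of the event.
#' @param eta Learning rate. Default 0.05.
#' @param alpha Target constant. Default 0.12.
#' @param gbar Unit conductance scaling the update (nS). Default 0.5.
#' @return Updated conductance (nS, >= 0).
#' @export
istdp_update <- function(g, event = c("pre", "post"), x_pre = 0, x_post = 0,
                         eta = 0.05, alpha = 0.12, gbar = 0.5) {
  event <- match.arg(event)
  dg <- if (event == "pre") eta * gbar * (x_post - alpha)
        else eta * gbar * x_pre
  max(0, g + dg)
}

#' Bernoulli-thinned Poisson external drive
#'
#' Each connected neuron independently receives an external event in a
#' membrane step with probability `rate * dt`; disconnected neurons (the
#' lesion projection zone after deafferentation) receive none.
#'
#' @param n Number of neurons.
#' @param rate Poisson rate per neuron (Hz).
#' @param dt Step duration (ms).
#' @param connected Logical vector (recycled) of per-neuron drive flags.
#' @return Logical vector of event indicators.
#' @export
poisson_drive <- function(n, rate = 10, dt = 0.1, connected = TRUE) {
  stopifnot(rate >= 0, dt > 0)
  p <- rate * dt / 1000
  ev <- stats::runif(n) < p
  ev & rep_len(connected, n)
}
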