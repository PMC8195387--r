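#' Assemble a simulatable spiking network
#'
#' Binds a spatial layout, a synapse table and a configuration into a
#' `spiking_network` object holding the full dynamical state: membrane
#' potentials (initialised uniformly between reset and threshold to avoid
#' artificial synchrony), synaptic conductances, refractory clocks, calcium
#' traces, STDP traces, the per-neuron external-drive flags, and the
#' 3-column matrix of continuous synaptic-element counts (axonal, post-
#' excitatory, post-inhibitory pools).
#'
#' @param layout Region-labelled layout from [place_neurons()] +
#'   [classify_regions()].
#' @param syn Synapse tibble from [wire_initial()].
#' @param cfg Configuration list from [default_config()].
#' @return A `spiking_network` object.
#' @export
build_network <- function(layout, syn, cfg = default_config()) {
  stopifnot(!is.null(layout$region))
  n <- nrow(layout)
  np <- cfg$neuron
  state <- list(
    V = stats::runif(n, np$V_reset, np$V_th),
    ge = numeric(n), gi = numeric(n), ref = numeric(n),
    ca = numeric(n), xtr = numeric(n),
    next_ext = rep(NA_real_, n),
    z = matrix(0, n, 3), # pools: axonal, post-excitatory, post-inhibitory
    t = 0
  )
  net <- list(
    layout = layout,
    extent = attr(layout, "extent"),
    mu_d_e = attr(layout, "mu_d_e") %||% 150,
    syn = syn,
    cfg = cfg,
    state = state,
    ext_on = rep(TRUE, n),
    Ie = numeric(n),
    curves = NULL,
    psi = NULL,
    ie_mean = NULL,
    g_th = NULL,
    deafferented = FALSE,
    csr = NULL
  )
  class(net) <- "spiking_network"
  net
}

#' @export
print.spiking_network <- function(x, ...) {
  n_e <- sum(x$layout$pop == "E")
  n_i <- sum(x$layout$pop == "I")
  cat("<spiking_network>", n_e, "E +", n_i, "I neurons,",
      nrow(x$syn), "synapses, t =", x$state$t / 1000, "s\n")
  cat("  structural curves:", if (is.null(x$curves)) "not instantiated"
      else "instantiated", "| deafferented:", x$deafferented, "\n")
  invisible(x)
}

# Build (and cache) the compressed sparse row view of the synapse table
# used by the compiled engine. The synapse tibble is re-ordered by source
# so engine weight updates map back by position.
ensure_csr <- function(net) {
  if (!is.null(net$csr)) return(net)
  n <- nrow(net$layout)
  syn <- net$syn[order(net$syn$pre), , drop = FALSE]
  cls_int <- c(EE = 0L, EI = 1L, IE = 2L, II = 3L)[as.character(syn$class)]
  src_ptr <- c(0L, cumsum(tabulate(syn$pre, nbins = n)))
  ie <- which(cls_int == 2L)
  ie <- ie[order(syn$post[ie])]
  ie_ptr <- c(0L, cumsum(tabulate(syn$post[ie], nbins = n)))
  net$syn <- syn
  net$csr <- list(
    src_ptr = as.integer(src_ptr),
    tgt = as.integer(syn$post - 1L),
    cls = as.integer(cls_int),
    syn_src = as.integer(syn$pre - 1L),
    ie_idx = as.integer(ie - 1L),
    ie_ptr = as.integer(ie_ptr)
  )
  net
}

# Engine parameter list in engine units (ms-based).
engine_params <- function(net, istdp, growth, record_spikes) {
  cfg <- net$cfg
  np <- cfg$neuron
  n <- nrow(net$layout)
  if (is.null(net$curves)) {
    zero <- matrix(0, n, 3)
    curves <- list(nu = zero, xi = zero, zeta = zero + 1, om = zero,
                   gconst = matrix(0L, n, 3))
    growth <- FALSE
  } else {
    curves <- net$curves
  }
  list(
    dt = cfg$dt_membrane_ms,
    C = np$C, g_L = np$g_L, E_L = np$E_L, E_exc = np$E_exc,
    E_inh = np$E_inh, V_th = np$V_th, V_reset = np$V_reset,
    t_ref = np$t_ref, tau_exc = np$tau_exc, tau_inh = np$tau_inh,
    beta_ca = np$beta_ca, tau_ca = np$tau_ca * 1000,
    rate_ext = cfg$synapse$rate_ext / 1000,
    istdp_on = as.integer(istdp),
    tau_stdp = cfg$synapse$tau_stdp,
    alpha = cfg$synapse$alpha,
    eta_w = cfg$synapse$eta_stdp * cfg$istdp_accel * cfg$synapse$gbar,
    growth_on = as.integer(growth),
    growth_dt = cfg$dt_growth_s * 1000,
    record_spikes = as.integer(record_spikes),
    nu = curves$nu / 1000 * cfg$growth_accel, # per s -> per ms
    xi = curves$xi, zeta = curves$zeta, om = curves$om,
    gconst = curves$gconst
  )
}

#' Advance a network over a fixed-connectivity interval
#'
#' Runs the compiled engine for `duration_ms` of simulated time with the
#' current synapse table. Membrane, conductance, calcium, STDP-trace and
#' (when growth curves are instantiated) element-count state all advance;
#' the synapse table's IE conductances are updated in place when inhibitory
#' STDP is enabled.
#'
#' @param net A `spiking_network`.
#' @param duration_ms Interval length (ms).
#' @param istdp Enable the inhibitory STDP rule on IE synapses.
#' @param growth Enable integration of the element counts (requires
#'   instantiated growth curves).
#' @param record_spikes Keep the spike raster for this interval.
#' @return List with the updated `net`, a `spikes` tibble (`id`, `t_ms`),
#'   and the per-neuron `spike_count`.
#' @export
simulate_interval <- function(net, duration_ms, istdp = TRUE,
                              growth = FALSE, record_spikes = TRUE) {
  net <- ensure_csr(net)
  csr <- net$csr
  netlist <- list(
    is_exc = as.integer(net$layout$pop == "E"),
    ext_on = as.integer(net$ext_on),
    Ie = net$Ie,
    g_ext = ifelse(net$layout$pop == "E", net$cfg$synapse$g_ext_E,
                   net$cfg$synapse$g_ext_I),
    src_ptr = csr$src_ptr, tgt = csr$tgt, w = net$syn$g, cls = csr$cls,
    ie_ptr = csr$ie_ptr, ie_idx = csr$ie_idx, syn_src = csr$syn_src
  )
  prm <- engine_params(net, istdp, growth, record_spikes)
  res <- engine_run(net$state, netlist, prm, duration_ms)
  net$state <- list(V = res$V, ge = res$ge, gi = res$gi, ref = res$ref,
                    ca = res$ca, xtr = res$xtr, next_ext = res$next_ext,
                    z = res$z, t = res$t)
  net$syn$g <- res$w
  spikes <- tibble::tibble(id = res$spike_id, t_ms = res$spike_t)
  list(net = net, spikes = spikes, spike_count = res$spike_count)
}

# Connected-element counts per neuron per pool, derived from the synapse
# table: pool 1 = axonal (out-degree), pool 2 = post-excitatory (in-degree
# from E sources), pool 3 = post-inhibitory (in-degree from I sources).
connected_counts <- function(net) {
  n <- nrow(net$layout)
  syn <- net$syn
  from_e <- syn$class %in% c("EE", "EI")
  cbind(tabulate(syn$pre, nbins = n),            # axonal
        tabulate(syn$post[from_e], nbins = n),   # post-excitatory
        tabulate(syn$post[!from_e], nbins = n))  # post-inhibitory
}
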