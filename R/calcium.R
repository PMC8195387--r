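#' Calcium activity trace
#'
#' Each neuron carries a low-pass filtered record of its own spiking, the
#' "calcium" trace: it decays exponentially with time constant `tau_ca`
#' and jumps by `beta` at every spike. Its long-run mean under Poisson
#' firing at rate r is `beta * r * tau_ca`, which makes it a slow,
#' dimensionless proxy for firing rate used by the growth curves.
#'
#' @param ca Initial concentration (dimensionless, >= 0).
#' @param beta Per-spike increment. Default 0.1.
#' @param tau_ca Decay time constant in seconds. Default 50.
#' @return An object of class `calcium_trace`.
#' @export
calcium_trace <- function(ca = 0, beta = 0.1, tau_ca = 50) {
  stopifnot(is.numeric(ca), length(ca) == 1L, ca >= 0,
            beta >= 0, tau_ca > 0)
  out <- list(ca = ca, beta = beta, tau_ca = tau_ca)
  class(out) <- "calcium_trace"
  out
}

#' Advance a calcium trace
#'
#' Applies exponential decay over an elapsed interval and then adds the
#' per-spike increment for each spike emitted in that interval. Spike
#' increments are instantaneous jumps of `beta`, matching the definition of
#' the per-spike calcium influx.
#'
#' @param trace A [calcium_trace()].
#' @param n_spikes Number of spikes emitted during the interval.
#' @param dt Elapsed time in seconds (> 0), or 0 to apply spikes only.
#' @return The updated `calcium_trace`.
#' @export
update_calcium <- function(trace, n_spikes = 0, dt = 0) {
  stopifnot(inherits(trace, "calcium_trace"))
  if (dt < 0) stop("`dt` must be non-negative")
  stopifnot(n_spikes >= 0)
  ca <- trace$ca * exp(-dt / trace$tau_ca) + n_spikes * trace$beta
  trace$ca <- ca
  trace
}
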