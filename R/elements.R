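#' Synaptic element pool
#'
#' Book-keeping for one class of synaptic elements on one neuron. The
#' continuous count `z` is driven by the growth curve; `z_connected` is the
#' integer number of elements currently bound in synapses; `z_free` is the
#' integer number of unbound elements harvested for synapse formation and
#' subject to decay at rate `tau_free` while unused.
#'
#' Element classes: excitatory neurons carry `"pre_exc"` (axonal),
#' `"post_exc"` and `"post_inh"` pools; inhibitory neurons carry
#' `"pre_inh"`, `"post_exc"` and `"post_inh"`. A neuron never owns the
#' axonal pool of the opposite polarity.
#'
#' @param element_class One of `"pre_exc"`, `"pre_inh"`, `"post_exc"`,
#'   `"post_inh"`.
#' @param z Continuous element count (>= 0).
#' @param z_connected Integer count of elements bound in synapses.
#' @param z_free Integer count of harvested unbound elements.
#' @param tau_free Per-update decay rate of free elements. Default 0.01.
#' @return An object of class `element_pool`.
#' @export
element_pool <- function(element_class = c("pre_exc", "pre_inh",
                                           "post_exc", "post_inh"),
                         z = 0, z_connected = 0L, z_free = 0L,
                         tau_free = 0.01) {
  element_class <- match.arg(element_class)
  stopifnot(z >= 0, z_connected >= 0, z_free >= 0,
            tau_free >= 0, tau_free < 1)
  out <- list(element_class = element_class, z = as.numeric(z),
              z_connected = as.integer(z_connected),
              z_free = as.integer(z_free), tau_free = tau_free)
  class(out) <- "element_pool"
  out
}

#' Integrate the continuous element count under a growth curve
#'
#' Adds `growth_rate(curve, ca) * dt` to `z` for `n_steps` consecutive
#' growth steps at a fixed calcium level. The total is clamped at zero from
#' below: element counts are physical quantities and never go negative.
#'
#' @param pool An [element_pool()].
#' @param curve The [growth_curve()] governing this pool.
#' @param ca Calcium level during the steps.
#' @param n_steps Number of growth steps (>= 1).
#' @param dt Duration of one growth step in seconds. Default 0.1.
#' @return The updated pool.
#' @export
integrate_elements <- function(pool, curve, ca, n_steps = 1L, dt = 0.1) {
  stopifnot(inherits(pool, "element_pool"), n_steps >= 1, dt > 0)
  pool$z <- max(0, pool$z + growth_rate(curve, ca) * dt * n_steps)
  pool
}

#' Harvest free elements
#'
#' Elements in excess of those bound in synapses become available for
#' synapse formation: `z_free = floor(z - z_connected)` when positive,
#' otherwise zero. Stores the result in the pool and returns it.
#'
#' @param pool An [element_pool()].
#' @return The pool with `z_free` updated.
#' @export
harvest_free_elements <- function(pool) {
  stopifnot(inherits(pool, "element_pool"))
  pool$z_free <- as.integer(max(0, floor(pool$z - pool$z_connected)))
  pool
}

#' Decay unused free elements
#'
#' Free elements that did not find a partner decay:
#' `z_free <- floor(z_free - tau_free * z_free)`. The continuous total `z`
#' is reduced by the same amount so decayed elements are not resurrected at
#' the next harvest.
#'
#' @param pool An [element_pool()].
#' @return The updated pool.
#' @export
decay_free_elements <- function(pool) {
  stopifnot(inherits(pool, "element_pool"), pool$z_free >= 0)
  new_free <- as.integer(floor(pool$z_free - pool$tau_free * pool$z_free))
  lost <- pool$z_free - new_free
  pool$z_free <- new_free
  pool$z <- max(0, pool$z - lost)
  pool
}

#' Synapse losses demanded by element retraction
#'
#' When the growth rule has retracted `z` below the number of connected
#' elements, the neuron must shed synapses:
#' `z_loss = floor(z_connected - z)` when positive, otherwise zero.
#'
#' @param pool An [element_pool()].
#' @return Integer number of synapses to delete for this pool.
#' @export
count_losses <- function(pool) {
  stopifnot(inherits(pool, "element_pool"))
  as.integer(max(0, floor(pool$z_connected - pool$z)))
}
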