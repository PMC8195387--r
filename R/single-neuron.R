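#' Single-neuron homeostasis experiment
#'
#' Tests the stabilising effect of the post-synaptic growth rules on an
#' isolated conductance-based neuron driven by current injection, in four
#' stages:
#' \enumerate{
#'   \item \strong{Baseline}: a constant current `I_base` drives regular
#'     firing until the calcium trace settles; the level reached defines
#'     the neuron's optimal calcium `psi`.
#'   \item \strong{Grow-in}: the current is lowered to `I_grow`
#'     (sub-optimal activity) and both post-synaptic pools sprout under
#'     identical growth windows with excitatory scaling four times the
#'     inhibitory one, initialising the element counts at the 4:1
#'     excitatory:inhibitory ratio of a balanced network neuron.
#'   \item \strong{Settle}: the current returns to `I_base` and the growth
#'     curves are replaced by the reference post-synaptic configuration
#'     (excitatory elements: stable fixed point at `epsilon = psi`;
#'     inhibitory: at `eta = psi`), whose turnover is zero at `psi`.
#'   \item \strong{Sinusoid}: the current is modulated sinusoidally and the
#'     element-count response is recorded. The net input conductance the
#'     elements would deliver, `g_net = z_postE * g_EE - z_postI * g_IE`,
#'     is tracked as a deviation from its pre-modulation baseline.
#' }
#' The isolated neuron's elements have no partners, so they are free
#' elements and decay at `tau_free` per update interval (continuously
#' here: the pools are never partitioned into connected and free). This
#' decay is what lets the element counts track — rather than indefinitely
#' integrate — the activity deviation.
#'
#' @param I_base Baseline current (pA).
#' @param I_grow Grow-in current (pA), below `I_base`.
#' @param amp Sinusoidal amplitude (pA).
#' @param period_s Sinusoid period (s).
#' @param n_cycles Number of modulation cycles.
#' @param t_base_s,t_grow_s,t_settle_s Stage durations (s).
#' @param nu_grow Inhibitory grow-in scaling factor (elements/s); the
#'   excitatory pool uses four times this value.
#' @param g_ee,g_ie Mean conductances per excitatory / inhibitory element
#'   (nS), as observed in balanced network simulations.
#' @param growth_accel Multiplier on the reference post-synaptic scaling
#'   factors for the sinusoidal stage.
#' @param cfg Configuration (neuron constants and growth block).
#' @param seed RNG seed (initial membrane potential only).
#' @return A `single_neuron_run`: tibble `ts` (per-second `t_s`, `stage`,
#'   `I_ext`, `ca`, `z_post_e`, `z_post_i`, `dg_net`), plus `psi`,
#'   `ratio_after_init`, and `cor_ca_dgnet`.
#' @export
run_single_neuron_experiment <- function(I_base = 150, I_grow = 120,
                                         amp = 30, period_s = 600,
                                         n_cycles = 2, t_base_s = 200,
                                         t_grow_s = 150, t_settle_s = 50,
                                         nu_grow = 0.3, g_ee = 0.5,
                                         g_ie = 2, growth_accel = 300,
                                         cfg = default_config(),
                                         seed = 1) {
  set.seed(seed)
  layout <- tibble::tibble(id = 1L, pop = "E", x = 0, y = 0,
                           region = factor("other",
                                           levels = c("LPZ_C", "LPZ_B",
                                                      "peri_LPZ", "other")))
  attr(layout, "extent") <- c(150, 150)
  attr(layout, "mu_d_e") <- 150
  syn <- tibble::tibble(pre = integer(), post = integer(),
                        class = factor(character(),
                                       levels = c("EE", "EI", "IE", "II")),
                        g = numeric())
  net <- build_network(layout, syn, cfg)
  net$ext_on[] <- FALSE
  tau_free <- cfg$growth$tau_free

  rows <- list()
  run_stage <- function(net, stage, dur_s, current_fn, growth, decay) {
    for (k in seq_len(dur_s)) {
      net$Ie[1] <- current_fn(net$state$t / 1000)
      res <- simulate_interval(net, 1000, istdp = FALSE, growth = growth,
                               record_spikes = FALSE)
      net <- res$net
      if (decay) {
        net$state$z[, 2:3] <- net$state$z[, 2:3] * (1 - tau_free)
      }
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        t_s = net$state$t / 1000, stage = stage, I_ext = net$Ie[1],
        ca = net$state$ca[1], z_post_e = net$state$z[1, 2],
        z_post_i = net$state$z[1, 3])
    }
    net
  }

  gauss <- function(nu, eta, eps, omega) {
    list(nu = nu, xi = (eta + eps) / 2,
         zeta = (eps - eta) / (2 * sqrt(-log(omega / 2))), om = omega)
  }
  set_post_curves <- function(net, ce, ci) {
    nu <- xi <- zeta <- om <- matrix(0, 1, 3)
    gconst <- matrix(0L, 1, 3)
    for (k in 2:3) {
      cc <- if (k == 2) ce else ci
      nu[1, k] <- cc$nu; xi[1, k] <- cc$xi
      zeta[1, k] <- cc$zeta; om[1, k] <- cc$om
    }
    zeta[zeta == 0] <- 1
    net$curves <- list(nu = nu, xi = xi, zeta = zeta, om = om,
                       gconst = gconst)
    net
  }

  # stage 1: baseline, record psi
  net <- run_stage(net, "baseline", t_base_s, function(t) I_base,
                   growth = FALSE, decay = FALSE)
  psi <- net$state$ca[1]

  # stage 2: grow-in at sub-optimal drive, nuE = 4 * nuI, identical window
  net <- set_post_curves(net,
                         gauss(4 * nu_grow, 0.25 * psi, psi, 1),
                         gauss(nu_grow, 0.25 * psi, psi, 1))
  net <- run_stage(net, "grow_in", t_grow_s, function(t) I_grow,
                   growth = TRUE, decay = TRUE)
  ratio <- net$state$z[1, 2] / net$state$z[1, 3]

  # stage 3: settle at baseline under the reference post-synaptic curves
  ge <- cfg$growth$E
  net <- set_post_curves(
    net,
    gauss(ge$post_exc$nu * growth_accel, 0.25 * psi, psi,
          ge$post_exc$omega),
    gauss(ge$post_inh$nu * growth_accel, psi, 3.5 * psi,
          ge$post_inh$omega))
  net <- run_stage(net, "settle", t_settle_s, function(t) I_base,
                   growth = TRUE, decay = TRUE)
  z0e <- net$state$z[1, 2]
  z0i <- net$state$z[1, 3]

  # stage 4: sinusoidal modulation
  t_start <- net$state$t / 1000
  net <- run_stage(net, "sinusoid", round(n_cycles * period_s),
                   function(t) I_base + amp * sin(2 * pi * (t - t_start) /
                                                    period_s),
                   growth = TRUE, decay = TRUE)

  ts <- dplyr::bind_rows(rows)
  ts$dg_e <- (ts$z_post_e - z0e) * g_ee
  ts$dg_i <- (ts$z_post_i - z0i) * g_ie
  ts$dg_net <- ts$dg_e - ts$dg_i
  sin_rows <- ts[ts$stage == "sinusoid", ]
  cor_cd <- stats::cor(sin_rows$ca - psi, sin_rows$dg_net)

  out <- list(ts = ts, psi = psi, ratio_after_init = ratio,
              cor_ca_dgnet = cor_cd, z0 = c(post_e = z0e, post_i = z0i))
  class(out) <- "single_neuron_run"
  out
}

#' @export
print.single_neuron_run <- function(x, ...) {
  cat("<single_neuron_run> psi =", signif(x$psi, 4), "\n")
  cat("  z_postE / z_postI after grow-in =", signif(x$ratio_after_init, 6),
      "\n")
  cat("  cor(ca - psi, dg_net) over sinusoid =",
      signif(x$cor_ca_dgnet, 4), "\n")
  invisible(x)
}

#' @export
glance.single_neuron_run <- function(x, ...) {
  tibble::tibble(psi = x$psi, ratio_after_init = x$ratio_after_init,
                 cor_ca_dgnet = x$cor_ca_dgnet)
}

#' @export
autoplot.single_neuron_run <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$ts[, c("t_s", "ca", "dg_net")],
    cols = c("ca", "dg_net"), names_to = "series")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$value)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
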