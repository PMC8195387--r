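#' Growth-curve sets for the axonal growth-regime battery
#'
#' Instantiates per-neuron growth curves for all three element pools
#' (axonal, post-excitatory, post-inhibitory) against each neuron's optimal
#' calcium `psi`. The axonal (pre-synaptic) curves follow the selected
#' regime:
#' \describe{
#'   \item{G0}{no axonal turnover (`nu = 0`).}
#'   \item{G0p}{constant activity-independent axonal sprouting.}
#'   \item{G1}{both excitatory and inhibitory axons sprout above `psi`.}
#'   \item{G2}{the reference configuration: excitatory axons sprout above
#'     `psi`, inhibitory axons sprout below `psi`.}
#'   \item{G3}{the mirror of G2.}
#'   \item{G4}{both axon types sprout at `psi` (peak at the optimum).}
#'   \item{G5}{both axon types sprout below `psi`.}
#' }
#' Post-synaptic curves default to the reference placement (excitatory
#' dendritic elements with stable fixed point `epsilon = psi`, inhibitory
#' with `eta = psi`) and can be switched per pool for the post-synaptic
#' battery: `"eps_psi"` (sprout below `psi`), `"mid"` (`eta < psi <
#' epsilon`), `"eta_psi"` (sprout above `psi`).
#'
#' @param psi Per-neuron optimal calcium (vector, length = neurons).
#' @param pop Character vector of populations ("E"/"I") per neuron.
#' @param cfg Configuration list (growth block used).
#' @param regime Axonal regime tag.
#' @param post_regime List with `post_exc` and `post_inh` placement tags,
#'   or `NULL` for the reference configuration.
#' @return List of per-neuron-by-pool matrices `nu`, `xi`, `zeta`, `om`,
#'   `gconst` consumed by the simulation engine.
#' @export
make_regime_curves <- function(psi, pop, cfg,
                               regime = c("G2", "G0", "G0p", "G1", "G3",
                                          "G4", "G5"),
                               post_regime = NULL) {
  regime <- match.arg(regime)
  n <- length(psi)
  stopifnot(length(pop) == n, all(psi > 0))
  pools <- c("axonal", "post_exc", "post_inh")
  nu <- xi <- zeta <- om <- matrix(0, n, 3)
  gconst <- matrix(0L, n, 3)

  post_tags <- list(eps_psi = c(0.25, 1), mid = c(0.5, 1.5),
                    eta_psi = c(1, 3.5))
  axonal_window <- function(regime, p) {
    above <- c(1, 1.75); below <- c(0.25, 1); mid <- c(0.5, 1.5)
    switch(regime,
           G1 = above,
           G2 = if (p == "E") above else below,
           G3 = if (p == "E") below else above,
           G4 = mid,
           G5 = below,
           NULL)
  }

  for (p in c("E", "I")) {
    sel <- pop == p
    if (!any(sel)) next
    gp <- cfg$growth[[p]]
    for (k in seq_along(pools)) {
      pl <- pools[k]
      base <- gp[[pl]]
      nu_k <- base$nu
      omega_k <- base$omega
      if (pl == "axonal") {
        if (regime == "G0") {
          next # nu stays 0
        } else if (regime == "G0p") {
          nu[sel, k] <- nu_k
          gconst[sel, k] <- 1L
          next
        }
        win <- axonal_window(regime, p)
      } else {
        tag <- post_regime[[pl]]
        win <- if (is.null(tag)) c(base$eta_f, base$eps_f)
               else post_tags[[tag]]
      }
      eta <- win[1] * psi[sel]
      eps <- win[2] * psi[sel]
      nu[sel, k] <- nu_k
      om[sel, k] <- omega_k
      xi[sel, k] <- (eta + eps) / 2
      zeta[sel, k] <- (eps - eta) / (2 * sqrt(-log(omega_k / 2)))
    }
  }
  list(nu = nu, xi = xi, zeta = zeta, om = om, gconst = gconst)
}

# Independent RNG sub-streams (drive / plasticity / sampling) realised by
# swapping saved .Random.seed states, so toggling one mechanism does not
# perturb the random numbers another consumes.
rng_streams <- function(seeds) {
  env <- new.env(parent = emptyenv())
  for (nm in names(seeds)) {
    set.seed(seeds[[nm]])
    env[[nm]] <- get(".Random.seed", globalenv())
  }
  env
}

clone_streams <- function(env) {
  out <- new.env(parent = emptyenv())
  for (nm in ls(env)) out[[nm]] <- env[[nm]]
  out
}

eval_with_stream <- function(env, name, fn) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  assign(".Random.seed", env[[name]], globalenv())
  res <- fn()
  env[[name]] <- get(".Random.seed", globalenv())
  if (had) assign(".Random.seed", old, globalenv())
  res
}

# Per-chunk region/population mean rates from engine spike counts.
chunk_rates <- function(layout, spike_count, t_s, dur_s) {
  df <- tibble::tibble(pop = layout$pop, region = layout$region,
                       n_sp = spike_count)
  out <- dplyr::summarise(dplyr::group_by(df, .data$pop, .data$region),
                          rate_hz = mean(.data$n_sp) / dur_s,
                          .groups = "drop")
  out$t_s <- t_s
  out
}

#' Balance a fresh network and record its steady state
#'
#' Phase 1 of every experiment. Until `t1` only the inhibitory STDP rule is
#' active, growing IE conductances from zero until the network settles into
#' its balanced low-rate asynchronous irregular (AI) state. At `t1` the
#' steady state is recorded: each neuron's optimal calcium `psi` (its
#' calcium trace at `t1`, floored at a small positive value so growth
#' curves stay well defined for silent neurons), the mean learned IE
#' conductance (also used to initialise new IE synapses), and the deletion
#' immunity threshold `g_th` (set to that mean). Growth curves are then
#' instantiated against `psi`, element counts are initialised to the
#' connected counts, and — when the structural toggle is on — structural
#' plasticity runs from `t1` to `t2` to verify that the network stays
#' balanced under both homeostatic mechanisms.
#'
#' @param net A fresh `spiking_network` from [build_network()].
#' @param ai_window_s Raster window (s) kept before `t1` and before `t2`
#'   for AI-state evaluation.
#' @param phase_a Optional phase-1a checkpoint (the `phase_a` element of a
#'   previous result) to reuse across mechanism-toggle experiments.
#' @param progress Print per-chunk progress.
#' @return A `balance_phase` list: updated `net`, `ai` (AI criterion at
#'   `t1`), `cc` (sampled pairwise correlation), `rates`, `syn_count`,
#'   `struct_log`, rasters, and the recorded `psi`, `ie_mean`, `g_th`.
#' @export
run_balance_phase <- function(net, ai_window_s = 10, phase_a = NULL,
                              progress = FALSE) {
  cfg <- net$cfg
  t1 <- cfg$protocol$t1_s
  t2 <- cfg$protocol$t2_s
  chunk_s <- cfg$struct_interval_s
  if (is.null(net$rng)) net$rng <- rng_streams(cfg$seeds)

  rates <- list(); raster_a <- list()
  if (is.null(phase_a)) {
    while (net$state$t / 1000 < t1 - 1e-9) {
      t_now <- net$state$t / 1000
      keep <- t_now >= t1 - ai_window_s - 1e-9
      res <- eval_with_stream(net$rng, "drive", function() {
        simulate_interval(net, chunk_s * 1000, istdp = TRUE,
                          growth = FALSE, record_spikes = keep)
      })
      net <- res$net
      rates[[length(rates) + 1L]] <-
        chunk_rates(net$layout, res$spike_count, t_now + chunk_s, chunk_s)
      if (keep) raster_a[[length(raster_a) + 1L]] <- res$spikes
      if (progress && (length(rates) %% 10 == 0)) {
        message(sprintf("balance t = %.0f s, mean rate %.2f Hz",
                        net$state$t / 1000,
                        sum(res$spike_count) / nrow(net$layout) / chunk_s))
      }
    }
    raster_a <- dplyr::bind_rows(raster_a)
    phase_a <- list(net = net, raster = raster_a,
                    rates = dplyr::bind_rows(rates))
  } else {
    net_a <- phase_a$net
    net_a$cfg <- cfg # allow toggle variations downstream
    net_a$rng <- clone_streams(net_a$rng)
    net <- net_a
    raster_a <- phase_a$raster
    rates <- list(phase_a$rates)
  }

  # steady-state recording at t1
  psi <- pmax(net$state$ca, 0.05)
  ie <- net$syn$g[net$syn$class == "IE"]
  ie_mean <- if (length(ie)) mean(ie) else 0
  net$psi <- psi
  net$ie_mean <- ie_mean
  net$g_th <- ie_mean
  net$curves <- make_regime_curves(psi, net$layout$pop, cfg,
                                   regime = cfg$regime)
  net$state$z <- connected_counts(net) * 1.0

  ai <- is_ai_state(raster_a, ids = net$layout$id,
                    t_range = c(t1 - ai_window_s, t1) * 1000)
  cc <- eval_with_stream(net$rng, "sampling", function() {
    pairwise_cc(raster_a, ids = net$layout$id,
                t_range = c(t1 - ai_window_s, t1) * 1000)
  })
  if (!isTRUE(ai$ai)) {
    warning("network failed the AI criterion at t1 (ISI CV = ",
            signif(ai$isi_cv, 3), ", sigma_rate = ",
            signif(ai$sigma_rate, 3), " Hz)")
  }

  # verification window t1 -> t2 with structural plasticity (per toggles)
  struct_log <- list(); syn_count <- list(); raster_b <- list()
  istdp_on <- isTRUE(cfg$toggles$istdp)
  struct_on <- isTRUE(cfg$toggles$structural)
  while (net$state$t / 1000 < t2 - 1e-9) {
    t_now <- net$state$t / 1000
    keep <- t_now >= t2 - ai_window_s - 1e-9
    res <- eval_with_stream(net$rng, "drive", function() {
      simulate_interval(net, chunk_s * 1000, istdp = istdp_on,
                        growth = struct_on, record_spikes = keep)
    })
    net <- res$net
    rates[[length(rates) + 1L]] <-
      chunk_rates(net$layout, res$spike_count, t_now + chunk_s, chunk_s)
    if (keep) raster_b[[length(raster_b) + 1L]] <- res$spikes
    if (struct_on) {
      upd <- eval_with_stream(net$rng, "plasticity", function() {
        structural_update(net)
      })
      net <- upd$net
      struct_log[[length(struct_log) + 1L]] <- upd$log
    }
    syn_count[[length(syn_count) + 1L]] <-
      tibble::tibble(t_s = net$state$t / 1000, n_syn = nrow(net$syn))
  }

  out <- list(
    net = net, ai = ai, cc = cc,
    rates = dplyr::bind_rows(rates),
    syn_count = dplyr::bind_rows(syn_count),
    struct_log = dplyr::bind_rows(struct_log),
    raster_t1 = raster_a,
    raster_t2 = dplyr::bind_rows(raster_b),
    psi = psi, ie_mean = ie_mean, g_th = ie_mean,
    phase_a = phase_a
  )
  class(out) <- "balance_phase"
  out
}

#' Deafferent the lesion projection zone
#'
#' Permanently disconnects the external Poisson drive from every neuron —
#' excitatory and inhibitory — whose region is LPZ_C or LPZ_B. Recurrent
#' synapses are untouched.
#'
#' @param net A `spiking_network`.
#' @return The lesioned network.
#' @export
deafferent <- function(net) {
  if (isTRUE(net$deafferented)) stop("network is already deafferented")
  lpz <- net$layout$region %in% c("LPZ_C", "LPZ_B")
  net$ext_on[lpz] <- FALSE
  net$state$next_ext[lpz] <- Inf
  net$deafferented <- TRUE
  net
}

#' Run a full lesion-and-repair experiment
#'
#' Balances the network (or reuses a supplied balanced state), deafferents
#' the LPZ at `t2`, and lets the network reorganise under the configured
#' mechanism toggles and growth regime until `t_end`. Produces everything
#' the analysis metrics need: region-resolved rate time series,
#' region-by-class connectivity snapshots, rasters around the lesion and at
#' the end of the run, and the structural-update log. Runs whose population
#' rate exceeds `rate_ceiling_mult` times the balanced mean for
#' `ceiling_sustain_s` are terminated early and flagged (`runaway`) — an
#' expected outcome for some regimes and for structural-only repair.
#'
#' @param fx A fixture list (`cfg`, `layout`, `syn`) from [make_fixture()].
#' @param balanced Optional `balance_phase` result to continue from.
#' @param raster_window_s Length (s) of the rasters kept after the lesion
#'   and before `t_end`.
#' @param progress Print per-chunk progress.
#' @return A `repair_run` object.
#' @export
run_lesion_experiment <- function(fx, balanced = NULL,
                                  raster_window_s = 60, progress = FALSE) {
  cfg <- fx$cfg
  if (is.null(balanced)) {
    net <- build_network(fx$layout, fx$syn, cfg)
    balanced <- run_balance_phase(net, progress = progress)
  }
  net <- balanced$net
  net$cfg <- cfg
  net$rng <- clone_streams(net$rng)
  t2 <- cfg$protocol$t2_s
  t_end <- cfg$protocol$t_end_s
  chunk_s <- cfg$struct_interval_s
  istdp_on <- isTRUE(cfg$toggles$istdp)
  struct_on <- isTRUE(cfg$toggles$structural)
  snap_every <- cfg$protocol$snapshot_every_s

  pre_rates <- dplyr::summarise(
    dplyr::group_by(
      dplyr::filter(balanced$rates, .data$t_s > t2 - 10),
      .data$pop, .data$region),
    rate_hz = mean(.data$rate_hz), .groups = "drop")
  balanced_mean <- mean(
    dplyr::filter(balanced$rates, .data$t_s > t2 - 10)$rate_hz)
  ceiling_hz <- cfg$protocol$rate_ceiling_mult * max(balanced_mean, 1)

  net <- deafferent(net)
  snapshot <- function(t_s) {
    s <- region_connectivity_summary(net$syn, net$layout)
    s$t_s <- t_s
    s
  }
  conn <- list(snapshot(t2))
  rates <- list(); struct_log <- list(); rasters <- list()
  over_since <- NA_real_
  runaway <- FALSE

  while (net$state$t / 1000 < t_end - 1e-9) {
    t_now <- net$state$t / 1000
    keep <- (t_now < t2 + raster_window_s) ||
      (t_now >= t_end - raster_window_s - 1e-9)
    res <- eval_with_stream(net$rng, "drive", function() {
      simulate_interval(net, chunk_s * 1000, istdp = istdp_on,
                        growth = struct_on, record_spikes = keep)
    })
    net <- res$net
    rates[[length(rates) + 1L]] <-
      chunk_rates(net$layout, res$spike_count, t_now + chunk_s, chunk_s)
    if (keep) rasters[[length(rasters) + 1L]] <- res$spikes
    if (struct_on) {
      upd <- eval_with_stream(net$rng, "plasticity", function() {
        structural_update(net)
      })
      net <- upd$net
      struct_log[[length(struct_log) + 1L]] <- upd$log
    }
    t_now <- net$state$t / 1000
    if (abs(t_now %% snap_every) < 1e-6 ||
        abs(t_now %% snap_every - snap_every) < 1e-6) {
      conn[[length(conn) + 1L]] <- snapshot(t_now)
    }
    mean_rate <- sum(res$spike_count) / nrow(net$layout) / chunk_s
    if (mean_rate > ceiling_hz) {
      if (is.na(over_since)) over_since <- t_now
      if (t_now - over_since >= cfg$protocol$ceiling_sustain_s) {
        runaway <- TRUE
        warning("population rate exceeded the instability ceiling (",
                signif(mean_rate, 4), " Hz > ", signif(ceiling_hz, 4),
                " Hz sustained); terminating with partial outputs")
        break
      }
    } else {
      over_since <- NA_real_
    }
    if (progress && (length(rates) %% 20 == 0)) {
      message(sprintf("repair t = %.0f s, mean rate %.2f Hz, %d synapses",
                      t_now, mean_rate, nrow(net$syn)))
    }
  }
  conn[[length(conn) + 1L]] <- snapshot(net$state$t / 1000)

  out <- list(
    cfg = cfg, net = net,
    pre_rates = pre_rates,
    balanced_mean = balanced_mean,
    rates = dplyr::bind_rows(rates),
    conn = dplyr::bind_rows(conn),
    raster = dplyr::bind_rows(rasters),
    struct_log = dplyr::bind_rows(struct_log),
    balance = list(ai = balanced$ai, cc = balanced$cc,
                   syn_count = balanced$syn_count,
                   rates = balanced$rates),
    runaway = runaway,
    raster_window_s = raster_window_s,
    t2 = t2, t_end_reached = net$state$t / 1000
  )
  class(out) <- "repair_run"
  out
}

#' @export
print.repair_run <- function(x, ...) {
  cat("<repair_run> regime", x$cfg$regime, "| toggles: istdp =",
      x$cfg$toggles$istdp, ", structural =", x$cfg$toggles$structural, "\n")
  cat("  lesion at", x$t2, "s; ran to", x$t_end_reached, "s",
      if (x$runaway) "(terminated: rate ceiling)" else "", "\n")
  invisible(x)
}

#' @export
glance.repair_run <- function(x, ...) {
  final <- dplyr::filter(x$rates, .data$t_s > x$t_end_reached - 10)
  lpz_c <- mean(dplyr::filter(final, .data$region == "LPZ_C")$rate_hz)
  pre_c <- mean(dplyr::filter(x$pre_rates,
                              .data$region == "LPZ_C")$rate_hz)
  tibble::tibble(
    regime = x$cfg$regime,
    istdp = x$cfg$toggles$istdp,
    structural = x$cfg$toggles$structural,
    runaway = x$runaway,
    t_end_s = x$t_end_reached,
    n_synapses = nrow(x$net$syn),
    lpz_c_rate_pre = pre_c,
    lpz_c_rate_final = lpz_c
  )
}
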