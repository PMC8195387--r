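#' Default run configuration
#'
#' The complete parameter inventory of the model with full-scale defaults:
#' neuron constants, synapse and STDP constants, spatial/network constants,
#' growth-rule parameters for every element pool of both populations, the
#' two-phase experiment schedule, mechanism toggles, the growth-regime tag
#' and the independent seed streams. Growth-curve positions are expressed
#' as multiples of each neuron's optimal calcium `psi`; scaling factors
#' `nu` are stored per second (the printed per-step values divided by the
#' 0.1 s growth step).
#'
#' `istdp_accel` and `growth_accel` multiply the STDP learning rate and all
#' growth-curve scaling factors; they default to 1 (the full-scale study
#' conditions) and are raised only in desk-scale fixtures, where the
#' acceleration factor is recorded in the run manifest.
#'
#' @param ... Named overrides, nested lists merged recursively (unknown
#'   keys are rejected).
#' @return A nested configuration list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    scale = 1,
    dt_membrane_ms = 0.1,
    dt_growth_s = 0.1,
    struct_interval_s = 1,
    istdp_accel = 1,
    growth_accel = 1,
    regime = "G2",
    neuron = unclass(neuron_params()),
    synapse = list(
      gbar = 0.5, g_sd = 0.1, g_II_mult = 10,
      g_ext_E = 8, g_ext_I = 12, rate_ext = 10,
      tau_stdp = 20, alpha = 0.12, eta_stdp = 0.05,
      w_E = 8, w_I = 24, p_hat_E = 0.8, p_hat_I = 0.3
    ),
    network = list(p = 0.02, mu_d_e = 150, sigma_d = 15,
                   fractions = c(0.025, 0.025, 0.05)),
    growth = list(
      tau_free = 0.01,
      E = list(
        axonal   = list(nu = 1.5e-2, omega = 1e-2, eta_f = 1, eps_f = 1.75),
        post_exc = list(nu = 3e-4, omega = 0.4, eta_f = 0.25, eps_f = 1),
        post_inh = list(nu = 3e-3, omega = 4e-2, eta_f = 1, eps_f = 3.5)
      ),
      I = list(
        axonal   = list(nu = 0.3, omega = 4e-4, eta_f = 0.25, eps_f = 1),
        post_exc = list(nu = 3e-4, omega = 0.4, eta_f = 0.25, eps_f = 1),
        post_inh = list(nu = 3e-4, omega = 0.4, eta_f = 1, eps_f = 3.5)
      )
    ),
    protocol = list(t1_s = 1500, t2_s = 2000, t_end_s = 18000,
                    rate_ceiling_mult = 10, ceiling_sustain_s = 10,
                    snapshot_every_s = 10),
    toggles = list(istdp = TRUE, structural = TRUE),
    seeds = list(placement = 101, wiring = 202, drive = 303,
                 plasticity = 404, sampling = 505)
  )
  cfg <- merge_config(cfg, list(...), path = "")
  class(cfg) <- c("run_config", "list")
  cfg
}

# Recursive merge rejecting keys absent from the defaults (typo safety).
merge_config <- function(base, override, path = "") {
  if (length(override) == 0) return(base)
  nms <- names(override)
  if (is.null(nms) || any(nms == "")) {
    stop("configuration overrides must be named (at '", path, "')")
  }
  for (j in seq_along(override)) {
    nm <- nms[j]
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base)) {
      stop("unknown configuration key: '", key, "'")
    }
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(override[[j]])) {
        stop("configuration key '", key, "' expects a nested block")
      }
      base[[nm]] <- merge_config(base[[nm]], override[[j]], key)
    } else {
      base[[nm]] <- override[[j]]
    }
  }
  base
}

#' Load a configuration file
#'
#' Reads a JSON (or YAML, by extension) configuration; unspecified keys
#' take the full-scale defaults and unknown keys are rejected with their
#' full key path.
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return A `run_config` list.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configurations")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(raw)) raw <- list()
  do.call(default_config, raw)
}

#' Write a configuration to JSON
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate a desk-scale fixture network
#'
#' Builds a miniature network that preserves the full-scale ratios: 4:1
#' E:I, initial sparsity `p`, region fractions, spacing and all per-neuron
#' parameters. Placement and wiring use the configuration's independent
#' seed streams, so two fixtures built from equal seeds are identical.
#'
#' @param scale Scale factor (must admit an even-by-even excitatory
#'   lattice, e.g. 0.05, 0.1, 0.2, 0.5).
#' @param seed Base seed; offsets derive the placement/wiring streams.
#' @param dir Optional directory: when given, `layout.csv`, `edges.csv`
#'   and `config.json` are written there.
#' @param overrides A list of configuration overrides (e.g.
#'   [desk_overrides()]), applied before `...`.
#' @param ... Further configuration overrides.
#' @return List with `cfg`, `layout` (region-labelled) and `syn`.
#' @export
make_fixture <- function(scale = 0.2, seed = 1, dir = NULL,
                         overrides = list(), ...) {
  cfg <- do.call(default_config, c(
    list(scale = scale,
         seeds = list(placement = seed + 11L, wiring = seed + 23L,
                      drive = seed + 37L, plasticity = seed + 53L,
                      sampling = seed + 71L)),
    overrides, list(...)))
  layout <- place_neurons(scale = scale, mu_d_e = cfg$network$mu_d_e,
                          sigma_d = cfg$network$sigma_d,
                          seed = cfg$seeds$placement)
  layout <- classify_regions(layout, cfg$network$fractions)
  syn <- wire_initial(layout, p = cfg$network$p, gbar = cfg$synapse$gbar,
                      g_sd = cfg$synapse$g_sd, w_e = cfg$synapse$w_E,
                      w_i = cfg$synapse$w_I, seed = cfg$seeds$wiring)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_layout(layout, file.path(dir, "layout.csv"))
    write_edges(syn, file.path(dir, "edges.csv"), t_s = 0)
    save_config(cfg, file.path(dir, "config.json"))
  }
  list(cfg = cfg, layout = layout, syn = syn)
}

#' Desk-scale experiment overrides
#'
#' The canonical accelerated protocol for desk-scale (0.2) fixtures, used
#' by the test suite and the worked examples. Scaling the network down by
#' a factor of five leaves each neuron with a fifth of its recurrent
#' synapses, so the recurrent conductance scale is raised (unit
#' conductance 2 nS instead of 0.5 nS) to preserve per-neuron recurrent
#' input, and the external conductances are doubled (16/24 nS) so that
#' the external share of each neuron's drive — the share removed by
#' deafferentation — remains dominant as at full scale. The inhibitory STDP learning
#' rate is accelerated tenfold so the balanced state is reached within a
#' minute of simulated time, and the growth-curve scaling factors are
#' accelerated (non-uniformly: the per-pool factors below) so that the
#' months-long biological repair, already compressed to hours in the
#' full-scale model, completes within a five-minute simulated repair
#' window. All accelerations are recorded in the run manifest via the
#' configuration they produce.
#'
#' @param t1_s,t2_s,t_end_s Desk phase schedule (s).
#' @return A named list of configuration overrides for [make_fixture()].
#' @export
desk_overrides <- function(t1_s = 60, t2_s = 80, t_end_s = 380) {
  list(
    # kernel widths shrink with the linear size of the sheet
    # (sqrt(0.2) of the full-scale 8 / 24) so the reach of excitatory and
    # inhibitory projections relative to the LPZ radius is preserved
    synapse = list(gbar = 1.25, g_ext_E = 16, g_ext_I = 24,
                   w_E = 3.6, w_I = 10.8),
    istdp_accel = 10,
    protocol = list(t1_s = t1_s, t2_s = t2_s, t_end_s = t_end_s,
                    snapshot_every_s = 10),
    growth = list(
      E = list(
        axonal   = list(nu = 0.3),   # 1.5e-2/s at full scale
        post_exc = list(nu = 0.6),   # 3e-4/s
        post_inh = list(nu = 1.0)    # 3e-3/s
      ),
      I = list(
        axonal   = list(nu = 5),     # 0.3/s
        post_exc = list(nu = 0.6),   # 3e-4/s
        post_inh = list(nu = 0.15)   # 3e-4/s
      )
    )
  )
}

#' Write a run manifest
#'
#' Records everything needed to reproduce or audit a run: a configuration
#' hash, the seed streams, phase boundary times, acceleration factors, the
#' scale (flagging desk-scale runs), and the output files with their
#' phases.
#'
#' @param run A run object (e.g. from [run_lesion_experiment()]) or a list
#'   with at least a `cfg` element.
#' @param path Output JSON path.
#' @param files Optional named character vector of output files by phase.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(run, path, files = character()) {
  cfg <- run$cfg
  manifest <- list(
    package_version = as.character(utils::packageVersion("neuroregrow")),
    config_hash = rlang::hash(unclass(cfg)),
    seeds = cfg$seeds,
    scale = cfg$scale,
    full_scale = isTRUE(all.equal(cfg$scale, 1)),
    phase_boundaries_s = list(t1 = cfg$protocol$t1_s, t2 = cfg$protocol$t2_s,
                              t_end = cfg$protocol$t_end_s),
    deafferentation_s = cfg$protocol$t2_s,
    acceleration = list(istdp = cfg$istdp_accel, growth = cfg$growth_accel),
    regime = cfg$regime,
    toggles = cfg$toggles,
    outputs = as.list(files)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
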