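#' Repair-feature checklist
#'
#' Evaluates the eight experimentally motivated repair features on the
#' artefacts of a lesion run. The underlying observations are qualitative,
#' so every threshold is exposed with a stated default:
#' \enumerate{
#'   \item network initially remains stable (pre-lesion synapse count
#'     varies by < `syn_var`, background rate drift < `stability_drift`);
#'   \item LPZ-C activity collapses (below `collapse_frac` of its
#'     pre-lesion rate) and then recovers (final rate at least
#'     `recovery_frac` of pre-lesion);
#'   \item neurons outside the LPZ transiently gain activity (peri-LPZ
#'     rate above `peri_rise_frac` of pre-lesion) and return to within
#'     `band_frac` of it;
#'   \item the network reaches a stable final state (no runaway, final
#'     background rate within `band_frac` of pre-lesion, drift between the
#'     two final windows < `final_drift`);
#'   \item LPZ-B activity recovers before LPZ-C;
#'   \item excitatory ingrowth: EE projections from outside the LPZ into
#'     LPZ-C increase over the repair period;
#'   \item inhibitory outgrowth: inhibitory projections from LPZ sources
#'     to targets outside the LPZ increase;
#'   \item transient dis-inhibition: the count of inhibitory inputs to
#'     LPZ-C excitatory neurons dips below its pre-lesion value (by more
#'     than `dip_frac`) before growing back.
#' }
#' Features that cannot be evaluated on the available artefacts (e.g.
#' after an early instability stop) are reported as `NA`.
#'
#' @param run A `repair_run` from [run_lesion_experiment()].
#' @param recovery_frac,collapse_frac,peri_rise_frac,band_frac Rate
#'   thresholds, as fractions of the pre-lesion rate.
#' @param dip_frac,stability_drift,final_drift,syn_var Change thresholds
#'   for the dis-inhibition dip, pre-lesion rate drift, final-state
#'   drift, and synapse-count variation.
#' @param sustain_s Averaging window (s) for "final" rates.
#' @return Tibble with `feature`, `status` (logical, `NA` = not
#'   evaluable), `detail`.
#' @export
repair_feature_checklist <- function(run, recovery_frac = 0.5,
                                     collapse_frac = 0.25,
                                     peri_rise_frac = 1.05,
                                     band_frac = 0.5, dip_frac = 0.05,
                                     stability_drift = 0.25,
                                     final_drift = 0.25, syn_var = 0.05,
                                     sustain_s = 20) {
  t2 <- run$t2
  t_done <- run$t_end_reached
  smooth5 <- function(v) as.numeric(stats::filter(v, rep(1 / 5, 5),
                                                  sides = 2))
  reg_series <- function(reg) {
    d <- run$rates[run$rates$pop == "E" &
                     as.character(run$rates$region) == reg, ]
    d <- d[order(d$t_s), ]
    d$sm <- smooth5(d$rate_hz)
    d
  }
  pre_rate <- function(reg) {
    pr <- run$pre_rates
    mean(pr$rate_hz[pr$pop == "E" & as.character(pr$region) == reg])
  }
  final_mean <- function(d) mean(utils::tail(d$rate_hz, sustain_s))

  lpz_c <- reg_series("LPZ_C"); lpz_b <- reg_series("LPZ_B")
  peri <- reg_series("peri_LPZ"); other <- reg_series("other")
  pre_c <- pre_rate("LPZ_C"); pre_b <- pre_rate("LPZ_B")
  pre_p <- pre_rate("peri_LPZ"); pre_o <- pre_rate("other")

  status <- rep(NA, 8)
  detail <- character(8)

  # 1. initial stability (pre-lesion verification window)
  sc <- run$balance$syn_count
  syn_ok <- if (nrow(sc) > 0) {
    (max(sc$n_syn) - min(sc$n_syn)) / sc$n_syn[1] < syn_var
  } else TRUE
  bal <- run$balance$rates
  t1_approx <- min(sc$t_s %||% t2)
  r_early <- mean(dplyr::filter(bal, .data$pop == "E",
                                .data$region == "other",
                                .data$t_s > t1_approx - 5,
                                .data$t_s <= t1_approx)$rate_hz)
  r_late <- mean(dplyr::filter(bal, .data$pop == "E",
                               .data$region == "other",
                               .data$t_s > t2 - 5)$rate_hz)
  rate_ok <- is.finite(r_early) && is.finite(r_late) && r_early > 0 &&
    abs(r_late - r_early) / r_early < stability_drift
  status[1] <- syn_ok && rate_ok
  detail[1] <- sprintf("syn count var ok: %s; rate %0.2f -> %0.2f Hz",
                       syn_ok, r_early, r_late)

  # 2. LPZ-C collapse and recovery
  if (nrow(lpz_c) > sustain_s) {
    collapsed <- min(lpz_c$sm, na.rm = TRUE) < collapse_frac * pre_c
    final_c <- final_mean(lpz_c)
    recovered <- final_c >= recovery_frac * pre_c
    status[2] <- collapsed && recovered
    detail[2] <- sprintf(
      "pre %0.2f Hz, min %0.2f, final %0.2f (need >= %0.2f)",
      pre_c, min(lpz_c$sm, na.rm = TRUE), final_c, recovery_frac * pre_c)
  }

  # 3. peri-LPZ transient rise then normalisation
  if (nrow(peri) > sustain_s) {
    early <- dplyr::filter(peri, .data$t_s <= t2 + 100)
    rose <- max(early$sm, na.rm = TRUE) > peri_rise_frac * pre_p
    final_p <- final_mean(peri)
    normal <- abs(final_p - pre_p) <= band_frac * pre_p
    status[3] <- rose && normal
    detail[3] <- sprintf("pre %0.2f Hz, early peak %0.2f, final %0.2f",
                         pre_p, max(early$sm, na.rm = TRUE), final_p)
  }

  # 4. stable final state
  if (!run$runaway && nrow(other) > 2 * sustain_s) {
    final_o <- final_mean(other)
    prev_o <- mean(other$rate_hz[(nrow(other) - 2 * sustain_s + 1):
                                   (nrow(other) - sustain_s)])
    in_band <- abs(final_o - pre_o) <= band_frac * pre_o
    drift_ok <- is.finite(prev_o) && prev_o > 0 &&
      abs(final_o - prev_o) / prev_o < final_drift
    status[4] <- in_band && drift_ok
    detail[4] <- sprintf("background pre %0.2f Hz, final %0.2f", pre_o,
                         final_o)
  } else if (run$runaway) {
    status[4] <- FALSE
    detail[4] <- "terminated at the instability rate ceiling"
  }

  # 5. LPZ-B recovers before LPZ-C. Region rates reignite in shared
  # network bursts, so the ordering is evaluated per neuron as the median
  # time of the first post-lesion spike over the region's excitatory
  # neurons (neurons silent throughout the post-lesion raster window
  # count as never-recovered).
  rw <- run$raster_window_s %||% 0
  k_spk <- 1L
  reactivation <- function(reg) {
    ids <- run$net$layout$id[run$net$layout$pop == "E" &
                               as.character(run$net$layout$region) == reg]
    sp <- run$raster[run$raster$id %in% ids &
                       run$raster$t_ms > t2 * 1000 &
                       run$raster$t_ms <= (t2 + rw) * 1000, ]
    kth <- vapply(ids, function(i) {
      tt <- sort(sp$t_ms[sp$id == i])
      if (length(tt) < k_spk) Inf else tt[k_spk] / 1000
    }, numeric(1))
    stats::median(kth)
  }
  if (nrow(run$raster) > 0 && rw > 0) {
    tb <- reactivation("LPZ_B")
    tc <- reactivation("LPZ_C")
    if (is.finite(tb) || is.finite(tc)) {
      status[5] <- tb < tc
      detail[5] <- sprintf(
        "median reactivation: LPZ-B %0.1f s, LPZ-C %0.1f s", tb, tc)
    } else {
      detail[5] <- "neither LPZ region reactivated in the raster window"
    }
  } else {
    detail[5] <- "no post-lesion raster available"
  }

  # connectivity-based features from the snapshot series
  conn <- run$conn
  series <- function(cls, src, tgt) {
    d <- dplyr::filter(conn, .data$class %in% cls,
                       .data$src_region %in% src,
                       .data$tgt_region %in% tgt)
    dplyr::summarise(dplyr::group_by(d, .data$t_s),
                     n = sum(.data$n), .groups = "drop")
  }
  outside <- c("peri_LPZ", "other")
  lpz <- c("LPZ_C", "LPZ_B")

  if (nrow(conn) > 0) {
    s6 <- series("EE", outside, "LPZ_C")
    if (nrow(s6) >= 2) {
      status[6] <- utils::tail(s6$n, 1) > s6$n[1]
      detail[6] <- sprintf("EE outside->LPZ-C: %d -> %d", s6$n[1],
                           utils::tail(s6$n, 1))
    }
    s7 <- series(c("IE", "II"), lpz, outside)
    if (nrow(s7) >= 2) {
      status[7] <- utils::tail(s7$n, 1) > s7$n[1]
      detail[7] <- sprintf("I LPZ->outside: %d -> %d", s7$n[1],
                           utils::tail(s7$n, 1))
    }
    s8 <- series("IE", levels(run$net$layout$region), "LPZ_C")
    if (nrow(s8) >= 3) {
      n0 <- s8$n[1]
      nmin <- min(s8$n)
      dipped <- nmin < (1 - dip_frac) * n0
      regrew <- utils::tail(s8$n, 1) > nmin
      status[8] <- dipped && regrew
      detail[8] <- sprintf("I inputs to LPZ-C: %d, min %d, final %d", n0,
                           nmin, utils::tail(s8$n, 1))
    }
  }

  tibble::tibble(
    feature = c("initial_stability", "lpz_rate_recovery",
                "outside_rate_normalisation", "stable_final_state",
                "lpz_b_before_lpz_c", "excitatory_ingrowth",
                "inhibitory_outgrowth", "transient_disinhibition"),
    status = as.logical(status),
    detail = detail
  )
}
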