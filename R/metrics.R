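#' Sliding-window firing-rate map
#'
#' Per-neuron firing rates computed in a sliding window (default 2500 ms)
#' advanced in fixed increments (default 100 ms).
#'
#' @param spikes Raster tibble (`id`, `t_ms`).
#' @param ids Neuron ids to include (silent neurons get 0 Hz rows).
#' @param t_range Analysis interval `c(from_ms, to_ms)`.
#' @param window Window length (ms). Default 2500.
#' @param step Window increment (ms). Default 100.
#' @return Tibble `id`, `t_ms` (window end), `rate_hz`.
#' @export
rate_map <- function(spikes, ids, t_range, window = 2500, step = 100) {
  stopifnot(window > 0, step > 0, diff(t_range) >= window)
  nb <- floor(diff(t_range) / step)
  sp <- spikes[spikes$id %in% ids & spikes$t_ms > t_range[1] &
                 spikes$t_ms <= t_range[1] + nb * step, ]
  idf <- factor(sp$id, levels = ids)
  bin <- floor((sp$t_ms - t_range[1] - 1e-9) / step) + 1L
  counts <- matrix(0L, length(ids), nb)
  if (nrow(sp) > 0) {
    tb <- table(idf, factor(bin, levels = seq_len(nb)))
    counts <- matrix(as.integer(tb), length(ids), nb)
  }
  k <- round(window / step)
  cs <- cbind(0L, t(apply(counts, 1, cumsum)))
  wins <- k:nb
  rates <- (cs[, wins + 1L, drop = FALSE] - cs[, wins - k + 1L,
                                               drop = FALSE]) /
    (window / 1000)
  tibble::tibble(
    id = rep(ids, times = length(wins)),
    t_ms = rep(t_range[1] + wins * step, each = length(ids)),
    rate_hz = as.vector(rates)
  )
}

#' Mean coefficient of variation of inter-spike intervals
#'
#' Per neuron, CV = SD(ISI)/mean(ISI); neurons with fewer than two ISIs
#' (three spikes) are excluded. Returns `NA` with an attribute flag when no
#' neuron qualifies — irregularity is undefined in the absence of spiking,
#' not an error.
#'
#' @param spikes Raster tibble (`id`, `t_ms`).
#' @param ids Neuron subset to evaluate.
#' @param t_range Optional analysis interval (ms).
#' @return Mean CV over qualifying neurons, or `NA`.
#' @export
isi_cv <- function(spikes, ids = unique(spikes$id), t_range = NULL) {
  sp <- spikes[spikes$id %in% ids, ]
  if (!is.null(t_range)) {
    sp <- sp[sp$t_ms >= t_range[1] & sp$t_ms <= t_range[2], ]
  }
  if (nrow(sp) == 0) return(NA_real_)
  cvs <- vapply(split(sp$t_ms, sp$id), function(tt) {
    if (length(tt) < 3) return(NA_real_)
    isi <- diff(sort(tt))
    stats::sd(isi) / mean(isi)
  }, numeric(1))
  cvs <- cvs[!is.na(cvs)]
  if (length(cvs) == 0) return(NA_real_)
  mean(cvs)
}

#' Sampled mean pairwise spike-train cross-correlation
#'
#' Bins each train (default 5 ms), computes the Pearson correlation for
#' every sampled pair and averages. Zero-variance trains are excluded.
#' Sampling rule: all neurons when the population has at most 800, else
#' the larger of 800 and 10% of the population.
#'
#' @param spikes Raster tibble (`id`, `t_ms`).
#' @param ids Ids of the population to sample from.
#' @param t_range Analysis interval (ms).
#' @param bin Bin width (ms). Default 5.
#' @param seed Optional sampling-stream seed.
#' @return Mean pairwise correlation (`NA` when fewer than two trains
#'   qualify).
#' @export
pairwise_cc <- function(spikes, ids, t_range, bin = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_pop <- length(ids)
  n_s <- cc_sample_size(n_pop)
  take <- if (n_s >= n_pop) ids else sort(sample(ids, n_s))
  sp <- spikes[spikes$id %in% take & spikes$t_ms > t_range[1] &
                 spikes$t_ms <= t_range[2], ]
  nb <- floor(diff(t_range) / bin)
  sp <- sp[sp$t_ms <= t_range[1] + nb * bin, ]
  idf <- factor(sp$id, levels = take)
  bidx <- floor((sp$t_ms - t_range[1] - 1e-9) / bin) + 1L
  m <- matrix(as.integer(table(idf, factor(bidx, levels = seq_len(nb)))),
              length(take), nb)
  v <- apply(m, 1, stats::var)
  m <- m[v > 0, , drop = FALSE]
  if (nrow(m) < 2) return(NA_real_)
  cc <- stats::cor(t(m))
  mean(cc[upper.tri(cc)])
}

# Sampling rule for the pairwise-correlation estimate.
cc_sample_size <- function(n_pop) {
  if (n_pop <= 800) n_pop else max(800, ceiling(0.1 * n_pop))
}

#' Asynchronous-irregular state criterion
#'
#' A population is in the asynchronous irregular (AI) regime when the mean
#' ISI CV exceeds 1 (irregular single-neuron spiking) and the standard
#' deviation of the instantaneous population firing rate is below 5 Hz
#' (no strong population fluctuations). The population rate is estimated
#' from the population spike histogram at the correlation bin width
#' (5 ms), expressed in Hz per neuron. Component values are always
#' returned.
#'
#' @param spikes Raster tibble (`id`, `t_ms`).
#' @param ids Population ids.
#' @param t_range Analysis interval (ms).
#' @param cv_threshold Strict lower ISI-CV bound. Default 1.
#' @param rate_sd_threshold Strict upper population-rate-SD bound (Hz).
#'   Default 5.
#' @param bin Population histogram bin (ms). Default 5.
#' @return List of class `ai_state`: `ai` flag, `isi_cv`, `sigma_rate`,
#'   `mean_rate`.
#' @export
is_ai_state <- function(spikes, ids, t_range, cv_threshold = 1,
                        rate_sd_threshold = 5, bin = 5) {
  cv <- isi_cv(spikes, ids, t_range)
  sp <- spikes[spikes$id %in% ids & spikes$t_ms > t_range[1] &
                 spikes$t_ms <= t_range[2], ]
  nb <- floor(diff(t_range) / bin)
  bidx <- floor((sp$t_ms - t_range[1] - 1e-9) / bin) + 1L
  counts <- tabulate(bidx[bidx <= nb], nbins = nb)
  pop_rate <- counts / (length(ids) * bin / 1000)
  sigma <- stats::sd(pop_rate)
  out <- list(ai = isTRUE(cv > cv_threshold) && isTRUE(sigma <
                                                         rate_sd_threshold),
              isi_cv = cv, sigma_rate = sigma,
              mean_rate = mean(pop_rate))
  class(out) <- "ai_state"
  out
}

#' @export
print.ai_state <- function(x, ...) {
  cat("<ai_state>", if (isTRUE(x$ai)) "asynchronous irregular"
      else "NOT asynchronous irregular", "\n")
  cat("  mean ISI CV =", signif(x$isi_cv, 4), "(> 1 required)\n")
  cat("  sigma_rate  =", signif(x$sigma_rate, 4), "Hz (< 5 required)\n")
  cat("  mean rate   =", signif(x$mean_rate, 4), "Hz\n")
  invisible(x)
}

#' @export
tidy.ai_state <- function(x, ...) {
  tibble::tibble(ai = x$ai, isi_cv = x$isi_cv, sigma_rate = x$sigma_rate,
                 mean_rate = x$mean_rate)
}

#' Region-resolved connectivity summary
#'
#' Cross-tabulates a connectome snapshot by synapse class, source region
#' and target region: synapse counts and mean conductances. The incoming
#' view (projections received by a region, split by source region) and the
#' outgoing axonal view are both recoverable by filtering.
#'
#' @param syn Synapse tibble.
#' @param layout Region-labelled layout.
#' @return Tibble `class`, `src_region`, `tgt_region`, `n`, `mean_g`.
#' @export
region_connectivity_summary <- function(syn, layout) {
  if (nrow(syn) > 0 &&
      (max(syn$pre, syn$post) > nrow(layout))) {
    stop("synapse ids exceed the layout")
  }
  regions <- levels(layout$region)
  if (nrow(syn) == 0) {
    grid <- expand.grid(class = c("EE", "EI", "IE", "II"),
                        src_region = regions, tgt_region = regions,
                        stringsAsFactors = FALSE)
    return(tibble::tibble(grid, n = 0L, mean_g = NA_real_))
  }
  df <- tibble::tibble(
    class = as.character(syn$class),
    src_region = as.character(layout$region[syn$pre]),
    tgt_region = as.character(layout$region[syn$post]),
    g = syn$g
  )
  dplyr::summarise(
    dplyr::group_by(df, .data$class, .data$src_region, .data$tgt_region),
    n = dplyr::n(), mean_g = mean(.data$g), .groups = "drop"
  )
}
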