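#' Structural-plasticity connectivity update
#'
#' Executed at the connectivity-update interval (1 s of simulated time).
#' In order:
#' \enumerate{
#'   \item \strong{Deletion}: every pool whose continuous count `z` has
#'     fallen below its connected count sheds `floor(z_connected - z)`
#'     synapses. Losses of axonal or post-synaptic excitatory elements pick
#'     candidates uniformly (EE/EI synapses are interchangeable static
#'     contacts); losses of inhibitory elements (IE/II synapses) use
#'     weight-dependent deletion: candidates with conductance at or above
#'     the immunity threshold `g_th` are excluded, the rest are sampled
#'     with probability weights [deletion_probability()].
#'   \item \strong{Harvest}: free counts `floor(max(z - z_connected, 0))`
#'     are computed per pool.
#'   \item \strong{Formation}: neurons with free axonal elements are
#'     visited in random order; all neurons holding complementary free
#'     post-synaptic elements are candidate partners, accepted with the
#'     distance kernel [formation_probability()] until either side's free
#'     supply is exhausted. New EE/EI conductances draw from
#'     N(`gbar`, `g_sd`), II from N(`10 gbar`, `g_sd`), and new IE synapses
#'     start near the mean learned IE conductance of the balanced network.
#'   \item \strong{Decay}: remaining free elements decay by `tau_free`
#'     (floored), and `z` is reduced by the decayed amount.
#' }
#'
#' @param net A `spiking_network` with instantiated growth curves and a
#'   recorded `g_th` / `ie_mean` (see [run_balance_phase()]).
#' @return List with the updated `net` and a one-row `log` tibble of
#'   formed/deleted counts per class and total free elements.
#' @export
structural_update <- function(net) {
  cfg <- net$cfg
  n <- nrow(net$layout)
  is_e <- net$layout$pop == "E"
  z <- net$state$z
  if (any(!is.finite(z))) stop("non-finite element counts")
  g_th <- net$g_th %||% Inf
  tau_free <- cfg$growth$tau_free

  syn <- net$syn
  nsyn <- nrow(syn)
  alive <- rep(TRUE, nsyn)
  zc <- connected_counts(net)
  loss <- pmax(floor(zc - z), 0)
  deleted <- integer(4) # per class EE, EI, IE, II
  names(deleted) <- c("EE", "EI", "IE", "II")
  cls_chr <- as.character(syn$class)

  del_from <- function(idx, k, weighted) {
    idx <- idx[alive[idx]]
    if (weighted) {
      idx <- idx[syn$g[idx] < g_th] # immune synapses never considered
      if (length(idx) == 0 || k == 0) return(invisible())
      k <- min(k, length(idx))
      pr <- deletion_probability(syn$g[idx], g_th)
      pick <- if (length(idx) == 1) idx
              else sample(idx, k, prob = pr)
    } else {
      if (length(idx) == 0 || k == 0) return(invisible())
      k <- min(k, length(idx))
      pick <- if (length(idx) == 1) idx else sample(idx, k)
    }
    alive[pick] <<- FALSE
    tab <- table(cls_chr[pick])
    deleted[names(tab)] <<- deleted[names(tab)] + as.integer(tab)
    invisible()
  }

  # axonal losses: outgoing synapses of the losing neuron
  ax_losers <- which(loss[, 1] > 0)
  if (length(ax_losers) > 0) {
    out_idx <- split(seq_len(nsyn), factor(syn$pre, levels = seq_len(n)))
    for (i in ax_losers) {
      del_from(out_idx[[i]], loss[i, 1], weighted = !is_e[i])
    }
  }
  # post-synaptic losses: incoming synapses of matching polarity
  from_e <- cls_chr %in% c("EE", "EI")
  pe_losers <- which(loss[, 2] > 0)
  pi_losers <- which(loss[, 3] > 0)
  if (length(pe_losers) > 0 || length(pi_losers) > 0) {
    in_e_idx <- split(which(from_e),
                      factor(syn$post[from_e], levels = seq_len(n)))
    in_i_idx <- split(which(!from_e),
                      factor(syn$post[!from_e], levels = seq_len(n)))
    for (i in pe_losers) del_from(in_e_idx[[i]], loss[i, 2],
                                  weighted = FALSE)
    for (i in pi_losers) del_from(in_i_idx[[i]], loss[i, 3],
                                  weighted = TRUE)
  }

  if (any(!alive)) {
    syn <- syn[alive, , drop = FALSE]
    net$syn <- syn
    net$csr <- NULL
    zc <- connected_counts(net)
  }

  # harvest free elements
  free <- pmax(floor(z - zc), 0)

  # formation: free axonal elements seek complementary free post elements
  new_pre <- integer(0); new_post <- integer(0)
  x <- net$layout$x; y <- net$layout$y
  mu <- net$mu_d_e
  for (polarity in c("exc", "inh")) {
    if (polarity == "exc") {
      src_pool <- which(is_e & free[, 1] > 0)
      post_col <- 2L
      p_hat <- cfg$synapse$p_hat_E; w <- cfg$synapse$w_E
    } else {
      src_pool <- which(!is_e & free[, 1] > 0)
      post_col <- 3L
      p_hat <- cfg$synapse$p_hat_I; w <- cfg$synapse$w_I
    }
    if (length(src_pool) == 0) next
    src_pool <- src_pool[sample.int(length(src_pool))]
    denom2 <- (w * mu)^2
    for (i in src_pool) {
      cand <- which(free[, post_col] > 0L)
      cand <- cand[cand != i]
      if (length(cand) == 0) next
      d <- torus_dist_point(x[i], y[i], x[cand], y[cand], net$extent)
      p <- p_hat * exp(-d^2 / denom2)
      acc <- cand[stats::runif(length(cand)) < p]
      k <- min(length(acc), free[i, 1])
      if (k == 0) next
      if (length(acc) > k) acc <- sample(acc, k)
      new_pre <- c(new_pre, rep.int(i, k))
      new_post <- c(new_post, acc)
      free[acc, post_col] <- free[acc, post_col] - 1L
      free[i, 1] <- free[i, 1] - k
    }
  }

  formed <- integer(4)
  names(formed) <- c("EE", "EI", "IE", "II")
  if (length(new_pre) > 0) {
    cls_new <- dplyr::case_when(
      is_e[new_pre] & is_e[new_post] ~ "EE",
      is_e[new_pre] & !is_e[new_post] ~ "EI",
      !is_e[new_pre] & is_e[new_post] ~ "IE",
      TRUE ~ "II"
    )
    gbar <- cfg$synapse$gbar; g_sd <- cfg$synapse$g_sd
    mean_g <- c(EE = gbar, EI = gbar,
                IE = net$ie_mean %||% 0,
                II = cfg$synapse$g_II_mult * gbar)
    g_new <- pmax(stats::rnorm(length(cls_new), mean_g[cls_new], g_sd), 0)
    g_new[cls_new %in% c("EE", "EI", "II")] <-
      pmax(g_new[cls_new %in% c("EE", "EI", "II")], 0.01)
    net$syn <- dplyr::bind_rows(
      net$syn,
      tibble::tibble(pre = new_pre, post = new_post,
                     class = factor(cls_new,
                                    levels = c("EE", "EI", "IE", "II")),
                     g = g_new))
    net$csr <- NULL
    tab <- table(cls_new)
    formed[names(tab)] <- formed[names(tab)] + as.integer(tab)
  }

  # decay of unused free elements; z shrinks by the decayed amount
  new_free <- floor(free - tau_free * free)
  z <- z - (free - new_free)
  z[z < 0] <- 0
  net$state$z <- z

  log <- tibble::tibble(
    t_s = net$state$t / 1000,
    formed_EE = formed["EE"], formed_EI = formed["EI"],
    formed_IE = formed["IE"], formed_II = formed["II"],
    deleted_EE = deleted["EE"], deleted_EI = deleted["EI"],
    deleted_IE = deleted["IE"], deleted_II = deleted["II"],
    free_axonal = sum(new_free[, 1]), free_post_exc = sum(new_free[, 2]),
    free_post_inh = sum(new_free[, 3])
  )
  list(net = net, log = log)
}
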