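#' Distance-dependent synapse formation probability
#'
#' Gaussian spatial kernel governing where new synapses form:
#' \deqn{p_{form} = \hat p \, e^{-(d/(w \mu_{dE}))^2}.}
#' Excitatory axons use a narrow kernel (`w = 8`), inhibitory axons a broad
#' one (`w = 24`), so local excitation coexists with far-reaching
#' inhibition.
#'
#' @param d Distance(s) between the candidate pair (um), >= 0.
#' @param p_hat Maximum probability at zero distance.
#' @param w Width multiplier (8 excitatory, 24 inhibitory).
#' @param mu_d_e Mean excitatory lattice spacing (um). Default 150.
#' @return Probabilities in `[0, p_hat]`.
#' @export
formation_probability <- function(d, p_hat, w, mu_d_e = 150) {
  stopifnot(all(d >= 0), p_hat >= 0, p_hat <= 1, w > 0)
  p_hat * exp(-(d / (w * mu_d_e))^2)
}

#' Weight-dependent synapse deletion probability
#'
#' Stability of a synapse grows with its efficacy: the probability that a
#' deletion candidate with conductance `g` is removed is
#' \deqn{p_{del} = e^{-(g/(2 g_{th}))^2}.}
#' Synapses with `g >= g_th` are immune: they are excluded from the
#' candidate set before sampling and are never deleted while weaker
#' candidates exist.
#'
#' @param g Conductance(s) in nS, >= 0.
#' @param g_th Immunity threshold conductance (nS, > 0).
#' @return Deletion probabilities.
#' @export
deletion_probability <- function(g, g_th) {
  stopifnot(all(g >= 0), g_th > 0)
  exp(-(g / (2 * g_th))^2)
}

#' Wire the initial sparse connectome
#'
#' Every neuron sends `n_out = round(p * (N - 1))` synapses to targets
#' sampled without replacement from the whole population (no self-
#' connections), with sampling weights given by the Gaussian spatial kernel
#' of [formation_probability()] (width `w_e` for excitatory sources, `w_i`
#' for inhibitory). Conductances: EE and EI draw from N(`gbar`, `g_sd`),
#' II from N(`10 gbar`, `g_sd`), and the plastic IE synapses start at zero,
#' to be grown by inhibitory STDP.
#'
#' @param layout A (optionally region-labelled) layout from
#'   [place_neurons()].
#' @param p Connection probability (initial sparsity). Default 0.02.
#' @param gbar Unit conductance in nS. Default 0.5.
#' @param g_sd Conductance jitter SD in nS. Default 0.1.
#' @param w_e,w_i Spatial width multipliers. Defaults 8 and 24.
#' @param seed Optional integer seed for the wiring stream.
#' @return A tibble of synapses: `pre`, `post`, `class`
#'   (EE/EI/IE/II), `g` (nS).
#' @export
wire_initial <- function(layout, p = 0.02, gbar = 0.5, g_sd = 0.1,
                         w_e = 8, w_i = 24, seed = NULL) {
  stopifnot(p > 0, p < 1)
  if (!is.null(seed)) set.seed(seed)
  extent <- attr(layout, "extent")
  mu_d_e <- attr(layout, "mu_d_e") %||% 150
  n <- nrow(layout)
  n_out <- as.integer(round(p * (n - 1)))
  if (n_out >= n) stop("n_out exceeds available targets")
  is_e <- layout$pop == "E"

  pre <- integer(n * n_out)
  post <- integer(n * n_out)
  x <- layout$x; y <- layout$y
  for (i in seq_len(n)) {
    w <- if (is_e[i]) w_e else w_i
    d <- torus_distance(x[i], y[i], x, y, extent)
    kern <- exp(-(d / (w * mu_d_e))^2)
    kern[i] <- 0 # no autapses
    # weighted sampling without replacement via exponential keys
    keys <- stats::rexp(n) / kern
    thr <- sort(keys, partial = n_out)[n_out]
    idx <- which(keys <= thr)
    if (length(idx) > n_out) idx <- idx[seq_len(n_out)]
    sl <- ((i - 1L) * n_out + 1L):(i * n_out)
    pre[sl] <- i
    post[sl] <- idx
  }

  # class labels are <pre><post> polarity: EE, EI, IE, II
  cls <- dplyr::case_when(
    is_e[pre] & is_e[post] ~ "EE",
    is_e[pre] & !is_e[post] ~ "EI",
    !is_e[pre] & is_e[post] ~ "IE",
    TRUE ~ "II"
  )
  g <- numeric(length(pre))
  exc_static <- cls %in% c("EE", "EI")
  g[exc_static] <- pmax(stats::rnorm(sum(exc_static), gbar, g_sd), 0.01)
  g[cls == "II"] <- pmax(stats::rnorm(sum(cls == "II"), 10 * gbar, g_sd),
                         0.01)
  g[cls == "IE"] <- 0
  tibble::tibble(pre = pre, post = post,
                 class = factor(cls, levels = c("EE", "EI", "IE", "II")),
                 g = g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
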