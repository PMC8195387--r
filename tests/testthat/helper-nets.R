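# Shared helpers: hand-built miniature networks and independent oracles.

# Layout with explicit coordinates on a given torus, all neurons labelled
# by population; regions default to "other".
manual_layout <- function(x, y, pop, extent, region = "other") {
  lay <- tibble::tibble(
    id = seq_along(x), pop = pop, x = x, y = y,
    region = factor(rep_len(region, length(x)),
                    levels = c("LPZ_C", "LPZ_B", "peri_LPZ", "other")))
  attr(lay, "extent") <- extent
  attr(lay, "mu_d_e") <- 150
  lay
}

empty_synapses <- function() {
  tibble::tibble(pre = integer(), post = integer(),
                 class = factor(character(),
                                levels = c("EE", "EI", "IE", "II")),
                 g = numeric())
}

make_synapses <- function(pre, post, class, g) {
  tibble::tibble(pre = as.integer(pre), post = as.integer(post),
                 class = factor(class, levels = c("EE", "EI", "IE", "II")),
                 g = g)
}

# Brute-force minimum-image distance over the 9 periodic images.
torus_distance_oracle <- function(ax, ay, bx, by, extent) {
  best <- Inf
  for (sx in c(-1, 0, 1)) {
    for (sy in c(-1, 0, 1)) {
      d <- sqrt((ax - bx + sx * extent[1])^2 +
                  (ay - by + sy * extent[2])^2)
      best <- min(best, d)
    }
  }
  best
}

# Poisson raster generator: independent homogeneous trains.
poisson_raster <- function(n, rate_hz, t_max_ms, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- lapply(seq_len(n), function(i) {
    k <- stats::rpois(1, rate_hz * t_max_ms / 1000)
    if (k == 0) return(NULL)
    tibble::tibble(id = i, t_ms = sort(stats::runif(k, 0, t_max_ms)))
  })
  dplyr::bind_rows(sp)
}

# Synapse identity keys (pre/post/class/conductance); conductances are
# continuous draws, so keys are effectively unique.
syn_keys <- function(syn) {
  paste(syn$pre, syn$post, as.character(syn$class), format(syn$g, digits = 15))
}

# Shared cache so the expensive balanced network is built once per run of
# the suite and reused across acceptance tests.
.cache <- new.env(parent = emptyenv())

desk_fixture_balanced <- function() {
  if (is.null(.cache$bal)) {
    fx <- make_fixture(scale = 0.2, seed = 1, overrides = desk_overrides())
    net <- build_network(fx$layout, fx$syn, fx$cfg)
    .cache$fx <- fx
    .cache$bal <- run_balance_phase(net)
  }
  list(fx = .cache$fx, bal = .cache$bal)
}
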