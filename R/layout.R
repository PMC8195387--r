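#' Choose rectangular lattice dimensions for a scaled network
#'
#' The full-scale network places 8000 excitatory neurons on a 100 x 80
#' lattice and 2000 inhibitory neurons on a 50 x 40 lattice (one inhibitory
#' neuron per 2 x 2 block of excitatory cells). A scale factor shrinks both
#' populations while preserving the 4:1 E:I ratio; the excitatory lattice
#' dimensions must be even integers so the interleaved inhibitory lattice
#' stays rectangular.
#'
#' @param scale Positive scale factor for neuron counts (1 = full scale).
#' @return List with `n_e`, `n_i`, `e_dims`, `i_dims`.
#' @export
lattice_dims <- function(scale = 1) {
  stopifnot(scale > 0)
  n_e <- 8000 * scale
  if (abs(n_e - round(n_e)) > 1e-9) {
    stop("scale ", scale, " gives a non-integer excitatory count (", n_e, ")")
  }
  n_e <- as.integer(round(n_e))
  # even divisors of n_e with even complement, closest to the full-scale
  # 100:80 aspect ratio
  divs <- which(n_e %% seq_len(n_e) == 0L)
  cols <- divs[divs %% 2L == 0L & (n_e / divs) %% 2L == 0L]
  if (length(cols) == 0L) {
    stop("scale ", scale, " admits no even-by-even excitatory lattice; ",
         "try a scale for which 8000*scale has an even-by-even ",
         "factorisation (e.g. 0.05, 0.1, 0.2, 0.5, 1)")
  }
  # pick the divisor whose aspect ratio ncol/nrow is nearest 100/80
  aspect <- cols^2 / n_e
  ncol_e <- cols[which.min(abs(log(aspect / (100 / 80))))]
  nrow_e <- n_e / ncol_e
  list(n_e = n_e, n_i = n_e %/% 4L,
       e_dims = c(as.integer(ncol_e), as.integer(nrow_e)),
       i_dims = c(as.integer(ncol_e) %/% 2L, as.integer(nrow_e) %/% 2L))
}

#' Place neurons on a jittered toroidal lattice
#'
#' Excitatory neurons sit on a rectangular lattice with mean spacing
#' `mu_d_e` (150 um) and Gaussian positional jitter; inhibitory neurons are
#' evenly interleaved on a lattice of twice the spacing, offset by half an
#' excitatory cell. The sheet wraps around as a torus, so there are no edge
#' effects. Positions are in micrometres.
#'
#' @param scale Scale factor for neuron counts (1 = 8000 E + 2000 I).
#' @param mu_d_e Mean spacing between adjacent excitatory neurons (um).
#' @param sigma_d Positional jitter SD (um), applied per coordinate.
#' @param seed Optional integer seed for the placement stream.
#' @return A tibble with columns `id`, `pop` ("E"/"I"), `x`, `y`, and
#'   attributes `extent` (torus size, um) and `dims`.
#' @export
place_neurons <- function(scale = 1, mu_d_e = 150, sigma_d = 15,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dims <- lattice_dims(scale)
  extent <- c(dims$e_dims[1] * mu_d_e, dims$e_dims[2] * mu_d_e)

  e_grid <- expand.grid(col = seq_len(dims$e_dims[1]) - 1L,
                        row = seq_len(dims$e_dims[2]) - 1L)
  ex <- e_grid$col * mu_d_e
  ey <- e_grid$row * mu_d_e

  mu_d_i <- 2 * mu_d_e
  i_grid <- expand.grid(col = seq_len(dims$i_dims[1]) - 1L,
                        row = seq_len(dims$i_dims[2]) - 1L)
  # offset by half a cell so inhibitory neurons sit between excitatory ones
  ix <- i_grid$col * mu_d_i + mu_d_e / 2
  iy <- i_grid$row * mu_d_i + mu_d_e / 2

  x <- c(ex, ix) + stats::rnorm(dims$n_e + dims$n_i, 0, sigma_d)
  y <- c(ey, iy) + stats::rnorm(dims$n_e + dims$n_i, 0, sigma_d)
  x <- x %% extent[1]
  y <- y %% extent[2]

  out <- tibble::tibble(
    id = seq_len(dims$n_e + dims$n_i),
    pop = rep(c("E", "I"), c(dims$n_e, dims$n_i)),
    x = x, y = y
  )
  attr(out, "extent") <- extent
  attr(out, "dims") <- dims
  attr(out, "mu_d_e") <- mu_d_e
  out
}

#' Minimum-image distance on the torus
#'
#' Euclidean distance between points on the periodic sheet, taking the
#' shortest wrap-around path in each coordinate.
#'
#' @param ax,ay,bx,by Coordinate vectors (recycled).
#' @param extent Numeric length-2 torus extent (um).
#' @return Numeric vector of distances (um).
#' @export
torus_distance <- function(ax, ay, bx, by, extent) {
  dx <- abs(ax - bx)
  dy <- abs(ay - by)
  dx <- pmin(dx, extent[1] - dx)
  dy <- pmin(dy, extent[2] - dy)
  sqrt(dx^2 + dy^2)
}

#' Label lesion-projection-zone regions
#'
#' Within each population independently, neurons are ranked by torus
#' distance from the grid centre; the nearest 2.5% form the LPZ centre
#' (`LPZ_C`), the next 2.5% the inner LPZ border (`LPZ_B`), the next 5% the
#' peri-LPZ ring (`peri_LPZ`), and the remaining 90% are `other`. Ranking
#' per population keeps the E:I ratio uniform across regions.
#'
#' @param layout A layout from [place_neurons()].
#' @param fractions Region fractions for LPZ_C, LPZ_B and peri_LPZ.
#' @return The layout with an added `region` factor column.
#' @export
classify_regions <- function(layout, fractions = c(0.025, 0.025, 0.05)) {
  extent <- attr(layout, "extent")
  stopifnot(!is.null(extent), length(fractions) == 3, sum(fractions) < 1)
  centre <- extent / 2
  d <- torus_distance(layout$x, layout$y, centre[1], centre[2], extent)
  region <- character(nrow(layout))
  for (p in unique(layout$pop)) {
    sel <- which(layout$pop == p)
    n <- length(sel)
    k <- round(cumsum(fractions) * n)
    rk <- rank(d[sel], ties.method = "first")
    lab <- rep("other", n)
    lab[rk <= k[3]] <- "peri_LPZ"
    lab[rk <= k[2]] <- "LPZ_B"
    lab[rk <= k[1]] <- "LPZ_C"
    region[sel] <- lab
  }
  layout$region <- factor(region,
                          levels = c("LPZ_C", "LPZ_B", "peri_LPZ", "other"))
  layout
}
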