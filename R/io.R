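#' Write a spike raster in gdf style
#'
#' Plain-text, two tab-separated columns: neuron id and spike time in ms,
#' no header.
#'
#' @param spikes Tibble with `id` and `t_ms`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(spikes, path) {
  utils::write.table(spikes[, c("id", "t_ms")], path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gdf-style spike raster
#'
#' @param path Path written by [write_raster()].
#' @return Tibble with `id` and `t_ms`.
#' @export
read_raster <- function(path) {
  df <- utils::read.table(path, sep = "\t", col.names = c("id", "t_ms"))
  tibble::as_tibble(df)
}

#' Write a connectome snapshot as an edge list
#'
#' @param syn Synapse tibble (`pre`, `post`, `class`, `g`).
#' @param path Output CSV path.
#' @param t_s Simulation time of the snapshot (s).
#' @return `path`, invisibly.
#' @export
write_edges <- function(syn, path, t_s = NA_real_) {
  df <- data.frame(pre_id = syn$pre, post_id = syn$post,
                   class = as.character(syn$class), g_nS = syn$g,
                   t_s = t_s)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an edge-list connectome snapshot
#'
#' @param path CSV path written by [write_edges()].
#' @return Synapse tibble (`pre`, `post`, `class`, `g`, `t_s`).
#' @export
read_edges <- function(path) {
  df <- utils::read.csv(path)
  tibble::tibble(pre = df$pre_id, post = df$post_id,
                 class = factor(df$class,
                                levels = c("EE", "EI", "IE", "II")),
                 g = df$g_nS, t_s = df$t_s)
}

#' Write a layout table
#'
#' @param layout Region-labelled layout tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  df <- data.frame(id = layout$id, population = layout$pop,
                   x_um = layout$x, y_um = layout$y,
                   region = as.character(layout$region %||% NA))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a layout table
#'
#' Restores the tibble form with `extent` and `mu_d_e` attributes inferred
#' from the written coordinates only when `extent` is supplied.
#'
#' @param path CSV path written by [write_layout()].
#' @param extent Optional torus extent (um) to reattach.
#' @param mu_d_e Excitatory lattice spacing to reattach. Default 150.
#' @return Layout tibble.
#' @export
read_layout <- function(path, extent = NULL, mu_d_e = 150) {
  df <- utils::read.csv(path)
  out <- tibble::tibble(id = df$id, pop = df$population,
                        x = df$x_um, y = df$y_um,
                        region = factor(df$region,
                                        levels = c("LPZ_C", "LPZ_B",
                                                   "peri_LPZ", "other")))
  if (!is.null(extent)) attr(out, "extent") <- extent
  attr(out, "mu_d_e") <- mu_d_e
  out
}
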