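#' Plot region-resolved rate trajectories of a lesion run
#'
#' One line per region (excitatory population), with the deafferentation
#' time marked. The LPZ collapse, the transient peri-LPZ rise and the
#' recovery are all visible on this plot.
#'
#' @param object A `repair_run`.
#' @param pop Population to plot ("E" or "I").
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.repair_run <- function(object, pop = "E", ...) {
  d <- object$rates[object$rates$pop == pop, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_s, y = .data$rate_hz,
                                  colour = .data$region)) +
    ggplot2::geom_vline(xintercept = object$t2, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "time (s)", y = "mean firing rate (Hz)",
                  colour = "region",
                  title = paste0("Lesion at t = ", object$t2,
                                 " s (regime ", object$cfg$regime, ")")) +
    ggplot2::theme_minimal()
}

#' Plot incoming-projection counts for a target region over time
#'
#' Reproduces the style of the region-resolved connectivity panels:
#' synapse counts into one target region, split by source region, for one
#' synapse class.
#'
#' @param run A `repair_run`.
#' @param class Synapse class to show (e.g. "EE" or "IE").
#' @param tgt_region Target region. Default `"LPZ_C"`.
#' @return A ggplot object.
#' @export
plot_incoming_projections <- function(run, class = "EE",
                                      tgt_region = "LPZ_C") {
  d <- run$conn[run$conn$class == class &
                  run$conn$tgt_region == tgt_region, ]
  d <- dplyr::summarise(dplyr::group_by(d, .data$t_s, .data$src_region),
                        n = sum(.data$n), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_s, y = .data$n,
                                  colour = .data$src_region)) +
    ggplot2::geom_vline(xintercept = run$t2, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = paste(class, "synapse count"),
                  colour = "source region",
                  title = paste0(class, " projections into ", tgt_region)) +
    ggplot2::theme_minimal()
}

#' Tidy the rate time series of a lesion run
#'
#' @param x A `repair_run`.
#' @param ... Unused.
#' @return The per-chunk region/population rate tibble.
#' @export
tidy.repair_run <- function(x, ...) {
  x$rates
}
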