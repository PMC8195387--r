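#' Gaussian neurite growth curve
#'
#' Constructs the activity-dependent growth rule for one class of synaptic
#' elements. The turnover rate of elements is a Gaussian function of the
#' neuron's calcium trace,
#' \deqn{dz/dt = \nu \left(2 e^{-\left((Ca - \xi)/\zeta\right)^2} - \omega\right),}
#' with zero crossings at `eta` and `epsilon`, midpoint
#' \eqn{\xi = (\eta+\epsilon)/2} and width
#' \eqn{\zeta = (\epsilon-\eta) / (2\sqrt{-\ln(\omega/2)})}. Elements sprout
#' (positive rate) for calcium between `eta` and `epsilon` and retract
#' outside that window; the vertical shift `omega` sets how fast retraction
#' is relative to sprouting.
#'
#' A degenerate activity-independent rule (constant sprouting at rate `nu`)
#' is available via `constant = TRUE`; it is used by the constant-sprouting
#' axonal regime in the growth-regime battery.
#'
#' @param nu Scaling factor, elements per second. `nu = 0` disables turnover.
#' @param eta Lower zero crossing (calcium units). Ignored when `constant`.
#' @param epsilon Upper zero crossing (calcium units); must exceed `eta`.
#' @param omega Vertical shift, in (0, 2). `omega = 1` gives the classical
#'   symmetric form (minimum \eqn{-\nu}, maximum \eqn{\nu}).
#' @param constant If `TRUE`, the rate is `nu` at every calcium level.
#' @return An object of class `growth_curve`.
#' @examples
#' gc <- growth_curve(nu = 1, eta = 5, epsilon = 15, omega = 0.001)
#' growth_rate(gc, c(5, 10, 15))
#' curve_extrema(gc)
#' @export
growth_curve <- function(nu, eta = NULL, epsilon = NULL, omega = 1,
                         constant = FALSE) {
  stopifnot(is.numeric(nu), length(nu) == 1L, is.finite(nu), nu >= 0)
  if (constant) {
    out <- list(nu = nu, eta = NA_real_, epsilon = NA_real_,
                omega = NA_real_, xi = NA_real_, zeta = NA_real_,
                constant = TRUE)
    class(out) <- "growth_curve"
    return(out)
  }
  stopifnot(is.numeric(eta), length(eta) == 1L, is.finite(eta))
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, is.finite(epsilon))
  stopifnot(is.numeric(omega), length(omega) == 1L, is.finite(omega))
  if (!(eta < epsilon)) {
    stop("`eta` must be strictly less than `epsilon` (got ", eta, " >= ",
         epsilon, ")")
  }
  if (!(omega > 0 && omega < 2)) {
    stop("`omega` must lie in (0, 2) so that the curve has real zero ",
         "crossings (got ", omega, ")")
  }
  xi <- (eta + epsilon) / 2
  zeta <- (epsilon - eta) / (2 * sqrt(-log(omega / 2)))
  out <- list(nu = nu, eta = eta, epsilon = epsilon, omega = omega,
              xi = xi, zeta = zeta, constant = FALSE)
  class(out) <- "growth_curve"
  out
}

#' @export
print.growth_curve <- function(x, ...) {
  if (x$constant) {
    cat("<growth_curve> constant sprouting, nu =", x$nu, "elements/s\n")
  } else {
    ex <- curve_extrema(x)
    cat("<growth_curve> nu =", x$nu, " eta =", x$eta, " epsilon =", x$epsilon,
        " omega =", x$omega, "\n")
    cat("  max dz/dt =", signif(ex$maximum, 6), "at Ca =", ex$argmax,
        "; asymptotic min =", signif(ex$infimum, 6), "\n")
  }
  invisible(x)
}

#' Element turnover rate at a calcium level
#'
#' Evaluates the growth curve at one or more calcium concentrations.
#' The rate is positive strictly between `eta` and `epsilon`, zero at both,
#' and negative outside (approaching \eqn{-\nu\omega} for large calcium).
#'
#' @param curve A [growth_curve()].
#' @param ca Numeric vector of calcium values (must be non-negative).
#' @return Numeric vector of turnover rates (elements per second).
#' @export
growth_rate <- function(curve, ca) {
  stopifnot(inherits(curve, "growth_curve"), is.numeric(ca), all(ca >= 0))
  if (curve$constant) {
    return(rep(curve$nu, length(ca)))
  }
  curve$nu * (2 * exp(-((ca - curve$xi) / curve$zeta)^2) - curve$omega)
}

#' Analytic extrema of a growth curve
#'
#' The maximum turnover rate \eqn{\nu(2-\omega)} is attained at the curve
#' midpoint \eqn{(\eta+\epsilon)/2}; the infimum \eqn{-\nu\omega} is
#' approached asymptotically as calcium grows large.
#'
#' @param curve A [growth_curve()].
#' @return A list with `infimum`, `maximum` and `argmax`.
#' @export
curve_extrema <- function(curve) {
  stopifnot(inherits(curve, "growth_curve"))
  if (curve$constant) {
    return(list(infimum = curve$nu, maximum = curve$nu, argmax = NA_real_))
  }
  list(infimum = -curve$nu * curve$omega,
       maximum = curve$nu * (2 - curve$omega),
       argmax = curve$xi)
}

#' Tidy a growth curve into a one-row tibble
#'
#' @param x A [growth_curve()].
#' @param ... Unused.
#' @export
tidy.growth_curve <- function(x, ...) {
  ex <- curve_extrema(x)
  tibble::tibble(
    nu = x$nu, eta = x$eta, epsilon = x$epsilon, omega = x$omega,
    xi = x$xi, zeta = x$zeta, constant = x$constant,
    rate_min = ex$infimum, rate_max = ex$maximum, argmax = ex$argmax
  )
}

#' Plot a growth curve over a calcium range
#'
#' @param object A [growth_curve()].
#' @param ca_max Upper end of the calcium axis; defaults to twice `epsilon`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.growth_curve <- function(object, ca_max = NULL, ...) {
  if (is.null(ca_max)) {
    ca_max <- if (object$constant) 10 else 2 * object$epsilon
  }
  ca <- seq(0, ca_max, length.out = 400)
  df <- tibble::tibble(ca = ca, rate = growth_rate(object, ca))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ca, y = .data$rate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "calcium trace", y = "dz/dt (elements / s)") +
    ggplot2::theme_minimal()
}
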