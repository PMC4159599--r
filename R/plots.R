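# ggplot2 visualisations of the package's result objects.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_tile labs
#'   facet_wrap autoplot theme_minimal geom_hline scale_y_log10
NULL

#' @export
ggplot2::autoplot

#' Plot a phase response curve
#'
#' @param object a [compute_prc()] object.
#' @param ... unused.
#' @return a ggplot showing `Z(theta)` and `Z'(theta)`.
#' @export
autoplot.prc <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(theta = object$curves$theta, value = object$curves$Z,
                   quantity = "Z(theta)"),
    tibble::tibble(theta = object$curves$theta, value = object$curves$dZ,
                   quantity = "Z'(theta)"))
  ggplot(df, aes(x = .data$theta, y = .data$value)) +
    geom_line() +
    facet_wrap(~quantity, scales = "free_y") +
    labs(x = expression(theta ~ "(rad)"), y = NULL,
         title = "Phase response curve (adjoint method)") +
    theme_minimal()
}

#' Plot a designed stimulus waveform
#'
#' @param object a [design_stimulus()] object.
#' @param ... unused.
#' @return a ggplot of the probe drive `u_p` and field input `u_e`.
#' @export
autoplot.dbs_stimulus <- function(object, ...) {
  wf <- object$waveform
  df <- dplyr::bind_rows(
    tibble::tibble(t = wf$t, value = wf$u_p, signal = "u_p (probe)"),
    tibble::tibble(t = wf$t, value = wf$u_e, signal = "u_e (field)"))
  ggplot(df, aes(x = .data$t, y = .data$value, colour = .data$signal)) +
    geom_line() +
    labs(x = "time (ms)", y = "input (u-units)",
         title = sprintf("Designed stimulus (gamma = %g)", object$weights$gamma),
         subtitle = sprintf("Lambda(T) = %.3f /ms", object$diagnostics$Lambda_T)) +
    theme_minimal()
}

#' Plot a population trace
#'
#' Mean voltage with the applied field input and spike raster.
#'
#' @param object a `population_trace` from [simulate_network()].
#' @param ... unused.
#' @return a ggplot (mean voltage and raster, stacked).
#' @export
autoplot.population_trace <- function(object, ...) {
  ras <- spike_raster(object)
  df <- dplyr::bind_rows(
    tibble::tibble(t = object$t, y = object$vbar, panel = "mean voltage (mV)"),
    tibble::tibble(t = object$t, y = object$u_e, panel = "field input u_e"),
    tibble::tibble(t = ras$spike_time, y = ras$neuron, panel = "raster"))
  ggplot(df, aes(x = .data$t, y = .data$y)) +
    geom_line(data = function(d) dplyr::filter(d, .data$panel != "raster")) +
    geom_point(data = function(d) dplyr::filter(d, .data$panel == "raster"),
               size = 0.2) +
    facet_wrap(~panel, ncol = 1, scales = "free_y") +
    labs(x = "time (ms)", y = NULL) +
    theme_minimal()
}

#' Plot a phase-difference trace with its exponential fit
#'
#' @param object a [numerical_exponent()] result.
#' @param ... unused.
#' @return a ggplot of `phi(t)` on a log scale with the fitted rate.
#' @export
autoplot.phase_difference_trace <- function(object, ...) {
  ggplot(object$trace, aes(x = .data$t, y = .data$phi)) +
    geom_line() +
    scale_y_log10() +
    labs(x = "time (ms)", y = expression(phi ~ "(rad)"),
         title = sprintf("Pairwise phase difference (fitted Lambda = %.4f /ms, R^2 = %.2f)",
                         object$lambda, object$r2)) +
    theme_minimal()
}
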