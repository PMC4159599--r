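# broom-style tidiers: tidy() returns the per-sample table of a result,
# glance() a one-row summary.

#' @rdname desyncdbs-tidiers
#' @param x a package result object.
#' @param ... unused.
#' @export
tidy.prc <- function(x, ...) x$curves

#' @rdname desyncdbs-tidiers
#' @export
glance.prc <- function(x, ...) {
  tibble::tibble(T = x$T, omega = x$omega,
                 Z_max = max(x$curves$Z),
                 theta_peak = x$curves$theta[which.max(x$curves$Z)],
                 norm_resid_max = max(abs(x$norm_resid)))
}

#' @rdname desyncdbs-tidiers
#' @export
tidy.limit_cycle <- function(x, ...) x$orbit

#' @rdname desyncdbs-tidiers
#' @export
glance.limit_cycle <- function(x, ...) {
  tibble::tibble(T = x$T, omega = x$omega, grid_size = x$grid_size,
                 V_min = min(x$orbit$V), V_max = max(x$orbit$V))
}

#' Tidiers for desyncdbs result objects
#'
#' `tidy()` methods return the underlying per-sample tibble (PRC curves,
#' stimulus waveform, population trace, phase-difference trace); `glance()`
#' methods return a one-row summary of the fit or run.
#'
#' @name desyncdbs-tidiers
#' @rdname desyncdbs-tidiers
#' @export
tidy.dbs_stimulus <- function(x, ...) x$waveform

#' @rdname desyncdbs-tidiers
#' @export
glance.dbs_stimulus <- function(x, ...) x$diagnostics

#' @rdname desyncdbs-tidiers
#' @export
tidy.population_trace <- function(x, ...) {
  tibble::tibble(t = x$t, vbar = x$vbar, u_p = x$u_p, u_e = x$u_e)
}

#' @rdname desyncdbs-tidiers
#' @export
glance.population_trace <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(N = cfg$N, sigma = cfg$sigma, noise_2D = cfg$noise_2D,
                 duration = cfg$duration, mode = attr(x, "mode"),
                 energy = attr(x, "energy"),
                 n_triggers = length(attr(x, "triggers")),
                 n_spikes = nrow(attr(x, "raster")))
}

#' @rdname desyncdbs-tidiers
#' @export
tidy.phase_difference_trace <- function(x, ...) x$trace

#' @rdname desyncdbs-tidiers
#' @export
glance.phase_difference_trace <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, r2 = x$r2, exponential = x$exponential,
                 window_start = x$window[1], window_end = x$window[2])
}
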