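# Finite-time Lyapunov exponents of the driven phase dynamics. Positive
# exponents mean nearby phases separate exponentially (desynchronization);
# electrotonic coupling contributes a synchronizing term -sigma f'(theta)
# Z(theta) that a stimulus must overcome.

as_ue_vector <- function(u_e) {
  if (is.data.frame(u_e)) u_e$u_e else as.numeric(u_e)
}

pad_u <- function(u, dt, tau) {
  need <- floor(tau / dt) + 2L
  if (length(u) < need) u <- c(u, numeric(need - length(u)))
  u
}

#' Uncoupled finite-time Lyapunov exponent
#'
#' `Lambda(tau) = (1/tau) * int_0^tau Z'(theta(s)) u(s) ds` along the phase
#' trajectory driven by `u` through `dtheta/dt = omega + Z(theta) u(t)`.
#' The input is padded with zeros beyond its final sample (a finished
#' stimulus injects nothing).
#'
#' @param u_e field input: numeric samples on a uniform grid, or a waveform
#'   data frame with a `u_e` column.
#' @param dt sample interval (ms); taken from the waveform when omitted.
#' @param prc a [compute_prc()] object.
#' @param theta0 starting phase (radians).
#' @param tau horizon (ms), defaulting to one period.
#' @return exponent (1/ms).
#' @export
exponent_uncoupled <- function(u_e, dt = NULL, prc, theta0 = 0, tau = prc$T) {
  if (is.data.frame(u_e) && is.null(dt)) dt <- u_e$t[2] - u_e$t[1]
  u <- pad_u(as_ue_vector(u_e), dt, tau)
  q <- cpp_phase_quadrature(u, dt, theta0, prc$omega, prc$z_coef, prc$f_coef, tau)
  q$int_zpu / tau
}

#' Coupled finite-time exponent (symmetric-distribution approximation)
#'
#' `Lambda_c(tau) ~ (1/tau) * int [Z'(theta) u - sigma f'(theta) Z(theta)] dt`:
#' valid when the phase distribution is symmetric about its peak, so the
#' ensemble voltage-difference sum averages out. With no input this is
#' negative for the thalamic cell (coupling synchronizes).
#'
#' @inheritParams exponent_uncoupled
#' @param sigma electrotonic coupling strength.
#' @return exponent (1/ms).
#' @export
exponent_coupled_approx <- function(u_e, dt = NULL, prc, sigma = 0.07,
                                    theta0 = 0, tau = prc$T) {
  if (is.data.frame(u_e) && is.null(dt)) dt <- u_e$t[2] - u_e$t[1]
  u <- pad_u(as_ue_vector(u_e), dt, tau)
  q <- cpp_phase_quadrature(u, dt, theta0, prc$omega, prc$z_coef, prc$f_coef, tau)
  (q$int_zpu - sigma * q$int_fpz) / tau
}

#' Coupled finite-time exponent with the full ensemble sum
#'
#' Evaluates the exact coupled integrand
#' `Z'(theta) (u + (sigma/N) sum_i (f(theta_i) - f(theta))) - sigma f'(theta) Z(theta)`
#' along phase-model dynamics of the whole ensemble (all-to-all electrotonic
#' coupling through the on-orbit voltage map; the large-N simplification
#' `(N-1)/N ~ 1` is applied to the pairwise term). The reference phase is
#' the first entry of `phases`.
#'
#' @param phases numeric vector of initial ensemble phases (radians); the
#'   first is the reference oscillator.
#' @inheritParams exponent_coupled_approx
#' @return exponent (1/ms).
#' @export
exponent_coupled_exact <- function(phases, u_e, dt = NULL, sigma = 0.07, prc,
                                   tau = prc$T) {
  if (!length(phases)) stop("empty phase ensemble")
  if (is.data.frame(u_e) && is.null(dt)) dt <- u_e$t[2] - u_e$t[1]
  u <- pad_u(as_ue_vector(u_e), dt, tau)
  ens <- cpp_phase_ensemble(as.numeric(phases), u, dt, prc$omega, sigma,
                            prc$z_coef, prc$f_coef, tau)
  ens$integral / tau
}

#' Numerical desynchronization exponent from a population trace
#'
#' Infers the phase of two tracked neurons at each recorded sample by
#' ballistic simulation: each frozen state is integrated forward, input-free
#' and noise-free, to its next spike, giving
#' `theta = 2*pi*(1 - t_next/T)`. The absolute circular phase difference
#' `phi(t)` is fitted by least squares on `log(phi)` over the window from
#' stimulus onset until `phi` first exceeds `phi_max` (beyond which the
#' linearisation behind exponential growth fails); decaying traces use the
#' full record. A fit with `R^2` below `r2_threshold` is flagged as not
#' exponential.
#'
#' @param trace a `population_trace` from [simulate_network()] (run with
#'   `D = 0`: phase inference requires deterministic states).
#' @param pair indices of the two tracked neurons.
#' @param phi_max fitting-window cap on the phase difference (radians).
#' @param r2_threshold minimum `R^2` to declare exponential behaviour.
#' @param ballistic_dt fixed step of the ballistic forward simulation (ms).
#' @return object of class `phase_difference_trace`: list with `trace`
#'   (tibble `t, theta1, theta2, phi`), fitted `lambda` (1/ms), `r2`,
#'   `exponential` flag and the fitting window.
#' @export
numerical_exponent <- function(trace, pair = c(1, 2), phi_max = 1,
                               r2_threshold = 0.9, ballistic_dt = 0.005) {
  if (attr(trace, "config")$D > 0) {
    stop("phase inference requires a noise-free (D = 0) trace")
  }
  params <- attr(trace, "params")
  T <- attr(trace, "period")
  st <- attr(trace, "states")
  tg <- st$t
  thetas <- lapply(pair, function(i) {
    states <- cbind(st$V[, i], st$h[, i], st$r[, i])
    tn <- cpp_next_spike(states, par_vec(params), attr(trace, "spike_threshold"),
                         ballistic_dt, 2.5 * T)
    (2 * pi * (1 - tn / T)) %% (2 * pi)
  })
  d <- abs(thetas[[2]] - thetas[[1]]) %% (2 * pi)
  phi <- pmin(d, 2 * pi - d)

  trg <- attr(trace, "triggers")
  t0 <- if (length(trg)) trg[1] else 0
  i0 <- which(tg >= t0)[1]
  iz <- which(phi < 1e-10 & seq_along(phi) >= i0)
  iend <- if (length(iz)) iz[1] - 1L else length(phi)
  ib <- which(phi > phi_max & seq_along(phi) >= i0)
  if (length(ib)) iend <- min(iend, ib[1])
  win <- seq(i0, iend)
  if (length(win) < 10) stop("phase-difference window too short for a fit")

  fit <- stats::lm(log(phi[win]) ~ tg[win])
  lambda <- unname(coef(fit)[2])
  r2 <- summary(fit)$r.squared
  structure(list(
    trace = tibble::tibble(t = tg, theta1 = thetas[[1]], theta2 = thetas[[2]],
                           phi = phi),
    lambda = lambda, r2 = r2,
    exponential = is.finite(r2) && r2 >= r2_threshold,
    window = range(tg[win])), class = "phase_difference_trace")
}

#' @export
print.phase_difference_trace <- function(x, ...) {
  cat(sprintf("Phase-difference trace: fitted Lambda = %.4f /ms (R^2 = %.3f, %s)\n",
              x$lambda, x$r2,
              if (x$exponential) "exponential" else "not exponential"))
  cat(sprintf("  fit window: %.1f to %.1f ms\n", x$window[1], x$window[2]))
  invisible(x)
}
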