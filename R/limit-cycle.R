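# Limit cycle and phase response curve of the periodically spiking neuron.
# Phase theta = 0 is anchored at the spike (upward crossing of the spike
# threshold); theta advances at the constant rate omega = 2*pi/T along the
# orbit. All theta-indexed quantities are stored both as samples on a uniform
# grid and as truncated Fourier series so that smooth derivatives are cheap
# to evaluate at arbitrary phase during boundary-value integration.

#' Find the stable limit cycle of the thalamic neuron
#'
#' Integrates the unforced neuron past its transient, measures the period
#' from interpolated spike times, and samples the orbit on a uniform phase
#' grid starting at the spike point. The orbit components are stored as
#' Fourier series: a near-Nyquist series used internally for accurate state
#' interpolation, and a smoothed `n_harm`-harmonic series for the on-orbit
#' voltage map `f(theta)` and its derivatives used by the design equations.
#'
#' @param params a [neuron_params()] object.
#' @param grid_size number of uniform phase samples on the orbit.
#' @param n_harm harmonics retained for the smoothed `f(theta)` series.
#' @param settle transient discard time (ms).
#' @param rtol integrator relative tolerance.
#' @param spike_threshold voltage threshold defining phase zero (mV).
#' @return an object of class `limit_cycle`: list with period `T`, frequency
#'   `omega`, `orbit` (tibble `theta, V, h, r`), full-resolution interpolation
#'   coefficients `coef_full` and smoothed voltage-map coefficients `f_coef`.
#' @examples
#' \donttest{
#' lc <- find_limit_cycle()
#' lc$T
#' }
#' @export
find_limit_cycle <- function(params = neuron_params(), grid_size = 512L,
                             n_harm = 64L, settle = 1200, rtol = 1e-10,
                             spike_threshold = -20) {
  pv <- par_vec(params)
  rhs <- function(t, y, parms) list(as.numeric(cpp_thal_rhs(matrix(y, 1), 0, pv)))

  o1 <- deSolve::ode(c(-65, 0.4, 0.2), c(0, settle), rhs, NULL,
                     method = "lsoda", rtol = rtol, atol = rtol, maxsteps = 500000)
  y0 <- o1[nrow(o1), -1]
  dt <- 0.002
  o2 <- deSolve::ode(y0, seq(0, 150, by = dt), rhs, NULL,
                     method = "lsoda", rtol = rtol, atol = rtol, maxsteps = 500000)
  spk <- detect_spikes(o2[, 1], o2[, 2], spike_threshold)
  if (length(spk) < 4) stop("not oscillating: no limit cycle found within horizon")
  period <- mean(diff(spk))

  # state at the penultimate spike: linear interpolation between dense samples
  ts <- spk[length(spk) - 1]
  i <- findInterval(ts, o2[, 1])
  w <- (ts - o2[i, 1]) / dt
  yspk <- (1 - w) * o2[i, -1] + w * o2[i + 1, -1]

  theta <- 2 * pi * seq(0, grid_size - 1) / grid_size
  o3 <- deSolve::ode(yspk, theta / (2 * pi) * period, rhs, NULL,
                     method = "lsoda", rtol = rtol, atol = rtol, maxsteps = 500000)
  orbit <- tibble::tibble(theta = theta, V = o3[, 2], h = o3[, 3], r = o3[, 4])

  full_h <- grid_size %/% 2 - 1L
  coef_full <- lapply(orbit[c("V", "h", "r")], fourier_fit, n_harm = full_h)
  structure(list(
    T = period, omega = 2 * pi / period, orbit = orbit,
    coef_full = coef_full,
    f_coef = fourier_fit(orbit$V, n_harm = n_harm),
    params = params, grid_size = grid_size, n_harm = n_harm,
    spike_threshold = spike_threshold
  ), class = "limit_cycle")
}

#' Evaluate the orbit state at arbitrary phase
#'
#' @param lc a [find_limit_cycle()] object.
#' @param theta phases (radians).
#' @return matrix with columns `V`, `h`, `r`.
#' @export
orbit_state <- function(lc, theta) {
  m <- vapply(lc$coef_full, function(cf) fourier_eval(cf, theta, 0L),
              numeric(length(theta)))
  m <- matrix(m, ncol = 3, dimnames = list(NULL, c("V", "h", "r")))
  m
}

#' @export
print.limit_cycle <- function(x, ...) {
  cat(sprintf("Limit cycle: T = %.4f ms (omega = %.4f rad/ms), %d phase samples\n",
              x$T, x$omega, x$grid_size))
  invisible(x)
}

# finite-difference Jacobian of the single-cell vector field (3 x 3)
thal_jacobian <- function(y, pv, eps = 1e-6) {
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    dy <- numeric(3); dy[j] <- eps * max(1, abs(y[j]))
    fp <- as.numeric(cpp_thal_rhs(matrix(y + dy, 1), 0, pv))
    fm <- as.numeric(cpp_thal_rhs(matrix(y - dy, 1), 0, pv))
    J[, j] <- (fp - fm) / (2 * dy[j])
  }
  J
}

#' Phase response curve by the adjoint method
#'
#' Integrates the adjoint equation backwards along the limit cycle until the
#' solution is periodic, then normalises it so that the inner product with
#' the orbit's vector field equals `omega` at every grid point (the product
#' is conserved analytically along the adjoint flow, so pointwise
#' normalisation only removes numerical drift of the neutral component; the
#' residual of the normalised solution is kept as a diagnostic).
#' The voltage component is the PRC `Z(theta)`; it is smoothed to `n_harm`
#' harmonics and returned with its first two phase derivatives, alongside the
#' on-orbit voltage map `f(theta)` and derivatives.
#'
#' @param lc a [find_limit_cycle()] object.
#' @param params neuron parameters (defaults to those stored in `lc`).
#' @param n_periods backward integration horizon in periods (transient
#'   discard; convergence is checked over the final two periods).
#' @param rtol integrator relative tolerance.
#' @param conv_tol max-norm relative change between successive periods below
#'   which the adjoint is declared periodic.
#' @return an object of class `prc`: list with `curves` (tibble
#'   `theta, Z, dZ, d2Z, f, df, d2f`), Fourier coefficients `z_coef` and
#'   `f_coef`, period `T`, `omega`, the normalisation residual profile and
#'   the embedded `lc`.
#' @examples
#' \donttest{
#' lc <- find_limit_cycle()
#' prc <- compute_prc(lc)
#' prc$curves$theta[which.max(prc$curves$Z)]  # peak near theta ~ 4.5
#' }
#' @export
compute_prc <- function(lc, params = lc$params, n_periods = 100L, rtol = 1e-10,
                        conv_tol = 1e-4) {
  pv <- par_vec(params)
  M <- lc$grid_size
  omega <- lc$omega

  # backward time s: x(s) = orbit(-omega * s); dz/ds = + J^T z. The
  # non-neutral adjoint components decay backwards in time (at the orbit's
  # Floquet rates, the slowest being the T-current gate), so a long backward
  # stretch with dense output over the final two periods suffices.
  rhs <- function(s, z, parms) {
    y <- as.numeric(orbit_state(lc, -omega * s))
    list(as.numeric(crossprod(thal_jacobian(y, pv), z)))
  }
  total <- n_periods * lc$T
  s_tail <- total - lc$T * rev(seq(0, 2, length.out = 2L * M + 1L))
  sample_s <- c(0, s_tail)
  out <- deSolve::ode(c(1, 0, 0), sample_s, rhs, NULL, method = "lsoda",
                      rtol = rtol, atol = 1e-12, maxsteps = 2000000)
  if (nrow(out) < length(sample_s)) stop("adjoint integration failed")
  tail_rows <- out[-1, -1, drop = FALSE]  # 2M + 1 rows over the last 2 periods
  y0 <- as.numeric(orbit_state(lc, 0))
  f0 <- as.numeric(cpp_thal_rhs(matrix(y0, 1), 0, pv))
  scl <- omega / sum(tail_rows[nrow(tail_rows), ] * f0)
  tail_rows <- tail_rows * scl
  p1 <- tail_rows[1:(M + 1), , drop = FALSE]
  p2 <- tail_rows[(M + 1):(2 * M + 1), , drop = FALSE]
  rel <- max(abs(p2 - p1)) / max(abs(p2))
  if (!is.finite(rel) || rel > conv_tol) {
    stop("adjoint did not converge to a periodic solution (relative change ",
         signif(rel, 3), ")")
  }

  # final-period samples at s = total - T + j T/M correspond to
  # theta = -omega s = 2 pi (1 - j/M) mod 2 pi
  zmat <- p2[1:M, , drop = FALSE]
  idx <- c(1, M:2)  # reorder to increasing theta
  adj <- zmat[idx, , drop = FALSE]
  theta <- 2 * pi * seq(0, M - 1) / M

  # <z, xdot> is conserved exactly along the adjoint flow, so any pointwise
  # departure from omega is integrator drift of the neutral component;
  # project it out by normalising at every grid point, then report the
  # residual of the normalised solution as the consistency diagnostic.
  xs <- orbit_state(lc, theta)
  fdot <- cpp_thal_rhs(xs, 0, pv)
  ip <- rowSums(adj * fdot)
  adj <- adj * (omega / ip)
  resid <- rowSums(adj * fdot) / omega - 1

  z_coef <- fourier_fit(adj[, 1], n_harm = lc$n_harm)
  ev <- cpp_fourier_eval(z_coef, theta)
  fv <- cpp_fourier_eval(lc$f_coef, theta)
  curves <- tibble::tibble(theta = theta,
                           Z = ev[, 1], dZ = ev[, 2], d2Z = ev[, 3],
                           f = fv[, 1], df = fv[, 2], d2f = fv[, 3])
  structure(list(curves = curves, z_coef = z_coef, f_coef = lc$f_coef,
                 adjoint = adj, norm_resid = resid,
                 T = lc$T, omega = omega, lc = lc, params = params),
            class = "prc")
}

#' @export
print.prc <- function(x, ...) {
  cat(sprintf("Phase response curve: T = %.4f ms, max Z = %.4g at theta = %.2f\n",
              x$T, max(x$curves$Z), x$curves$theta[which.max(x$curves$Z)]))
  cat(sprintf("  normalisation residual (max |<Z,xdot>/omega - 1|): %.2e\n",
              max(abs(x$norm_resid))))
  invisible(x)
}

#' Phase response curve by direct perturbation
#'
#' Independent check of the adjoint PRC: delivers small instantaneous
#' voltage kicks of opposite signs at a set of phases, measures the
#' asymptotic spike-time shift after several periods, and forms the central
#' difference. Slow (one pair of simulations per phase); intended for
#' validation rather than production use.
#'
#' @param lc a [find_limit_cycle()] object.
#' @param phases phases at which to probe (radians).
#' @param dv kick amplitude (mV).
#' @param n_settle periods to wait before reading the phase shift.
#' @param rtol integrator tolerance.
#' @return tibble with columns `theta` and `Z`.
#' @export
compute_prc_direct <- function(lc, phases = 2 * pi * (0:31) / 32, dv = 0.05,
                               n_settle = 30L, rtol = 1e-10) {
  pv <- par_vec(lc$params)
  rhs <- function(t, y, parms) list(as.numeric(cpp_thal_rhs(matrix(y, 1), 0, pv)))
  horizon <- (n_settle + 1) * lc$T
  times <- seq(0, horizon, by = 0.002)
  last_spike <- function(y0) {
    out <- deSolve::ode(y0, times, rhs, NULL, method = "lsoda",
                        rtol = rtol, atol = 1e-12)
    spk <- detect_spikes(out[, 1], out[, 2], lc$spike_threshold)
    spk[length(spk)]
  }
  Z <- vapply(phases, function(th) {
    y <- as.numeric(orbit_state(lc, th))
    tp <- last_spike(y + c(dv, 0, 0))
    tm <- last_spike(y - c(dv, 0, 0))
    # a positive phase advance makes the late spikes come earlier; wrap the
    # raw shift so a kick that carries a spike across the horizon boundary
    # (off-by-one spike count) cannot alias by a full period
    d <- (lc$omega * (tm - tp) + pi) %% (2 * pi) - pi
    d / (2 * dv)
  }, numeric(1))
  tibble::tibble(theta = phases, Z = Z)
}

#' Evaluate PRC quantities at arbitrary phase
#'
#' Evaluates the smoothed Fourier representation of the PRC `Z`, the
#' on-orbit voltage map `f`, or their first and second phase derivatives at
#' arbitrary phases.
#'
#' @param prc a [compute_prc()] object.
#' @param theta phases (radians).
#' @param quantity one of `"Z"`, `"dZ"`, `"d2Z"`, `"f"`, `"df"`, `"d2f"`.
#' @return numeric vector.
#' @export
prc_eval <- function(prc, theta,
                     quantity = c("Z", "dZ", "d2Z", "f", "df", "d2f")) {
  quantity <- match.arg(quantity)
  coef <- if (grepl("Z", quantity)) prc$z_coef else prc$f_coef
  deriv <- c(Z = 0L, dZ = 1L, d2Z = 2L, f = 0L, df = 1L, d2f = 2L)[[quantity]]
  fourier_eval(coef, theta, deriv)
}
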