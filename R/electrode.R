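# Electrode-electrolyte interface: double-layer capacitance C_dl in parallel
# with a Faradaic charge-transfer resistance R_ct, in series with the
# spreading resistance R_s of the extracellular medium. The probe drive and
# the field seen by the neurons are carried in "u-units" (a fixed positive
# scaling of volts, u = -F(d) V / (R_i C)); the circuit ODE is identical in
# either unit system. Internally all time constants are in ms.

#' Electrode circuit parameters
#'
#' @param C_dl double-layer capacitance (F).
#' @param R_ct Faradaic charge-transfer resistance (Ohm).
#' @param R_s spreading resistance of the extracellular medium (Ohm).
#' @return object of class `circuit_params`. The derived rate constants
#'   `kct = 1/(C_dl R_ct)` and `ks = 1/(C_dl R_s)` are stored in 1/ms.
#' @export
circuit_params <- function(C_dl = 5e-4, R_ct = 2e5, R_s = 29) {
  stopifnot(C_dl > 0, R_ct > 0, R_s > 0)
  structure(list(C_dl = C_dl, R_ct = R_ct, R_s = R_s,
                 kct = 1 / (C_dl * R_ct * 1000),  # F * Ohm = s -> ms
                 ks = 1 / (C_dl * R_s * 1000)),
            class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat(sprintf("Electrode circuit: C_dl = %g F, R_ct = %g Ohm, R_s = %g Ohm\n",
              x$C_dl, x$R_ct, x$R_s))
  cat(sprintf("  time constants: C_dl*R_ct = %g ms, C_dl*R_s = %g ms\n",
              1 / x$kct, 1 / x$ks))
  invisible(x)
}

#' Probe geometry and effective-input scaling
#'
#' @param probe_radius spherical probe radius (mm).
#' @param distance neuron distance from the probe centre (mm).
#' @param R_i effective intra-axonal resistance (model units); only needed
#'   for conversions between volts and effective input units.
#' @param C membrane capacitance (uF/cm^2).
#' @return object of class `field_geometry` with the effective strength
#'   `F = effective_strength(probe_radius, distance)` precomputed.
#' @export
field_geometry <- function(probe_radius = 0.5, distance = 1, R_i = NA_real_, C = 1) {
  structure(list(probe_radius = probe_radius, distance = distance,
                 R_i = R_i, C = C,
                 F = effective_strength(probe_radius, distance)),
            class = "field_geometry")
}

#' Extracellular potential of a spherical probe
#'
#' Laplace solution outside a conducting sphere held at potential `V_e`:
#' `V(r) = V_e * a / r`, equal to `V_e` on the probe surface and decaying to
#' zero at infinity.
#'
#' @param a probe radius (mm).
#' @param V_e potential at the probe surface (V).
#' @param r radial distance from the probe centre (mm), at least `a`.
#' @return potential (V) at `r`.
#' @export
probe_potential <- function(a, V_e, r) {
  stopifnot(a > 0)
  if (any(r < a)) stop("r < a: point lies inside the probe")
  V_e * a / r
}

#' Effective stimulus strength at distance d
#'
#' Second spatial derivative of the extracellular potential along the
#' direction perpendicular to the probe-neuron line, evaluated with the
#' probe at -1 V (the activating-function scaling). For the spherical probe
#' the closed form is `F(d) = a / d^3`.
#'
#' @param a probe radius (mm).
#' @param d neuron distance from the probe centre (mm), `d > a`.
#' @return effective strength (V/mm^2), positive and decreasing in `d`.
#' @export
effective_strength <- function(a, d) {
  stopifnot(a > 0)
  if (any(d <= a)) stop("d <= a: neuron must lie outside the probe")
  a / d^3
}

#' Simulate the electrode circuit
#'
#' Solves `du_e/dt = du_p/dt + kct (u_p - u_e) - ks u_e` for a sampled probe
#' drive `u_p(t)` on a uniform grid, using the exact exponential update of
#' the continuous variable `w = u_e - u_p` (which obeys
#' `dw/dt = -(kct + ks) w - ks u_p` and stays continuous across steps in
#' `u_p`, so pulse edges are propagated to `u_e` without numerical smearing).
#' `u_p` is treated as piecewise linear between samples.
#'
#' @param waveform a data frame with columns `t` (ms, uniform) and `u_p`, or
#'   a numeric vector of `u_p` samples (then `dt` must be given).
#' @param params a [circuit_params()] object.
#' @param ue0 initial field value `u_e(0)` (defaults to 0).
#' @param dt sample interval when `waveform` is a bare vector.
#' @return tibble with columns `t`, `u_p`, `u_e`.
#' @export
simulate_circuit <- function(waveform, params = circuit_params(), ue0 = 0, dt = NULL) {
  if (is.data.frame(waveform)) {
    t <- waveform$t
    up <- waveform$u_p
    dt <- t[2] - t[1]
    if (max(abs(diff(t) - dt)) > 1e-9) stop("waveform grid must be uniform")
  } else {
    if (is.null(dt)) stop("dt required when waveform is a bare vector")
    up <- as.numeric(waveform)
    t <- (seq_along(up) - 1) * dt
  }
  if (dt > 0.1 / params$ks) {
    warning("waveform grid coarser than C_dl*R_s/10; circuit response may be ",
            "under-resolved")
  }
  a <- params$kct + params$ks
  E <- exp(-a * dt)
  I0 <- (1 - E) / a
  I1 <- (dt - I0) / a
  n <- length(up)
  w0 <- ue0 - up[1]
  q <- -params$ks * (up[-n] * I0 + diff(up) / dt * I1)
  w <- c(w0, stats::filter(q, E, method = "recursive", init = w0))
  tibble::tibble(t = t, u_p = up, u_e = as.numeric(w) + up)
}

#' Circuit transfer gain (V_p - V_e)/V_p
#'
#' Frequency response of the double-layer voltage relative to the probe
#' drive: `R_ct / (R_ct + R_s (R_ct C_dl s + 1))` at `s = i * freq`.
#' A fast pulse passes to the field with little double-layer drop (small
#' Faradaic current); a slow drive loses amplitude across the interface.
#'
#' @param freq angular frequency (rad/ms); 0 gives the DC gain.
#' @param params a [circuit_params()] object.
#' @return complex gain, same length as `freq`.
#' @export
transfer_gain <- function(freq, params = circuit_params()) {
  s <- 1i * freq
  tau <- 1 / params$kct  # R_ct C_dl in ms
  params$R_ct / (params$R_ct + params$R_s * (tau * s + 1))
}

#' Convert a voltage waveform to effective input units (and back)
#'
#' Effective input `u = -F(d) V / (R_i C)`: the current effectively injected
#' into a neuron at distance `d` per unit membrane capacitance, for a probe
#' (or field) voltage `V`. `from_effective_input()` is the exact inverse.
#'
#' @param V voltage samples (V).
#' @param geom a [field_geometry()] object with `R_i` specified.
#' @return numeric vector in u-units.
#' @export
to_effective_input <- function(V, geom) {
  if (!is.finite(geom$R_i) || geom$R_i == 0) {
    stop("R_i must be specified and non-zero for unit conversion")
  }
  -geom$F * V / (geom$R_i * geom$C)
}

#' @rdname to_effective_input
#' @param u effective-input samples (u-units).
#' @export
from_effective_input <- function(u, geom) {
  if (!is.finite(geom$R_i) || geom$R_i == 0) {
    stop("R_i must be specified and non-zero for unit conversion")
  }
  -u * geom$R_i * geom$C / geom$F
}

#' Read/write stimulus waveforms as CSV
#'
#' Waveform CSV files carry columns `t_ms`, `u_p` and (optionally) `u_e`.
#'
#' @param waveform tibble with columns `t`, `u_p` and optionally `u_e`.
#' @param path file path.
#' @return `read_waveform_csv` returns a tibble with columns `t`, `u_p` and,
#'   when present in the file, `u_e`.
#' @export
write_waveform_csv <- function(waveform, path) {
  df <- data.frame(t_ms = waveform$t, u_p = waveform$u_p)
  if (!is.null(waveform$u_e)) df$u_e <- waveform$u_e
  utils::write.csv(df, path, row.names = FALSE)
  invisible(waveform)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path)
  out <- tibble::tibble(t = df$t_ms, u_p = df$u_p)
  if (!is.null(df$u_e)) out$u_e <- df$u_e
  out
}
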