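# Reduced conductance-based thalamocortical neuron: leak, sodium, potassium
# and low-threshold calcium (T) currents with two gating variables (h, r).
# Functional forms follow the Rubin-Terman thalamic cell. Units: mV, ms,
# uA/cm^2, uF/cm^2.

#' Parameters of the reduced thalamic neuron
#'
#' Returns the parameter set of the periodically spiking thalamic cell used
#' throughout the package. At the defaults (baseline current
#' `I_SM = 5` uA/cm^2, `C = 1` uF/cm^2) the free-running period is 8.395 ms,
#' which serves as the calibration anchor for the model transcription.
#'
#' @param C membrane capacitance (uF/cm^2).
#' @param I_SM baseline (depolarising) current (uA/cm^2).
#' @param g_L,E_L leak conductance (mS/cm^2) and reversal potential (mV).
#' @param g_Na,E_Na sodium conductance and reversal potential.
#' @param g_K,E_K potassium conductance and reversal potential.
#' @param g_T,E_T T-type calcium conductance and reversal potential.
#' @return an object of class `neuron_params` (named list).
#' @examples
#' p <- neuron_params()
#' p$I_SM
#' @export
neuron_params <- function(C = 1, I_SM = 5, g_L = 0.05, E_L = -70,
                          g_Na = 3, E_Na = 50, g_K = 5, E_K = -90,
                          g_T = 5, E_T = 0) {
  stopifnot(C > 0)
  structure(list(C = C, I_SM = I_SM, g_L = g_L, E_L = E_L, g_Na = g_Na,
                 E_Na = E_Na, g_K = g_K, E_K = E_K, g_T = g_T, E_T = E_T),
            class = "neuron_params")
}

# flat numeric vector in the layout the compiled code expects
par_vec <- function(params) {
  with(params, c(C, I_SM, g_L, E_L, g_Na, E_Na, g_K, E_K, g_T, E_T))
}

as_state_matrix <- function(state) {
  if (is.data.frame(state)) state <- as.matrix(state[, c("V", "h", "r")])
  if (is.null(dim(state))) state <- matrix(state, nrow = 1)
  if (any(!is.finite(state))) stop("non-finite neuron state")
  state
}

#' Total intrinsic membrane current
#'
#' Signed sum of the intrinsic currents,
#' `I_m = -I_L - I_Na - I_K - I_T + I_SM`, so that `dV/dt = (I_m + I_app)/C`.
#'
#' @param state a data frame (or length-3 vector) with columns `V`, `h`, `r`.
#' @param params a [neuron_params()] object.
#' @return numeric vector of membrane currents (uA/cm^2), one per row.
#' @export
membrane_current <- function(state, params = neuron_params()) {
  as.numeric(cpp_thal_im(as_state_matrix(state), par_vec(params)))
}

#' Single-cell vector field
#'
#' Time derivative of the neuron state `(V, h, r)` under an applied current:
#' `dV/dt = (I_m + i_applied)/C`, with first-order gating relaxation
#' `dh/dt = (h_inf(V) - h)/tau_h(V)` and `dr/dt = (r_inf(V) - r)/tau_r(V)`.
#'
#' @inheritParams membrane_current
#' @param i_applied applied current (uA/cm^2), recycled across rows.
#' @return a tibble with columns `dV`, `dh`, `dr`.
#' @export
vector_field <- function(state, params = neuron_params(), i_applied = 0) {
  m <- cpp_thal_rhs(as_state_matrix(state), as.numeric(i_applied), par_vec(params))
  tibble::tibble(dV = m[, 1], dh = m[, 2], dr = m[, 3])
}

#' Simulate a single deterministic neuron
#'
#' Integrates the single-cell model with an adaptive solver
#' ([deSolve::ode()], `lsoda`) and detects spikes as upward crossings of a
#' voltage threshold, located by linear interpolation between samples.
#'
#' @param params a [neuron_params()] object.
#' @param i_applied applied current: a constant or a function of time (ms).
#' @param t_span length-2 numeric, simulation interval in ms.
#' @param init initial state `c(V, h, r)`.
#' @param dt_out output sampling interval (ms).
#' @param rtol relative tolerance of the adaptive integrator.
#' @param spike_threshold spike detection threshold (mV), crossed upward.
#' @return an object of class `neuron_trajectory`: a tibble with columns
#'   `t`, `V`, `h`, `r` and attributes `spikes` (spike times, ms) and
#'   `params`.
#' @examples
#' \donttest{
#' traj <- simulate_neuron(t_span = c(0, 100))
#' head(spike_times(traj))
#' }
#' @export
simulate_neuron <- function(params = neuron_params(), i_applied = 0,
                            t_span = c(0, 300), init = c(V = -65, h = 0.4, r = 0.2),
                            dt_out = 0.01, rtol = 1e-8, spike_threshold = -20) {
  stopifnot(length(t_span) == 2, all(is.finite(t_span)))
  pv <- par_vec(params)
  cur <- if (is.function(i_applied)) i_applied else function(t) i_applied
  rhs <- function(t, y, parms) {
    if (!all(is.finite(y))) stop("non-finite state at t = ", t)
    list(as.numeric(cpp_thal_rhs(matrix(y, 1), cur(t), pv)))
  }
  times <- seq(t_span[1], t_span[2], by = dt_out)
  out <- deSolve::ode(y = unname(init), times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = rtol, maxsteps = 500000)
  if (nrow(out) < length(times)) {
    stop("solver failed; last valid time ", max(out[, 1]))
  }
  traj <- tibble::tibble(t = out[, 1], V = out[, 2], h = out[, 3], r = out[, 4])
  spk <- detect_spikes(traj$t, traj$V, spike_threshold)
  structure(traj, spikes = spk, params = params, class = c("neuron_trajectory", class(traj)))
}

# upward threshold crossings with linear interpolation
detect_spikes <- function(t, V, threshold = -20) {
  n <- length(V)
  i <- which(V[-n] < threshold & V[-1] >= threshold)
  if (!length(i)) return(numeric(0))
  t[i] + (t[i + 1] - t[i]) * (threshold - V[i]) / (V[i + 1] - V[i])
}

#' Spike times of a simulated trajectory
#'
#' @param traj a `neuron_trajectory` from [simulate_neuron()].
#' @return numeric vector of spike times (ms).
#' @export
spike_times <- function(traj) attr(traj, "spikes")

#' Free-running inter-spike period
#'
#' Simulates the unforced neuron long enough for transients in the slow
#' T-current gate to die out and returns the mean inter-spike interval over
#' the final stretch.
#'
#' @param params a [neuron_params()] object.
#' @param settle transient discard time (ms).
#' @param measure measurement window after the transient (ms).
#' @param rtol integrator relative tolerance.
#' @return period (ms).
#' @export
free_running_period <- function(params = neuron_params(), settle = 1200,
                                measure = 120, rtol = 1e-10) {
  pv <- par_vec(params)
  rhs <- function(t, y, parms) list(as.numeric(cpp_thal_rhs(matrix(y, 1), 0, pv)))
  o1 <- deSolve::ode(c(-65, 0.4, 0.2), c(0, settle), rhs, NULL,
                     method = "lsoda", rtol = rtol, atol = rtol, maxsteps = 500000)
  y0 <- o1[nrow(o1), -1]
  o2 <- deSolve::ode(y0, seq(0, measure, by = 0.002), rhs, NULL,
                     method = "lsoda", rtol = rtol, atol = rtol, maxsteps = 500000)
  spk <- detect_spikes(o2[, 1], o2[, 2])
  if (length(spk) < 4) stop("not oscillating: fewer than 4 spikes detected")
  mean(diff(spk))
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("Reduced thalamic neuron parameters\n")
  cat(sprintf("  C = %g uF/cm^2, I_SM = %g uA/cm^2\n", x$C, x$I_SM))
  cat(sprintf("  g_L=%g (E_L=%g), g_Na=%g (E_Na=%g), g_K=%g (E_K=%g), g_T=%g (E_T=%g)\n",
              x$g_L, x$E_L, x$g_Na, x$E_Na, x$g_K, x$E_K, x$g_T, x$E_T))
  invisible(x)
}

#' Export a trajectory to CSV and its spike times to JSON
#'
#' @param traj a `neuron_trajectory`.
#' @param csv_path,json_path output file paths (`NULL` to skip either).
#' @return `traj`, invisibly.
#' @export
write_trajectory <- function(traj, csv_path, json_path = NULL) {
  utils::write.csv(as.data.frame(traj)[, c("t", "V", "h", "r")], csv_path,
                   row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(spike_times(traj), json_path, auto_unbox = FALSE, digits = NA)
  }
  invisible(traj)
}
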