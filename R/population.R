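# Stochastic simulation of the electrotonically coupled neuron population
# with the electrode circuit in the loop. All-to-all coupling
# (1/N) sum_j sigma (V_j - V_i) (sigma_ii = 0) reduces to sigma (Vbar - V_i).
# Integration: fixed-step stochastic Heun (two-stage second-order
# Runge-Kutta drift with Euler-Maruyama Gaussian increments on the voltage),
# with the circuit advanced by its exact exponential update each step.

#' Network simulation configuration
#'
#' @param N population size.
#' @param sigma electrotonic coupling strength (all-to-all, zero diagonal).
#' @param noise_2D noise variance parameter `2D`; the voltage equation
#'   receives increments `sqrt(2D dt) N(0,1) / C`.
#' @param dt fixed integration step (ms); must resolve the spike upstroke.
#' @param duration simulated time (ms).
#' @param distances either `"homogeneous"` (all neurons at 1 mm) or a
#'   specification understood by [sample_distances()].
#' @param theta_center centre of the initial phase distribution (radians).
#' @param jitter_sd standard deviation of the i.i.d. initial phase jitter
#'   (radians) about `theta_center`.
#' @param seed RNG seed applied before initial-condition sampling and noise
#'   generation (`NULL` leaves the RNG state alone).
#' @param rec_dt state recording interval (ms); must be a multiple of `dt`.
#' @return object of class `network_config`.
#' @export
network_config <- function(N = 100, sigma = 0.07, noise_2D = 0.7, dt = 0.01,
                           duration = 300, distances = "homogeneous",
                           theta_center = pi, jitter_sd = 0.1, seed = NULL,
                           rec_dt = 0.1) {
  stopifnot(N >= 2, sigma >= 0, noise_2D >= 0, dt > 0, dt <= 0.02, duration > 0)
  structure(list(N = N, sigma = sigma, D = noise_2D / 2, noise_2D = noise_2D,
                 dt = dt, duration = duration, distances = distances,
                 theta_center = theta_center, jitter_sd = jitter_sd,
                 seed = seed, rec_dt = rec_dt),
            class = "network_config")
}

#' Sample neuron-probe distances and input scale factors
#'
#' Effective input scales with the inverse cube of the probe distance, so
#' each neuron's share of the field input is `(1/d_i)^3` relative to the
#' reference distance of 1 mm.
#'
#' @param spec `"homogeneous"` (all at 1 mm) or a list
#'   `list(law = "uniform", min =, max =)` / `list(law = "lognormal",
#'   meanlog =, sdlog =)`.
#' @param N number of neurons.
#' @param seed RNG seed (`NULL` leaves the RNG state alone).
#' @param probe_radius probe radius (mm); all sampled distances must exceed it.
#' @return tibble with columns `d` (mm) and `scale` (`F(d)/F(1)`).
#' @export
sample_distances <- function(spec = "homogeneous", N = 100, seed = NULL,
                             probe_radius = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  if (identical(spec, "homogeneous")) {
    d <- rep(1, N)
  } else if (is.list(spec)) {
    d <- switch(spec$law,
      uniform = stats::runif(N, spec$min, spec$max),
      lognormal = stats::rlnorm(N, spec$meanlog, spec$sdlog),
      stop("unsupported distance law: ", spec$law))
  } else if (is.numeric(spec)) {
    d <- rep_len(spec, N)
  } else {
    stop("unsupported distance specification")
  }
  if (any(d <= probe_radius)) stop("sampled distance inside the probe radius")
  tibble::tibble(d = d, scale = effective_strength(probe_radius, d) /
                   effective_strength(probe_radius, 1))
}

#' Charge-balanced biphasic pulse train
#'
#' Repeats `[+A for w, -A for w, 0 for period - 2w]` (anodic phase first by
#' default; the energy and charge-balance metrics are order-invariant). The
#' integral of `u_p` over each cycle is zero by construction.
#'
#' @param amplitude pulse amplitude in u-units.
#' @param phase_width width of each phase (ms).
#' @param period pulse repetition period (ms); must fit both phases.
#' @param duration total train length (ms).
#' @param dt sample interval (ms).
#' @param anodic_first `TRUE` for + then -, `FALSE` for the reverse.
#' @return tibble with columns `t` and `u_p`.
#' @export
pulsatile_waveform <- function(amplitude = 98, phase_width = 0.2, period = 4,
                               duration = 300, dt = 0.01, anodic_first = TRUE) {
  stopifnot(2 * phase_width <= period)
  t <- seq(0, duration, by = dt)
  tp <- t %% period
  s <- if (anodic_first) 1 else -1
  eps <- 1e-9
  # each cycle starts from zero so the leading edge (and its capacitive
  # transmission to the field) falls inside the simulated window
  up <- ifelse(tp > eps & tp <= phase_width + eps, s * amplitude,
               ifelse(tp > phase_width + eps & tp <= 2 * phase_width + eps,
                      -s * amplitude, 0))
  tibble::tibble(t = t, u_p = up)
}

#' Total injected energy of a field waveform
#'
#' `int u_e^2 dt` by trapezoidal quadrature (u-units squared times ms).
#'
#' @param waveform data frame with `t` and `u_e` columns, or a
#'   `population_trace`.
#' @return scalar energy.
#' @export
energy_metric <- function(waveform) {
  if (inherits(waveform, "population_trace")) return(attr(waveform, "energy"))
  trapz(waveform$t, waveform$u_e^2)
}

#' Total Faradaic charge-transfer measure
#'
#' `int |u_p - u_e| / R_ct dt`: the (rectified) current through the
#' charge-transfer resistance, integrated over the record.
#'
#' @param waveform data frame with `t`, `u_p`, `u_e`, or a `population_trace`.
#' @param R_ct charge-transfer resistance (Ohm).
#' @return scalar Faradaic measure.
#' @export
faradaic_metric <- function(waveform, R_ct = 2e5) {
  if (inherits(waveform, "population_trace")) {
    return(attr(waveform, "faradaic_raw") / R_ct)
  }
  if (length(waveform$t) != length(waveform$u_p) ||
      length(waveform$u_p) != length(waveform$u_e)) {
    stop("grid mismatch between u_p and u_e")
  }
  trapz(waveform$t, abs(waveform$u_p - waveform$u_e)) / R_ct
}

#' Simulate the coupled noisy network with the circuit in the loop
#'
#' Integrates all `3N` neuron states plus the electrode circuit with a
#' fixed-step stochastic Heun scheme. A shared field input `u_e` (scaled per
#' neuron by `F(d_i)/F(1)`) drives every neuron. Stimulation modes:
#' `"none"`, `"event"` (the two-state event-based controller triggers
#' playback of `stimulus` whenever the mean voltage crests above the trigger
#' threshold with negative slope) and `"pulsatile"` (continuous playback of
#' `stimulus` from `t = 0`). The circuit state persists across stimuli.
#'
#' @param cfg a [network_config()] object.
#' @param lc a [find_limit_cycle()] object (initial conditions are placed on
#'   the orbit at jittered phases, and the period is attached for phase
#'   inference).
#' @param stimulus a waveform (tibble `t`, `u_p`, e.g. from
#'   [design_stimulus()]`$waveform` or [pulsatile_waveform()]); `NULL` for
#'   mode `"none"`.
#' @param mode `"none"`, `"event"` or `"pulsatile"`.
#' @param circuit a [circuit_params()] object.
#' @param trigger_threshold,rearm_threshold controller thresholds (mV): a
#'   stimulus is triggered when the mean voltage exceeds `trigger_threshold`
#'   with negative slope; an inactive controller re-arms when the mean
#'   voltage registers above `rearm_threshold`.
#' @param lockout window (ms) after a stimulus with no mean-voltage
#'   excursion above the trigger threshold that switches the controller to
#'   its inactive state; defaults to 1.5 periods.
#' @param init optional explicit initial state matrix (`N x 3`), overriding
#'   phase-based initialisation.
#' @return object of class `population_trace`: tibble with `t`, `vbar`,
#'   `u_p`, `u_e` at full resolution, with recorded state matrices, spike
#'   raster, controller trigger times and energy/Faradaic totals attached as
#'   attributes.
#' @export
simulate_network <- function(cfg, lc, stimulus = NULL,
                             mode = c("none", "event", "pulsatile"),
                             circuit = circuit_params(),
                             trigger_threshold = -45, rearm_threshold = -40,
                             lockout = NULL, init = NULL) {
  mode <- match.arg(mode)
  if (mode != "none" && is.null(stimulus)) stop("mode ", mode, " needs a stimulus")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  params <- lc$params
  if (is.null(lockout)) lockout <- 1.5 * lc$T

  if (is.null(init)) {
    th0 <- (cfg$theta_center + stats::rnorm(cfg$N, 0, cfg$jitter_sd)) %% (2 * pi)
    init <- orbit_state(lc, th0)
  }
  dist <- sample_distances(cfg$distances, cfg$N, seed = NULL)

  if (is.null(stimulus)) {
    stim <- c(0, 0); stim_dt <- 1
  } else {
    stim <- stimulus$u_p
    stim_dt <- stimulus$t[2] - stimulus$t[1]
  }
  nsteps <- round(cfg$duration / cfg$dt)
  rec_stride <- max(1L, round(cfg$rec_dt / cfg$dt))
  nsteps <- (nsteps %/% rec_stride) * rec_stride

  out <- cpp_network_sim(init, par_vec(params), cfg$dt, nsteps, cfg$sigma,
                         cfg$D, dist$scale, stim, stim_dt,
                         match(mode, c("none", "event", "pulsatile")) - 1L,
                         circuit$kct, circuit$ks,
                         trigger_threshold, rearm_threshold, lockout,
                         rec_stride)

  tfull <- seq(0, nsteps) * cfg$dt
  trace <- tibble::tibble(t = tfull, vbar = out$vbar, u_p = out$u_p, u_e = out$u_e)
  raster <- do.call(rbind, lapply(seq_len(cfg$N), function(i) {
    st <- detect_spikes(out$t, out$V[, i], lc$spike_threshold)
    if (length(st)) data.frame(neuron = i, spike_time = st) else NULL
  }))
  structure(trace,
            states = list(t = out$t, V = out$V, h = out$h, r = out$r),
            raster = tibble::as_tibble(raster %||% data.frame(neuron = integer(),
                                                              spike_time = numeric())),
            energy = out$energy, faradaic_raw = out$faradaic_raw,
            triggers = out$triggers, config = cfg, params = params,
            period = lc$T, spike_threshold = lc$spike_threshold,
            distances = dist, mode = mode,
            class = c("population_trace", class(trace)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spike raster of a population trace
#'
#' @param trace a `population_trace`.
#' @return tibble with columns `neuron` and `spike_time`.
#' @export
spike_raster <- function(trace) attr(trace, "raster")

#' Controller trigger times of a population trace
#'
#' @param trace a `population_trace`.
#' @return numeric vector of stimulus onset times (ms).
#' @export
controller_triggers <- function(trace) attr(trace, "triggers")

#' Step the event-based controller over a mean-voltage history
#'
#' Reference implementation of the two-state controller used inside
#' [simulate_network()], exposed for inspection and testing: given a sampled
#' mean-voltage history it returns the stimulus trigger times and the
#' active/inactive state at every sample. The controller triggers (once per
#' upward excursion) when the mean voltage exceeds `trigger_threshold` with
#' negative slope, goes inactive when no excursion above the trigger
#' threshold occurs within `lockout` after the last stimulus ends, and
#' re-arms when the mean voltage registers above `rearm_threshold`.
#'
#' @param vbar sampled mean voltage (mV).
#' @param dt sample interval (ms).
#' @param stim_length stimulus playback length (ms).
#' @param trigger_threshold,rearm_threshold,lockout controller parameters.
#' @return list with `triggers` (times) and `active` (logical per sample).
#' @export
controller_step <- function(vbar, dt, stim_length,
                            trigger_threshold = -45, rearm_threshold = -40,
                            lockout = 12.6) {
  n <- length(vbar)
  active <- logical(n)
  playing <- FALSE
  armed <- TRUE
  state_active <- TRUE
  play_end <- -Inf
  last_end <- -Inf
  last_up <- 0
  triggers <- numeric(0)
  for (s in 2:n) {
    t_now <- (s - 1) * dt
    if (playing && t_now >= play_end) playing <- FALSE
    if (vbar[s - 1] <= trigger_threshold && vbar[s] > trigger_threshold) {
      last_up <- t_now; armed <- TRUE
    }
    if (state_active && !playing && armed &&
        vbar[s] > trigger_threshold && vbar[s] < vbar[s - 1]) {
      playing <- TRUE
      play_end <- t_now + stim_length
      last_end <- play_end
      armed <- FALSE
      triggers <- c(triggers, t_now)
    }
    if (state_active && !playing && t_now - last_end > lockout && last_up < last_end) {
      state_active <- FALSE
    }
    if (!state_active && vbar[s] > rearm_threshold) { state_active <- TRUE; armed <- FALSE }
    active[s] <- state_active
  }
  active[1] <- active[2]
  list(triggers = triggers, active = active)
}
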