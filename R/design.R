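# Locally optimal stimulus design. The cost
#   G = int_0^t1 [ u_e^2 + alpha (du_p/dt)^2 - beta Z'(theta) u_e
#                  + gamma (u_p - u_e)^2 ] dt
# trades energy, probe slew, desynchronising action (the finite-time Lyapunov
# integrand) and Faradaic current. Its Euler-Lagrange equations form a
# six-dimensional two-point boundary-value problem in
# (X1 = u_p, X2 = du_p/dt, theta, u_e, lambda1, lambda2) with
# X1(0) = X2(0) = theta(0) = u_e(0) = 0 and X1(t1) = u_e(t1) = 0, solved by
# shooting on the initial Lagrange multipliers with a double (nested)
# bisection.

#' Control weights for stimulus design
#'
#' @param alpha probe-slew weight (must be positive: it regularises the
#'   problem, which is otherwise singular in the control).
#' @param beta Lyapunov-exponent weight.
#' @param gamma Faradaic-current weight.
#' @param t1 stimulus duration (ms); should be slightly below the neuron's
#'   period so the stimulus ends before the next spike.
#' @param sigma electrotonic coupling strength used by the coupled design
#'   variant (0 recovers the uncoupled problem).
#' @return object of class `control_weights`.
#' @export
control_weights <- function(alpha = 0.2, beta = 50, gamma = 8, t1 = 8.02,
                            sigma = 0) {
  stopifnot(alpha > 0, beta >= 0, gamma >= 0, t1 > 0, sigma >= 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, t1 = t1,
                 sigma = sigma), class = "control_weights")
}

el_par_vec <- function(weights, prc, circuit, coupled) {
  sig <- if (coupled) weights$sigma else 0
  c(weights$alpha, weights$beta, weights$gamma, sig, prc$omega,
    circuit$kct, circuit$ks)
}

#' Euler-Lagrange right-hand side
#'
#' Time derivative of the boundary-value state
#' `(X1, X2, theta, u_e, lambda1, lambda2)`. The constant mass matrix of the
#' system is inverted once symbolically: `dX1 = X2`,
#' `dX2 = (r2 + r4)/(2 alpha)`, `dtheta = omega + Z(theta) u_e`,
#' `du_e = X2 + kct (X1 - u_e) - ks u_e`, `dlambda1 = r4`, `dlambda2 = r3`,
#' where `r2, r3, r4` are the multiplier/stationarity entries; the coupled
#' variant adds `beta*sigma*(f''(theta) Z(theta) + f'(theta) Z'(theta))` to
#' the `dlambda2` channel.
#'
#' @param state numeric vector (length 6) or matrix/data frame with columns
#'   `X1, X2, theta, u_e, lambda1, lambda2`.
#' @param weights a [control_weights()] object.
#' @param prc a [compute_prc()] object.
#' @param circuit a [circuit_params()] object.
#' @param coupled use the coupled variant with `weights$sigma`.
#' @return tibble of the six time derivatives.
#' @export
el_rhs <- function(state, weights, prc, circuit = circuit_params(),
                   coupled = weights$sigma > 0) {
  if (weights$alpha == 0) stop("alpha = 0: the control problem is singular")
  if (is.data.frame(state)) {
    state <- as.matrix(state[, c("X1", "X2", "theta", "u_e", "lambda1", "lambda2")])
  }
  if (is.null(dim(state))) state <- matrix(state, nrow = 1)
  m <- cpp_el_rhs(state, el_par_vec(weights, prc, circuit, coupled),
                  prc$z_coef, prc$f_coef)
  tibble::tibble(dX1 = m[, 1], dX2 = m[, 2], dtheta = m[, 3],
                 du_e = m[, 4], dlambda1 = m[, 5], dlambda2 = m[, 6])
}

#' Shoot the Euler-Lagrange system from trial multipliers
#'
#' Integrates the system from the stated zero initial conditions with trial
#' initial multipliers and returns the terminal residual pair
#' `(X1(t1), u_e(t1))`, which a converged solution drives to zero. Blow-up
#' before `t1` yields large sentinel residuals flagged by the `blowup`
#' attribute.
#'
#' @param lambda1_0,lambda2_0 trial initial Lagrange multipliers.
#' @inheritParams el_rhs
#' @param rtol integrator relative tolerance.
#' @return length-2 numeric `c(X1_t1, ue_t1)` with attribute `blowup`.
#' @export
shoot <- function(lambda1_0, lambda2_0, weights, prc, circuit = circuit_params(),
                  coupled = weights$sigma > 0, rtol = 1e-9) {
  out <- cpp_el_integrate(lambda1_0, lambda2_0,
                          el_par_vec(weights, prc, circuit, coupled),
                          prc$z_coef, prc$f_coef, weights$t1, rtol, 1e8)
  if (ncol(out) < 7L || anyNA(out)) {
    return(structure(c(1e9, 1e9), blowup = TRUE))
  }
  structure(c(out[nrow(out), 2], out[nrow(out), 5]), blowup = FALSE)
}

# residual pair or NULL on blow-up
shoot_resid <- function(l1, l2, par, zc, fc, t1, rtol) {
  out <- cpp_el_integrate(l1, l2, par, zc, fc, t1, rtol, 1e8)
  if (ncol(out) < 7L || anyNA(out)) return(NULL)
  c(out[nrow(out), 2], out[nrow(out), 5])
}

#' Double-bisection search for the shooting multipliers
#'
#' Finds initial multiplier pairs `(lambda1_0, lambda2_0)` that satisfy both
#' terminal boundary conditions by nested bisection: an inner bisection
#' zeroes one terminal residual along one multiplier axis, and an outer
#' bisection zeroes the other residual along the other axis, tracking the
#' inner root. The pairing of residuals with axes is chosen automatically
#' from a coarse scan of the box (whichever orientation exhibits sign
#' changes). Several distinct local solutions may be returned.
#'
#' Note that the residual amplification of the boundary-value problem grows
#' like e^(2.2/ms * t1), so for durations near the full period the residuals
#' are only finite in a thin neighbourhood of each root and the box must
#' already be a reasonable bracket (see [design_stimulus()] for how such
#' brackets are produced); at shorter durations the box can be searched
#' blindly.
#'
#' @param weights,prc,circuit,coupled as in [el_rhs()].
#' @param box length-2 numeric: the symmetric search interval applied to both
#'   multipliers.
#' @param n_scan coarse scan resolution per axis.
#' @param tol bisection tolerance on the multipliers.
#' @param rtol shooting integrator tolerance.
#' @return tibble with columns `lambda1_0`, `lambda2_0`, `resid_X1`,
#'   `resid_ue`; one row per converged root. Errors with the sampled residual
#'   grid attached if no sign change is found in the box.
#' @export
double_bisection <- function(weights, prc, circuit = circuit_params(),
                             coupled = weights$sigma > 0,
                             box = c(-200, 200), n_scan = 15, tol = 1e-10,
                             rtol = 1e-9) {
  par <- el_par_vec(weights, prc, circuit, coupled)
  zc <- prc$z_coef; fc <- prc$f_coef; t1 <- weights$t1
  res0 <- function(l1, l2) shoot_resid(l1, l2, par, zc, fc, t1, rtol)

  # orientations: (outer axis, inner axis, residual zeroed by the inner loop)
  orientations <- list(
    list(swap_axes = FALSE, swap_res = FALSE),
    list(swap_axes = TRUE,  swap_res = FALSE),
    list(swap_axes = FALSE, swap_res = TRUE),
    list(swap_axes = TRUE,  swap_res = TRUE))

  run_orientation <- function(ori) {
    res <- function(a, b) {
      r <- if (ori$swap_axes) res0(b, a) else res0(a, b)
      if (is.null(r)) return(NULL)
      if (ori$swap_res) rev(r) else r  # element 2 is zeroed by the inner loop
    }
    inner_bisect <- function(a, lo, hi, rlo, rhi) {
      for (i in 1:80) {
        mid <- (lo + hi) / 2
        rm <- res(a, mid)
        if (is.null(rm)) return(NULL)
        if (sign(rm[2]) == sign(rlo[2])) { lo <- mid; rlo <- rm } else { hi <- mid; rhi <- rm }
        if (hi - lo < tol) break
      }
      mid <- (lo + hi) / 2
      r <- res(a, mid)
      if (is.null(r)) NULL else list(b = mid, r = r)
    }
    inner_roots <- function(a, bgrid) {
      rs <- lapply(bgrid, function(b) res(a, b))
      roots <- list()
      for (k in seq_len(length(bgrid) - 1)) {
        ri <- rs[[k]]; rj <- rs[[k + 1]]
        if (is.null(ri) || is.null(rj)) next
        if (sign(ri[2]) != sign(rj[2])) {
          r <- inner_bisect(a, bgrid[k], bgrid[k + 1], ri, rj)
          if (!is.null(r)) roots[[length(roots) + 1]] <- r
        }
      }
      roots
    }
    inner_near <- function(a, bseed, radius) {
      for (grow in 0:4) {
        rad <- radius * 2^grow
        roots <- inner_roots(a, seq(bseed - rad, bseed + rad, length.out = 9))
        if (length(roots)) {
          d <- vapply(roots, function(r) abs(r$b - bseed), numeric(1))
          return(roots[[which.min(d)]])
        }
      }
      NULL
    }
    agrid <- seq(box[1], box[2], length.out = n_scan)
    bgrid <- seq(box[1], box[2], length.out = n_scan)
    scan <- lapply(agrid, inner_roots, bgrid = bgrid)
    sols <- list()
    for (k in seq_len(length(agrid) - 1)) {
      ra <- scan[[k]]; rb <- scan[[k + 1]]
      if (!length(ra) || !length(rb)) next
      for (a0 in ra) {
        d <- vapply(rb, function(r) abs(r$b - a0$b), numeric(1))
        b0 <- rb[[which.min(d)]]
        if (sign(a0$r[1]) == sign(b0$r[1])) next
        lo <- agrid[k]; hi <- agrid[k + 1]
        alo <- a0; ahi <- b0
        for (i in 1:80) {
          mid <- (lo + hi) / 2
          seed <- (alo$b + ahi$b) / 2
          rad <- max(abs(ahi$b - alo$b), diff(box) * 1e-3, 10 * tol)
          rm <- inner_near(mid, seed, rad)
          if (is.null(rm)) break
          if (sign(rm$r[1]) == sign(alo$r[1])) { lo <- mid; alo <- rm } else { hi <- mid; ahi <- rm }
          if (hi - lo < tol) break
        }
        final <- inner_near((lo + hi) / 2, (alo$b + ahi$b) / 2,
                            max(abs(ahi$b - alo$b), 10 * tol))
        if (!is.null(final)) {
          a_val <- (lo + hi) / 2
          r_pair <- if (ori$swap_res) rev(final$r) else final$r
          lam <- if (ori$swap_axes) c(final$b, a_val) else c(a_val, final$b)
          sols[[length(sols) + 1]] <- c(lam, r_pair)
        }
      }
    }
    sols
  }

  sols <- list()
  for (ori in orientations) {
    sols <- run_orientation(ori)
    if (length(sols)) break
  }
  if (!length(sols)) {
    grid <- seq(box[1], box[2], length.out = n_scan)
    grid_dump <- do.call(rbind, lapply(grid, function(l1) {
      do.call(rbind, lapply(grid, function(l2) {
        r <- res0(l1, l2)
        c(l1, l2, if (is.null(r)) c(NA, NA) else r)
      }))
    }))
    colnames(grid_dump) <- c("lambda1_0", "lambda2_0", "resid_X1", "resid_ue")
    stop(structure(class = c("bracket_failed", "error", "condition"),
                   list(message = "bracket failed: no residual sign change in box",
                        call = sys.call(), grid = grid_dump)))
  }
  m <- do.call(rbind, sols)
  out <- tibble::tibble(lambda1_0 = m[, 1], lambda2_0 = m[, 2],
                        resid_X1 = m[, 3], resid_ue = m[, 4])
  out[!duplicated(round(cbind(out$lambda1_0, out$lambda2_0), 5)), ]
}

trapz <- function(t, y) sum(diff(t) * (y[-1] + y[-length(y)]) / 2)

# cost terms from a (t, u_p, u_e, theta) table
cost_terms_tbl <- function(t, up, ue, theta, weights, prc) {
  dZ <- fourier_eval(prc$z_coef, theta, 1L)
  dup <- c(diff(up)[1], diff(up, lag = 2) / 2, diff(up)[length(up) - 1]) / (t[2] - t[1])
  c(energy = trapz(t, ue^2),
    slew = weights$alpha * trapz(t, dup^2),
    lyap = -weights$beta * trapz(t, dZ * ue),
    faradaic = weights$gamma * trapz(t, (up - ue)^2))
}

#' Design a locally optimal desynchronizing stimulus
#'
#' Finds a locally optimal probe waveform for the design cost. Two solvers
#' are available:
#' \describe{
#'   \item{transcription (default)}{direct transcription of the control
#'     problem on a uniform time grid with an exact discrete adjoint
#'     gradient, minimised by L-BFGS from a canonical initial profile shaped
#'     like \eqn{(\beta/2) Z'(\omega t)}. Deterministic and robust; at the
#'     default weights it converges to the lowest-cost local optimum we know
#'     of, whose predicted exponent is confirmed by two-neuron
#'     conductance-model simulation.}
#'   \item{shooting}{solves the Euler-Lagrange two-point boundary-value
#'     problem by continuation in the Lyapunov weight \eqn{\beta} from the
#'     trivial zero-input root, with damped Newton correction of the two
#'     initial Lagrange multipliers. This tracks the solution branch
#'     connected to zero input (a different, weaker local optimum than the
#'     transcription default). The returned multipliers can be refined by
#'     [double_bisection()] in a bracketing box around them.}
#' }
#' The boundary-value problem is so unstable (terminal residuals amplify
#' trial multiplier errors by ~e^18 at the default duration) that blind
#' bracketing over a large multiplier box is not numerically meaningful;
#' see the methods vignette for the full discussion.
#'
#' Solutions whose field input exceeds `u_cap` are rejected: inputs that
#' large drive the neuron off its limit cycle, where the phase reduction
#' behind the design no longer holds.
#'
#' @inheritParams double_bisection
#' @param method `"transcription"` or `"shooting"` (see Details).
#' @param dt_out waveform output sampling interval (ms).
#' @param u_cap admissibility cap on `max |u_e|` (u-units).
#' @param sigma_eval coupling strength used for the reported coupled
#'   exponent diagnostics.
#' @param maxit iteration cap for the transcription optimiser.
#' @param mu terminal penalty weight enforcing `u_e(t1) = 0` in the
#'   transcription solver.
#' @return an object of class `dbs_stimulus`: list with `waveform` (tibble
#'   `t, u_p, u_e, theta`) and `diagnostics`, a one-row tibble holding the
#'   finite-time exponents over one period (`Lambda_T` along the driven
#'   phase; `Lambda_T_uniform` along the uniform rotation `theta = omega t`),
#'   the coupled exponents at `sigma_eval` under both conventions, the four
#'   cost terms, the terminal boundary residuals, the estimated (or exact,
#'   for shooting) initial Lagrange multipliers and the stationarity
#'   residual of the multiplier extraction.
#' @examples
#' \donttest{
#' prc <- compute_prc(find_limit_cycle())
#' stim <- design_stimulus(prc, control_weights(gamma = 8))
#' glance(stim)
#' }
#' @export
design_stimulus <- function(prc, weights = control_weights(),
                            circuit = circuit_params(),
                            coupled = weights$sigma > 0,
                            method = c("transcription", "shooting"),
                            box = c(-200, 200), n_scan = 15, tol = 1e-10,
                            rtol = 1e-9, dt_out = 0.005, u_cap = 50,
                            sigma_eval = 0.07, maxit = 8000, mu = 1e7) {
  method <- match.arg(method)
  if (weights$t1 >= prc$T) {
    warning("t1 >= period T: the stimulus should end before the next spike")
  }
  par <- el_par_vec(weights, prc, circuit, coupled)
  t1 <- weights$t1
  tt <- seq(0, t1, by = dt_out)
  if (tt[length(tt)] < t1 - 1e-12) tt <- c(tt, t1)
  n <- length(tt)

  if (method == "transcription") {
    sol <- design_transcription(prc, weights, circuit, par, tt, maxit, mu)
    up <- sol$up
    ue <- sol$ue
    theta <- sol$theta
    lam0 <- sol$lam0
    resid <- c(up[n], ue[n])
    el_rms <- sol$el_rms
  } else {
    lam0 <- el_continuation(prc, weights, circuit, coupled, rtol)
    # polish against the dense-output trajectory: the boundary-value problem
    # amplifies multiplier perturbations by ~e^18, so the root must be
    # refined with respect to the exact integration path that is returned
    dense_resid <- function(l) {
      tr <- cpp_el_integrate(l[1], l[2], par, prc$z_coef, prc$f_coef, tt,
                             rtol, 1e8)
      if (ncol(tr) < 7L) return(NULL)
      list(r = c(tr[n, 2], tr[n, 5]), traj = tr)
    }
    dr <- dense_resid(lam0)
    if (is.null(dr)) stop("shooting solution lost during dense output")
    for (it in 1:25) {
      if (max(abs(dr$r)) < 1e-9) break
      J <- matrix(0, 2, 2)
      ok <- TRUE
      for (j in 1:2) {
        h <- 1e-10 * (1 + abs(lam0[j]))
        lp <- lam0; lp[j] <- lam0[j] + h
        dp <- dense_resid(lp)
        if (is.null(dp)) { ok <- FALSE; break }
        J[, j] <- (dp$r - dr$r) / h
      }
      if (!ok) break
      dl <- tryCatch(solve(J, -dr$r), error = function(e) NULL)
      if (is.null(dl)) break
      dn <- dense_resid(lam0 + dl)
      if (is.null(dn) || max(abs(dn$r)) >= max(abs(dr$r))) break
      lam0 <- lam0 + dl
      dr <- dn
    }
    traj <- dr$traj
    up <- traj[, 2]; ue <- traj[, 5]; theta <- traj[, 4]
    resid <- dr$r
    el_rms <- 0
  }
  if (max(abs(ue)) > u_cap) {
    stop("designed input exceeds u_cap = ", u_cap,
         ": phase reduction not trustworthy at this amplitude")
  }

  terms <- cost_terms_tbl(tt, up, ue, theta, weights, prc)
  wq <- rep(dt_out, n); wq[c(1, n)] <- dt_out / 2
  zp_uniform <- fourier_eval(prc$z_coef, prc$omega * tt, 1L)
  q <- cpp_phase_quadrature(ue, dt_out, 0, prc$omega, prc$z_coef, prc$f_coef,
                            prc$T)
  qu <- cpp_phase_quadrature(numeric(n), dt_out, 0, prc$omega, prc$z_coef,
                             prc$f_coef, prc$T)
  lam_drv <- q$int_zpu / prc$T
  lam_uni <- sum(wq * zp_uniform * ue) / prc$T
  lamc_drv <- (q$int_zpu - sigma_eval * q$int_fpz) / prc$T
  lamc_uni <- lam_uni - sigma_eval * qu$int_fpz / prc$T

  diagnostics <- tibble::tibble(
    Lambda_T = lam_drv, Lambda_T_uniform = lam_uni,
    Lambda_c_T = lamc_drv, Lambda_c_T_uniform = lamc_uni,
    cost = sum(terms),
    cost_energy = terms[["energy"]], cost_slew = terms[["slew"]],
    cost_lyap = terms[["lyap"]], cost_faradaic = terms[["faradaic"]],
    lambda1_0 = lam0[1], lambda2_0 = lam0[2],
    resid_X1 = resid[1], resid_ue = resid[2],
    el_resid_rms = el_rms, method = method)
  structure(list(waveform = tibble::tibble(t = tt, u_p = up, u_e = ue,
                                           theta = theta),
                 diagnostics = diagnostics,
                 weights = weights, circuit = circuit, coupled = coupled,
                 sigma_eval = sigma_eval, prc_period = prc$T, dt = dt_out),
            class = "dbs_stimulus")
}

# direct transcription with the compiled adjoint gradient; returns the
# optimal probe profile, its circuit/phase response, the least-squares
# estimate of the initial multipliers and the stationarity residual of that
# fit (rms over the interior of the window)
design_transcription <- function(prc, weights, circuit, par, tt, maxit, mu) {
  dt <- tt[2] - tt[1]
  n <- length(tt)
  obj <- function(free) {
    cpp_direct_cost_grad(c(0, 0, free, 0), par, prc$z_coef, prc$f_coef, dt, mu)$J
  }
  grd <- function(free) {
    cpp_direct_cost_grad(c(0, 0, free, 0), par, prc$z_coef, prc$f_coef, dt,
                         mu)$grad[3:(n - 1)]
  }
  # canonical start: circuit-consistent probe drive whose field input is the
  # tapered pointwise optimum (beta/2) Z'(omega t)
  a <- circuit$kct + circuit$ks
  taper <- pmin(1, tt / 0.3, (tt[n] - tt) / 0.3)
  ue0 <- (weights$beta / 2) * fourier_eval(prc$z_coef, prc$omega * tt, 1L) * taper
  up0 <- numeric(n)
  for (i in 1:(n - 1)) {
    up0[i + 1] <- (up0[i] + dt * ((ue0[i + 1] - ue0[i]) / dt + a * ue0[i + 1])) /
      (1 + dt * circuit$kct)
  }
  opt <- stats::optim(up0[3:(n - 1)], obj, grd, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e3))
  up <- c(0, 0, opt$par, 0)
  ue <- simulate_circuit(up, circuit, dt = dt)$u_e
  q <- cpp_phase_quadrature(ue, dt, 0, prc$omega, prc$z_coef, prc$f_coef, tt[n])
  theta <- q$theta
  ex <- extract_multipliers(prc, weights, circuit, par, tt, up, ue, theta)
  list(up = up, ue = ue, theta = theta, lam0 = ex$lam0, el_rms = ex$rms,
       value = opt$value, convergence = opt$convergence)
}

# least-squares estimate of the initial Lagrange multipliers along a fixed
# trajectory: the multiplier subsystem is linear given (u_e, theta), so the
# stationarity residual of the probe channel is affine in lambda(t1);
# integrating backwards keeps the fit well conditioned.
extract_multipliers <- function(prc, weights, circuit, par, tt, up, ue, theta) {
  dt <- tt[2] - tt[1]
  n <- length(tt)
  kct <- circuit$kct; ks <- circuit$ks
  beta <- weights$beta; gam <- weights$gamma; alpha <- weights$alpha
  sig <- par[4]
  Z <- fourier_eval(prc$z_coef, theta, 0L)
  zp <- fourier_eval(prc$z_coef, theta, 1L)
  zpp <- fourier_eval(prc$z_coef, theta, 2L)
  fp <- fourier_eval(prc$f_coef, theta, 1L)
  fpp <- fourier_eval(prc$f_coef, theta, 2L)
  upp <- numeric(n)
  upp[2:(n - 1)] <- (up[3:n] - 2 * up[2:(n - 1)] + up[1:(n - 2)]) / dt^2
  upp[1] <- upp[2]; upp[n] <- upp[n - 1]
  lam_back <- function(lT) {
    l1 <- numeric(n); l2 <- numeric(n); l1[n] <- lT[1]; l2[n] <- lT[2]
    f <- function(j, l1v, l2v) {
      c(2 * ue[j] - beta * zp[j] - 2 * gam * (up[j] - ue[j]) - l2v * Z[j] +
          l1v * (kct + ks),
        -(beta * zpp[j] + l2v * zp[j]) * ue[j] +
          beta * sig * (fpp[j] * Z[j] + fp[j] * zp[j]))
    }
    for (i in n:2) {
      k1 <- f(i, l1[i], l2[i])
      k2 <- f(i - 1, l1[i] - dt * k1[1], l2[i] - dt * k1[2])
      l1[i - 1] <- l1[i] - dt * (k1[1] + k2[1]) / 2
      l2[i - 1] <- l2[i] - dt * (k1[2] + k2[2]) / 2
    }
    cbind(l1, l2)
  }
  b0 <- lam_back(c(0, 0))
  h1 <- lam_back(c(1, 0)) - b0
  h2 <- lam_back(c(0, 1)) - b0
  mid <- 3:(n - 2)
  r0 <- (2 * alpha * upp - 2 * ue + beta * zp + b0[, 2] * Z - b0[, 1] * ks)[mid]
  M <- cbind((h1[, 2] * Z - h1[, 1] * ks)[mid], (h2[, 2] * Z - h2[, 1] * ks)[mid])
  lT <- as.numeric(solve(crossprod(M), -crossprod(M, r0)))
  path <- b0 + lT[1] * h1 + lT[2] * h2
  list(lam0 = path[1, ], rms = sqrt(mean((r0 + M %*% lT)^2)))
}

# continuation in beta from the trivial zero-input root, secant predictor,
# damped Newton corrector on the two initial multipliers
el_continuation <- function(prc, weights, circuit, coupled, rtol,
                            newton_tol = 1e-7) {
  par <- el_par_vec(weights, prc, circuit, coupled)
  t1 <- weights$t1
  res <- function(lam, b) {
    par[2] <- b
    shoot_resid(lam[1], lam[2], par, prc$z_coef, prc$f_coef, t1, rtol)
  }
  newton <- function(lam, b) {
    for (it in 1:12) {
      R <- res(lam, b)
      if (is.null(R)) return(NULL)
      nr <- max(abs(R))
      if (nr < newton_tol) return(list(lam = lam, it = it))
      J <- matrix(0, 2, 2)
      for (j in 1:2) {
        h <- 1e-9 * (1 + abs(lam[j])); lp <- lam; lp[j] <- lam[j] + h
        Rp <- res(lp, b)
        if (is.null(Rp)) return(NULL)
        J[, j] <- (Rp - R) / h
      }
      dl <- tryCatch(solve(J, -R), error = function(e) NULL)
      if (is.null(dl)) return(NULL)
      st <- 1; ok <- FALSE
      while (st > 1e-5) {
        lt <- lam + st * dl
        Rt <- res(lt, b)
        if (!is.null(Rt) && max(abs(Rt)) < nr) { lam <- lt; ok <- TRUE; break }
        st <- st / 2
      }
      if (!ok) return(NULL)
    }
    R <- res(lam, b)
    if (!is.null(R) && max(abs(R)) < 1e-4) list(lam = lam, it = 12) else NULL
  }
  beta_target <- weights$beta
  hist_b <- 0; hist_l <- list(c(0, 0))
  b <- 0; db <- 0.5; lam <- c(0, 0)
  while (b < beta_target) {
    bn <- min(b + db, beta_target)
    nh <- length(hist_b)
    lp <- if (nh >= 2) {
      hist_l[[nh]] + (bn - hist_b[nh]) / (hist_b[nh] - hist_b[nh - 1]) *
        (hist_l[[nh]] - hist_l[[nh - 1]])
    } else lam
    sol <- newton(lp, bn)
    if (is.null(sol)) {
      db <- db / 2
      if (db < 1e-4) stop("beta continuation stalled at beta = ", b)
      next
    }
    lam <- sol$lam; b <- bn
    hist_b <- c(hist_b, b); hist_l <- c(hist_l, list(lam))
    db <- if (sol$it <= 3) min(db * 1.6, 5) else if (sol$it >= 8) db / 2 else db
  }
  # final polish at the target weight
  for (k in 1:3) {
    sol <- newton(lam, beta_target)
    if (is.null(sol)) break
    lam <- sol$lam
    R <- res(lam, beta_target)
    if (!is.null(R) && max(abs(R)) < 1e-8) break
  }
  lam
}

#' Evaluate the design cost of a stimulus waveform
#'
#' Recomputes the four cost terms for an arbitrary probe/field waveform
#' pair. The pair must be circuit-consistent: `u_e` is re-simulated from
#' `u_p` and compared against the supplied values. The phase trajectory is
#' obtained by integrating the driven phase equation (not the
#' `theta = omega t` shortcut).
#'
#' @param waveform data frame with uniform `t`, `u_p` and `u_e` columns.
#' @param prc a [compute_prc()] object.
#' @param weights a [control_weights()] object.
#' @param circuit a [circuit_params()] object.
#' @param consistency_tol relative max-norm tolerance for the `u_p`/`u_e`
#'   consistency check.
#' @return named numeric: the four terms and their sum `total`.
#' @export
cost_functional <- function(waveform, prc, weights, circuit = circuit_params(),
                            consistency_tol = 1e-3) {
  t <- waveform$t
  dt <- t[2] - t[1]
  resim <- simulate_circuit(waveform[c("t", "u_p")], circuit, ue0 = waveform$u_e[1])
  scale <- max(abs(waveform$u_e), 1e-12)
  if (max(abs(resim$u_e - waveform$u_e)) > consistency_tol * scale + 1e-9) {
    stop("inconsistent waveform: u_e does not match the circuit response to u_p")
  }
  ph <- cpp_phase_quadrature(waveform$u_e, dt, 0, prc$omega, prc$z_coef,
                             prc$f_coef, t[length(t)] - t[1])
  terms <- cost_terms_tbl(t, waveform$u_p, waveform$u_e, ph$theta, weights, prc)
  c(terms, total = sum(terms))
}

#' @export
print.dbs_stimulus <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("Designed stimulus (%s, %s): t1 = %g ms, gamma = %g\n",
              d$method, if (x$coupled) "coupled" else "uncoupled",
              x$weights$t1, x$weights$gamma))
  cat(sprintf("  Lambda(T) = %.4f /ms (uniform-rotation evaluation %.4f)\n",
              d$Lambda_T, d$Lambda_T_uniform))
  cat(sprintf("  Lambda_c(T) at sigma = %g: %.4f (uniform %.4f); cost = %.4f\n",
              x$sigma_eval, d$Lambda_c_T, d$Lambda_c_T_uniform, d$cost))
  cat(sprintf("  terminal residuals (%.2e, %.2e), multipliers (%.5g, %.5g)\n",
              d$resid_X1, d$resid_ue, d$lambda1_0, d$lambda2_0))
  invisible(x)
}
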