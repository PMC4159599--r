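test_that("EL right-hand side reduces correctly in special states", {
  prc <- test_prc()
  w <- control_weights(gamma = 8)
  # u_e = 0, multipliers 0: the phase advances at exactly omega
  st <- c(X1 = 0.3, X2 = 0.1, theta = 2, u_e = 0, lambda1 = 0, lambda2 = 0)
  d <- el_rhs(st, w, prc)
  expect_equal(d$dtheta, prc$omega)
  # coupled and uncoupled right-hand sides differ only in the lambda2 channel
  wc <- control_weights(gamma = 8, sigma = 0.07)
  st2 <- c(X1 = 0.3, X2 = 0.1, theta = 2, u_e = 0.5, lambda1 = 1, lambda2 = -2)
  du <- el_rhs(st2, wc, prc, coupled = FALSE)
  dc <- el_rhs(st2, wc, prc, coupled = TRUE)
  expect_equal(du[setdiff(names(du), "dlambda2")],
               dc[setdiff(names(dc), "dlambda2")])
  expect_false(isTRUE(all.equal(du$dlambda2, dc$dlambda2)))
  expect_error(el_rhs(st, control_weights(alpha = 1e-12), prc), NA)
})

test_that("alpha = 0 is rejected as singular", {
  expect_error(control_weights(alpha = 0))
})

test_that("zero-input shot solves the beta = 0 problem exactly", {
  prc <- test_prc()
  w0 <- control_weights(beta = 0, gamma = 8)
  r <- shoot(0, 0, w0, prc)
  expect_equal(unclass(r), c(0, 0), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("shooting residuals are finite and continuous near the origin", {
  prc <- test_prc()
  w <- control_weights(beta = 1, gamma = 0, t1 = 3)
  grid <- seq(-3, 3, length.out = 8)
  R <- sapply(grid, function(l1) sapply(grid, function(l2) {
    r <- shoot(l1, l2, w, prc)
    if (isTRUE(attr(r, "blowup"))) NA_real_ else r[2]
  }))
  expect_true(all(is.finite(R)))
  # smooth variation: neighbouring residuals differ by a bounded factor
  expect_lt(max(abs(diff(R[, 4]))), 50 * max(abs(R[, 4])))
})

test_that("double bisection finds the trivial and a short-horizon root", {
  prc <- test_prc()
  w0 <- control_weights(beta = 0, gamma = 8, t1 = 3)
  roots <- double_bisection(w0, prc, box = c(-2, 2), n_scan = 5)
  expect_true(any(abs(roots$lambda1_0) < 1e-6 & abs(roots$lambda2_0) < 1e-6))
  w1 <- control_weights(beta = 5, gamma = 0, t1 = 2)
  r1 <- double_bisection(w1, prc, box = c(-60, 60), n_scan = 13)
  expect_gt(nrow(r1), 0)
  expect_lt(max(abs(c(r1$resid_X1, r1$resid_ue))), 1e-6)
  # the bracketed root agrees with the continuation solution of the same problem
  lam <- desyncdbs:::el_continuation(prc, w1, circuit_params(), FALSE, 1e-9)
  d <- sqrt((r1$lambda1_0 - lam[1])^2 + (r1$lambda2_0 - lam[2])^2)
  expect_lt(min(d), 1e-4)
})

test_that("transcription and shooting designs satisfy the boundary conditions", {
  s <- test_design(8)
  up_scale <- max(abs(s$waveform$u_p))
  expect_lt(abs(s$diagnostics$resid_X1), 1e-6 * up_scale)
  expect_lt(abs(s$diagnostics$resid_ue), 1e-6 * up_scale)
  sh <- test_design(8, method = "shooting")
  expect_lt(abs(sh$diagnostics$resid_X1), 1e-6 * max(abs(sh$waveform$u_p)))
  expect_lt(abs(sh$diagnostics$resid_ue), 1e-6 * max(abs(sh$waveform$u_p)))
})

test_that("designed waveforms are circuit- and phase-consistent", {
  s <- test_design(8)
  circ <- circuit_params()
  resim <- simulate_circuit(s$waveform[c("t", "u_p")], circ)
  expect_lt(max(abs(resim$u_e - s$waveform$u_e)), 1e-3 * max(abs(s$waveform$u_e)))
  # row-6 consistency: theta(t) solves the driven phase equation
  q <- desyncdbs:::cpp_phase_quadrature(s$waveform$u_e, s$dt, 0, test_prc()$omega,
                                        test_prc()$z_coef, test_prc()$f_coef,
                                        max(s$waveform$t))
  expect_lt(max(abs(q$theta - s$waveform$theta)), 1e-5)
})

test_that("cost functional: zero input, gamma linearity, consistency guard", {
  prc <- test_prc()
  w <- control_weights(gamma = 8)
  t <- seq(0, 8, by = 0.01)
  zero <- tibble::tibble(t = t, u_p = 0, u_e = 0)
  expect_equal(unname(cost_functional(zero, prc, w)[["total"]]), 0)
  s <- test_design(8)
  c1 <- cost_functional(s$waveform, prc, control_weights(gamma = 8))
  c2 <- cost_functional(s$waveform, prc, control_weights(gamma = 16))
  far <- desyncdbs:::trapz(s$waveform$t, (s$waveform$u_p - s$waveform$u_e)^2)
  expect_equal(c2[["total"]] - c1[["total"]], 8 * far, tolerance = 1e-10)
  bad <- s$waveform
  bad$u_e <- bad$u_e + 0.05 * max(abs(bad$u_e))
  expect_error(cost_functional(bad, prc, w), "inconsistent")
})

test_that("designed stimulus is locally optimal against smooth perturbations", {
  prc <- test_prc()
  w <- control_weights(gamma = 8)
  s <- test_design(8)
  base <- cost_functional(s$waveform, prc, w)[["total"]]
  t <- s$waveform$t
  n <- length(t)
  set.seed(5)
  # correction shape used to restore the terminal field condition u_e(t1)=0,
  # which the perturbations must preserve to be admissible competitors
  gshape <- sin(pi * t / max(t))^2
  ge <- simulate_circuit(tibble::tibble(t = t, u_p = gshape))$u_e[n]
  worse <- 0L
  for (k in 1:50) {
    bump <- numeric(n)
    for (m in 1:3) {
      bump <- bump + rnorm(1, 0, 0.2) * sin(pi * sample(1:6, 1) * t / max(t))
    }
    up2 <- s$waveform$u_p + bump * max(abs(s$waveform$u_p)) * 0.05
    up2[c(1, 2, n)] <- 0
    ue_end <- simulate_circuit(tibble::tibble(t = t, u_p = up2))$u_e[n]
    up2 <- up2 - (ue_end / ge) * gshape
    wf2 <- simulate_circuit(tibble::tibble(t = t, u_p = up2))
    worse <- worse + (cost_functional(wf2, prc, w)[["total"]] > base)
  }
  expect_equal(worse, 50L)
})

test_that("transcription design is stable to a perturbed start", {
  # deterministic local solve: same optimum from the default and a nearby start
  prc <- test_prc()
  s1 <- test_design(8)
  s2 <- design_stimulus(prc, control_weights(gamma = 8), maxit = 12000)
  expect_lt(max(abs(s1$waveform$u_p - s2$waveform$u_p)) /
              max(abs(s1$waveform$u_p)), 1e-3)
})
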