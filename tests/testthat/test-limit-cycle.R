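test_that("limit cycle is phase-parameterized by the flow", {
  lc <- test_lc()
  th0 <- 2.0; dtv <- 1.7
  y0 <- orbit_state(lc, th0)
  traj <- simulate_neuron(init = y0[1, ], t_span = c(0, dtv), dt_out = dtv / 100,
                          rtol = 1e-10)
  yend <- as.numeric(traj[nrow(traj), c("V", "h", "r")])
  ypred <- as.numeric(orbit_state(lc, th0 + lc$omega * dtv))
  expect_lt(abs(yend[1] - ypred[1]), 0.02)
  expect_lt(max(abs(yend[2:3] - ypred[2:3])), 1e-3)
})

test_that("PRC normalization identity holds on the grid", {
  prc <- test_prc()
  expect_lt(max(abs(prc$norm_resid)), 1e-6)
})

test_that("PRC has a single dominant positive lobe peaking near theta = 4.5", {
  prc <- test_prc()
  peak <- prc$curves$theta[which.max(prc$curves$Z)]
  expect_gt(peak, 4)
  expect_lt(peak, 5)
  expect_gt(max(prc$curves$Z), 0)
  expect_lt(abs(min(prc$curves$Z)), 0.2 * max(prc$curves$Z))
  # Z'(2 pi) is well below the extrema of Z' (qualitatively small)
  expect_lt(abs(prc$curves$dZ[1]), 0.5 * max(abs(prc$curves$dZ)))
})

test_that("on-orbit voltage map couples positively to the PRC", {
  prc <- test_prc()
  dtheta <- 2 * pi / nrow(prc$curves)
  expect_gt(sum(prc$curves$df * prc$curves$Z) * dtheta, 0)
})

test_that("PRC agrees between grid resolutions", {
  prc <- test_prc()
  lc256 <- find_limit_cycle(grid_size = 256L)
  prc256 <- compute_prc(lc256)
  th <- prc$curves$theta
  z512 <- prc$curves$Z
  z256 <- prc_eval(prc256, th, "Z")
  expect_lt(max(abs(z512 - z256)) / max(abs(z512)), 0.005)
  expect_lt(abs(lc256$T - prc$T), 1e-3)
})

test_that("adjoint PRC matches the direct perturbation method", {
  prc <- test_prc()
  dir <- compute_prc_direct(test_lc(), phases = 2 * pi * (0:31) / 32)
  za <- prc_eval(prc, dir$theta, "Z")
  expect_lt(max(abs(dir$Z - za)) / max(abs(prc$curves$Z)), 0.02)
})
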