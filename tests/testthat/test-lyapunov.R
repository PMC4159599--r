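test_that("zero input gives a vanishing exponent; sigma = 0 collapses variants", {
  prc <- test_prc()
  expect_equal(exponent_uncoupled(0, dt = 1, prc = prc), 0)
  s <- test_design(8)
  u <- s$waveform$u_e
  lam <- exponent_uncoupled(u, dt = s$dt, prc = prc, theta0 = 0.7)
  expect_equal(exponent_coupled_approx(u, dt = s$dt, prc = prc, sigma = 0,
                                       theta0 = 0.7), lam, tolerance = 1e-12)
  expect_equal(exponent_coupled_exact(0.7, u, dt = s$dt, sigma = 0, prc = prc),
               lam, tolerance = 1e-6)
  expect_error(exponent_coupled_exact(numeric(0), u, dt = s$dt, prc = prc),
               "empty")
})

test_that("identical-phase ensemble reproduces the coupling-only exponent", {
  prc <- test_prc()
  n <- 200L
  u <- numeric(n)
  lam_ex <- exponent_coupled_exact(rep(1.2, 12), u, dt = prc$T / (n - 1),
                                   sigma = 0.07, prc = prc)
  lam_ap <- exponent_coupled_approx(u, dt = prc$T / (n - 1), prc = prc,
                                    sigma = 0.07, theta0 = 1.2)
  expect_equal(lam_ex, lam_ap, tolerance = 1e-6)
})

test_that("symmetric ensembles agree with the two-term approximation", {
  prc <- test_prc()
  s <- test_design(8)
  ens <- 1.0 + seq(-0.25, 0.25, length.out = 15)
  lam_ex <- exponent_coupled_exact(c(1.0, ens), s$waveform$u_e, dt = s$dt,
                                   sigma = 0.07, prc = prc)
  lam_ap <- exponent_coupled_approx(s$waveform$u_e, dt = s$dt, prc = prc,
                                    sigma = 0.07, theta0 = 1.0)
  expect_lt(abs(lam_ex - lam_ap) / abs(lam_ap), 0.05)
})

test_that("coupling reduces the exponent of designed stimuli", {
  s <- test_design(8)
  expect_lt(s$diagnostics$Lambda_c_T, s$diagnostics$Lambda_T)
})

test_that("the exponent matches the variational divergence of the phase model", {
  prc <- test_prc()
  set.seed(9)
  for (k in 1:10) {
    n <- 1605L
    dt <- 0.005
    tt <- (0:(n - 1)) * dt
    u <- numeric(n)
    for (m in 1:3) u <- u + rnorm(1, 0, 0.8) * sin(2 * pi * sample(1:3, 1) * tt / max(tt) + runif(1, 0, 6))
    u <- c(u, numeric(200))  # cover the full horizon tau = T explicitly
    th0 <- runif(1, 0, 2 * pi)
    lam <- exponent_uncoupled(u, dt = dt, prc = prc, theta0 = th0, tau = prc$T)
    eps <- 1e-6
    qa <- desyncdbs:::cpp_phase_quadrature(u, dt, th0, prc$omega, prc$z_coef,
                                           prc$f_coef, prc$T)
    qb <- desyncdbs:::cpp_phase_quadrature(u, dt, th0 + eps, prc$omega,
                                           prc$z_coef, prc$f_coef, prc$T)
    dth <- abs(qb$theta[length(qb$theta)] - qa$theta[length(qa$theta)])
    lam_var <- log(dth / eps) / prc$T
    expect_lt(abs(lam_var - lam) / max(abs(lam), 1e-3), 0.01)
  }
})

test_that("uncoupled identical neurons preserve phase differences", {
  lc <- test_lc()
  cfg <- network_config(N = 2, sigma = 0, noise_2D = 0, duration = 5 * lc$T,
                        seed = 3, jitter_sd = 0.05)
  tr <- simulate_network(cfg, lc, NULL, mode = "none")
  f <- numerical_exponent(tr)
  expect_lt(abs(f$lambda), 1e-4)
  expect_error(numerical_exponent(
    simulate_network(network_config(N = 2, noise_2D = 0.7, duration = 10,
                                    seed = 1), lc, NULL, mode = "none")),
    "noise-free")
})
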