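test_that("spherical probe potential satisfies its boundary conditions", {
  expect_equal(probe_potential(0.5, -1, 0.5), -1)
  expect_equal(probe_potential(0.5, -1, 1.0), -0.5)
  expect_lte(abs(probe_potential(0.5, -1, 500)), 1e-3)
  expect_error(probe_potential(0.5, -1, 0.3), "inside")
  # radial finite-difference solution of the Laplace equation as oracle
  r <- seq(0.5, 60, by = 0.005)
  n <- length(r)
  A <- matrix(0, n, n)
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- 1 / 0.005^2 - 1 / (r[i] * 0.005)
    A[i, i] <- -2 / 0.005^2
    A[i, i + 1] <- 1 / 0.005^2 + 1 / (r[i] * 0.005)
  }
  A[1, 1] <- 1; A[n, n] <- 1
  b <- numeric(n); b[1] <- -1; b[n] <- -0.5 / 60  # far field ~ a V_e / r
  V <- solve(A, b)
  i1 <- which.min(abs(r - 1))
  expect_lt(abs(V[i1] - probe_potential(0.5, -1, 1)), 1e-3)
})

test_that("effective strength is the perpendicular second derivative", {
  expect_equal(effective_strength(0.5, 1), 0.5)
  d1 <- 0.9; d2 <- 1.7
  expect_equal(effective_strength(0.5, d1) / effective_strength(0.5, d2),
               (d2 / d1)^3)
  # central finite differences of the potential along the perpendicular
  h <- 1e-4
  fd <- (probe_potential(0.5, -1, sqrt(1 + h^2)) * 2 -
           2 * probe_potential(0.5, -1, 1)) / h^2
  expect_lt(abs(fd - effective_strength(0.5, 1)), 1e-4)
  expect_error(effective_strength(0.5, 0.4), "outside")
})

test_that("circuit simulation matches the closed-form responses", {
  circ <- circuit_params()
  # zero input stays zero
  z <- simulate_circuit(rep(0, 100), dt = 0.01)
  expect_equal(z$u_e, rep(0, 100))
  # a unit step (edge inside the window) jumps through the double layer and
  # relaxes to the resistive divider value with the analytic time constant
  t <- seq(0, 600, by = 0.01)
  st <- simulate_circuit(tibble::tibble(t = t, u_p = c(0, rep(1, length(t) - 1))), circ)
  uinf <- circ$R_s / (circ$R_s + circ$R_ct)
  expect_lt(abs(st$u_e[length(t)] - uinf) / uinf, 1e-3)
  tau <- 1 / (circ$kct + circ$ks)
  pred <- uinf + (1 - uinf) * exp(-(t - 0.005) / tau)
  late <- t >= 0.02
  expect_lt(max(abs(st$u_e[late] - pred[late])), 1e-3)
  # linearity
  up <- sin(seq(0, 20, by = 0.01))
  a1 <- simulate_circuit(3.7 * up, dt = 0.01)$u_e
  a2 <- 3.7 * simulate_circuit(up, dt = 0.01)$u_e
  expect_lt(max(abs(a1 - a2)), 1e-10)
  expect_warning(simulate_circuit(rep(1, 5), dt = 2), "coarser")
})

test_that("transfer gain matches the time-domain frequency response", {
  circ <- circuit_params()
  expect_equal(Re(transfer_gain(0)), circ$R_ct / (circ$R_ct + circ$R_s))
  f <- c(0.01, 0.1, 1, 10)
  expect_true(all(diff(Mod(transfer_gain(f))) < 0))
  for (om in c(0.05, 1)) {
    t <- seq(0, 900, by = 0.005)
    sim <- simulate_circuit(tibble::tibble(t = t, u_p = sin(om * t)), circ)
    drop <- sim$u_p - sim$u_e
    tail_idx <- t > 500
    # quadrature regression is robust to partial cycles in the window
    fit <- lm(drop[tail_idx] ~ sin(om * t[tail_idx]) + cos(om * t[tail_idx]))
    amp <- sqrt(sum(coef(fit)[2:3]^2))
    gain <- Mod(transfer_gain(om, circ))
    expect_lt(abs(amp - gain) / gain, 0.01)
    phase <- atan2(-coef(fit)[3], coef(fit)[2])
    expect_lt(abs(phase - (-Arg(transfer_gain(om, circ)))), 0.02)
  }
})

test_that("effective-input conversion is exact and distance-scaled", {
  geom <- field_geometry(distance = 1, R_i = 2)
  V <- c(0, -0.5, 1.2)
  expect_equal(to_effective_input(0, geom), 0)
  expect_equal(from_effective_input(to_effective_input(V, geom), geom), V)
  g2 <- field_geometry(distance = 2, R_i = 2)
  expect_equal(to_effective_input(-1, geom) / to_effective_input(-1, g2), 8)
  expect_error(to_effective_input(1, field_geometry(R_i = 0)), "R_i")
})
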