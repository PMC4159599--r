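test_that("membrane current is the signed sum with additive baseline", {
  p0 <- neuron_params(I_SM = 0)
  p5 <- neuron_params(I_SM = 5)
  st <- data.frame(V = c(-65, -40, 10), h = c(0.3, 0.5, 0.1), r = c(0.1, 0.05, 0.2))
  expect_equal(membrane_current(st, p5) - membrane_current(st, p0), rep(5, 3))
  expect_error(membrane_current(c(NaN, 0.5, 0.5)), "non-finite")
})

test_that("vector field has additive applied current and relaxational gating", {
  st <- c(V = -55, h = 0.4, r = 0.15)
  va <- vector_field(st, i_applied = 1.3)
  vb <- vector_field(st, i_applied = 0)
  expect_equal(va$dV - vb$dV, 1.3 / neuron_params()$C)
  expect_equal(va$dh, vb$dh)
  # h above its equilibrium relaxes downward
  p <- neuron_params()
  hinf <- 1 / (1 + exp((-55 + 41) / 4))
  v2 <- vector_field(c(V = -55, h = hinf + 0.05, r = 0.15))
  expect_lt(v2$dh, 0)
})

test_that("free-running simulation spikes periodically; suppression works", {
  # the slow T-current gate keeps the period drifting for a few hundred ms,
  # so judge regularity after that transient
  traj <- simulate_neuron(t_span = c(0, 400))
  isi <- diff(spike_times(traj))
  expect_gt(length(isi), 8)
  expect_lt(sd(tail(isi, 5)), 0.02)
  quiet <- simulate_neuron(i_applied = -20, t_span = c(0, 60))
  expect_length(spike_times(quiet), 0)
})

test_that("spike times are solver-tolerance stable", {
  t1 <- simulate_neuron(t_span = c(0, 60), rtol = 1e-8)
  t2 <- simulate_neuron(t_span = c(0, 60), rtol = 1e-10)
  n <- min(length(spike_times(t1)), length(spike_times(t2)))
  expect_lt(max(abs(spike_times(t1)[1:n] - spike_times(t2)[1:n])), 1e-3)
})

test_that("gating variables stay inside the unit box from random states", {
  set.seed(11)
  N <- 20L
  init <- cbind(runif(N, -90, 0), runif(N), runif(N))
  out <- desyncdbs:::cpp_network_sim(init, desyncdbs:::par_vec(neuron_params()),
                                     0.01, 5000L, 0, 0, rep(1, N), c(0, 0), 1,
                                     0L, 1e-5, 1 / 14.5, -45, -40, 12.6, 100L)
  expect_true(all(out$h >= 0 & out$h <= 1))
  expect_true(all(out$r >= 0 & out$r <= 1))
})
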