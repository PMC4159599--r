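test_that("pulsatile trains are charge balanced with the right pulse count", {
  pw <- pulsatile_waveform(amplitude = 98, phase_width = 0.2, period = 4,
                           duration = 300, dt = 0.01)
  per_cycle <- desyncdbs:::trapz(pw$t, pw$u_p)
  expect_lt(abs(per_cycle), 1e-9)
  # 75 anodic phases of 0.2 ms at amplitude 98
  expect_equal(sum(pw$u_p > 0) * 0.01, 75 * 0.2, tolerance = 0.01)
  expect_equal(pulsatile_waveform(amplitude = 0)$u_p,
               rep(0, nrow(pulsatile_waveform(amplitude = 0))))
})

test_that("energy and Faradaic metrics behave and are grid stable", {
  circ <- circuit_params()
  z <- tibble::tibble(t = 0:10, u_p = 0, u_e = 0)
  expect_equal(energy_metric(z), 0)
  expect_equal(faradaic_metric(z), 0)
  s1 <- simulate_circuit(pulsatile_waveform(duration = 100, dt = 0.01), circ)
  s2 <- simulate_circuit(pulsatile_waveform(duration = 100, dt = 0.005), circ)
  expect_lt(abs(energy_metric(s1) - energy_metric(s2)) / energy_metric(s2), 0.005)
  expect_lt(abs(faradaic_metric(s1) - faradaic_metric(s2)) / faradaic_metric(s2),
            0.005)
  s3 <- s1; s3$u_e <- 3 * s3$u_e
  expect_equal(energy_metric(s3), 9 * energy_metric(s1))
  expect_error(faradaic_metric(list(t = 1:3, u_p = 1:3, u_e = 1:2)), "mismatch")
})

test_that("distance sampling gives cubic-law scale factors", {
  h <- sample_distances("homogeneous", N = 7)
  expect_equal(h$scale, rep(1, 7))
  d <- sample_distances(c(1, 2), N = 2)
  expect_equal(d$scale, c(1, 0.125))
  u <- sample_distances(list(law = "uniform", min = 0.75, max = 1.5), N = 50,
                        seed = 4)
  expect_true(all(u$d > 0.5))
  expect_error(sample_distances(list(law = "cauchy"), N = 5), "unsupported")
})

test_that("controller triggers once per crossing and re-arms above -40", {
  # synthetic mean-voltage: rise through -45 (no trigger on the way up),
  # crest at -43 (single trigger at the first falling sample), then fall
  vbar <- c(seq(-60, -43, length.out = 50), seq(-43.1, -60, length.out = 50))
  out <- controller_step(vbar, dt = 0.1, stim_length = 2)
  expect_length(out$triggers, 1)
  expect_gt(out$triggers, 49 * 0.1 - 1e-9)
  # inactive controller stays inactive while the crest stays below -40
  vbar2 <- rep(c(seq(-60, -41, length.out = 30), seq(-41, -60, length.out = 30)), 6)
  out2 <- controller_step(vbar2, dt = 0.5, stim_length = 2, lockout = 10)
  expect_false(out2$active[length(vbar2)])
  expect_lt(length(out2$triggers), 3)
})

test_that("deterministic network integration matches the adaptive solver", {
  lc <- test_lc()
  init <- orbit_state(lc, c(1.3, 4.2))
  cfg <- network_config(N = 2, sigma = 0, noise_2D = 0, duration = 10 * lc$T,
                        dt = 0.01, seed = 1)
  tr <- simulate_network(cfg, lc, NULL, mode = "none", init = init)
  ras <- spike_raster(tr)
  s1 <- ras$spike_time[ras$neuron == 1]
  ref <- simulate_neuron(init = init[1, ], t_span = c(0, 10 * lc$T),
                         rtol = 1e-10)
  s2 <- spike_times(ref)
  n <- min(length(s1), length(s2))
  expect_gt(n, 8)
  expect_lt(max(abs(s1[1:n] - s2[1:n])), 1e-2)
})

test_that("voltage spread scales linearly with the noise variance 2D", {
  lc <- test_lc()
  init <- orbit_state(lc, rep(2.0, 60))
  vspread <- sapply(c(0.35, 0.7, 1.4), function(D2) {
    cfg <- network_config(N = 60, sigma = 0, noise_2D = D2, duration = 1,
                          dt = 0.01, seed = 99)
    tr <- simulate_network(cfg, lc, NULL, mode = "none", init = init)
    st <- attr(tr, "states")
    var(st$V[nrow(st$V), ])
  })
  expect_gt(vspread[2] / vspread[1], 1.6)
  expect_lt(vspread[2] / vspread[1], 2.4)
  expect_gt(vspread[3] / vspread[2], 1.6)
  expect_lt(vspread[3] / vspread[2], 2.4)
})

test_that("event control desynchronizes and logs stimuli; circuit persists", {
  lc <- test_lc()
  s <- test_design(8)
  cfg <- network_config(N = 30, sigma = 0.07, noise_2D = 0.35, duration = 120,
                        seed = 21)
  tr <- simulate_network(cfg, lc, s$waveform, mode = "event")
  expect_gt(length(controller_triggers(tr)), 2)
  st <- attr(tr, "states")
  idx <- match(round(st$t, 6), round(tr$t, 6))
  expect_equal(rowMeans(st$V), tr$vbar[idx], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_gt(energy_metric(tr), 0)
})
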