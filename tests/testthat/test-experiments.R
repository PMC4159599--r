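test_that("unknown experiments list the valid names", {
  expect_error(run_experiment("fig99"), "fig4_gamma_sweep")
})

test_that("fixtures are seeded and satisfy their invariants", {
  ph <- generate_fixtures("phases", list(n = 20, jitter_sd = 0), seed = 1)
  expect_equal(var(ph$theta), 0)
  wf <- generate_fixtures("waveform", seed = 1)
  expect_lt(abs(desyncdbs:::trapz(wf$t, wf$u_p)), 1e-9)
  di <- generate_fixtures("distances", list(n = 10), seed = 1)
  expect_equal(di$scale, rep(1, 10))
  a <- generate_fixtures("phases", list(n = 5), seed = 7)
  b <- generate_fixtures("phases", list(n = 5), seed = 7)
  expect_identical(a, b)
})

test_that("experiments are deterministic given the seed", {
  prc <- test_prc()
  ov <- list(N = 10, duration = 25, jitter_sd = 0.05)
  d1 <- tempfile(); d2 <- tempfile()
  r1 <- run_experiment("fig8_sync_validation", ov, seed = 3, prc = prc,
                       out_dir = d1)
  r2 <- run_experiment("fig8_sync_validation", ov, seed = 3, prc = prc,
                       out_dir = d2)
  f1 <- file.path(d1, "fig8_sync_validation_metrics.json")
  f2 <- file.path(d2, "fig8_sync_validation_metrics.json")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_lt(r1$metrics$expected_rate, 0)
})
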