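test_that("spectral differentiation is exact for band-limited signals", {
  th <- 2 * pi * (0:255) / 256
  expect_lt(max(abs(differentiate_periodic(sin(th)) - cos(th))), 1e-8)
  expect_lt(max(abs(differentiate_periodic(cos(3 * th), 2L) + 9 * cos(3 * th))), 1e-7)
  expect_equal(differentiate_periodic(rep(2.5, 64)), rep(0, 64))
})

test_that("rough input triggers the spectral-energy warning", {
  set.seed(2)
  y <- rep(c(1, -1), 64) + 0.01 * rnorm(128)  # Nyquist-dominated signal
  expect_warning(differentiate_periodic(y), "spectral")
})

test_that("Fourier fit reproduces samples and analytic derivatives", {
  th <- 2 * pi * (0:127) / 128
  y <- 1 + 0.5 * cos(th) - 2 * sin(3 * th)
  cf <- desyncdbs:::fourier_fit(y, n_harm = 10)
  expect_lt(max(abs(desyncdbs:::fourier_eval(cf, th) - y)), 1e-12)
  d1 <- -0.5 * sin(th) - 6 * cos(3 * th)
  expect_lt(max(abs(desyncdbs:::fourier_eval(cf, th, 1L) - d1)), 1e-12)
})
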