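# Truncated Fourier representation of 2*pi-periodic tabulated quantities.
# Coefficients are stored as c(a0, a_1..a_K, b_1..b_K) so compiled code can
# evaluate value, first and second theta-derivative at arbitrary phase.

#' Fit a truncated Fourier series to uniformly sampled periodic data
#'
#' Samples are assumed to lie at `theta_j = 2*pi*(j-1)/M`, `j = 1..M`.
#'
#' @param y numeric vector of samples on the uniform phase grid.
#' @param n_harm number of harmonics retained (must be `< length(y)/2`).
#' @return numeric coefficient vector `c(a0, a_1..a_K, b_1..b_K)`.
#' @keywords internal
fourier_fit <- function(y, n_harm = 64L) {
  m <- length(y)
  if (n_harm >= m / 2) stop("n_harm must be below the Nyquist limit")
  cf <- stats::fft(y) / m
  k <- seq_len(n_harm)
  c(Re(cf[1]), 2 * Re(cf[k + 1]), -2 * Im(cf[k + 1]))
}

#' Evaluate a fitted Fourier series and its phase derivatives
#'
#' @param coef coefficient vector from [fourier_fit()].
#' @param theta phases (radians) at which to evaluate.
#' @param deriv derivative order: 0, 1 or 2.
#' @return numeric vector of the requested derivative at `theta`.
#' @keywords internal
fourier_eval <- function(coef, theta, deriv = 0L) {
  out <- cpp_fourier_eval(coef, as.numeric(theta))
  out[, deriv + 1L]
}

#' Spectral differentiation of a uniformly sampled periodic signal
#'
#' Differentiates samples of a \eqn{2\pi}-periodic signal on a uniform phase
#' grid by multiplication in Fourier space. Warns when more than half of the
#' spectral energy sits in the top quartile of modes, which indicates the
#' input is too rough for spectral differentiation to be trustworthy.
#'
#' @param y numeric samples on the uniform grid `theta_j = 2*pi*(j-1)/M`.
#' @param order derivative order (1 or 2).
#' @return numeric vector of derivative samples on the same grid.
#' @examples
#' th <- 2 * pi * (0:255) / 256
#' max(abs(differentiate_periodic(sin(th)) - cos(th)))
#' @export
differentiate_periodic <- function(y, order = 1L) {
  m <- length(y)
  cf <- stats::fft(y)
  pw <- Mod(cf[2:(m %/% 2 + 1)])^2
  hi <- pw[seq.int(ceiling(length(pw) * 0.75), length(pw))]
  if (sum(pw) > 0 && sum(hi) / sum(pw) > 0.5) {
    warning("over half of the spectral energy is in the top quartile of modes; ",
            "spectral derivative may be unreliable")
  }
  k <- c(0:(m %/% 2), -((m - m %/% 2 - 1):1))
  if (m %% 2 == 0 && order %% 2 == 1) k[m %/% 2 + 1] <- 0  # odd-order Nyquist
  Re(stats::fft(cf * (1i * k)^order, inverse = TRUE)) / m
}
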