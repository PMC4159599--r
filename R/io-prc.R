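# CSV caching of the phase response curve tabulation, so stimulus design can
# run from a file without recomputing the adjoint.

#' Export/import a PRC tabulation as CSV
#'
#' Writes the uniform-grid tabulation (`theta, Z, dZ, d2Z, f, df, d2f`) plus
#' a `period` column. `read_prc_csv()` re-fits the Fourier representation
#' from the samples and returns a `prc` object sufficient for stimulus
#' design and exponent evaluation (the embedded limit cycle and adjoint
#' diagnostics of a freshly computed PRC are not preserved).
#'
#' @param prc a [compute_prc()] object.
#' @param path CSV file path.
#' @param n_harm harmonics used when re-fitting on import.
#' @return `read_prc_csv()` returns an object of class `prc`.
#' @export
write_prc_csv <- function(prc, path) {
  df <- as.data.frame(prc$curves)
  df$period <- prc$T
  utils::write.csv(df, path, row.names = FALSE)
  invisible(prc)
}

#' @rdname write_prc_csv
#' @export
read_prc_csv <- function(path, n_harm = 64L) {
  df <- utils::read.csv(path)
  need <- c("theta", "Z", "f", "period")
  if (!all(need %in% names(df))) {
    stop("PRC CSV must contain columns: ", paste(need, collapse = ", "))
  }
  period <- df$period[1]
  z_coef <- fourier_fit(df$Z, n_harm = min(n_harm, nrow(df) %/% 2 - 1))
  f_coef <- fourier_fit(df$f, n_harm = min(n_harm, nrow(df) %/% 2 - 1))
  theta <- df$theta
  ev <- cpp_fourier_eval(z_coef, theta)
  fv <- cpp_fourier_eval(f_coef, theta)
  curves <- tibble::tibble(theta = theta, Z = ev[, 1], dZ = ev[, 2],
                           d2Z = ev[, 3], f = fv[, 1], df = fv[, 2],
                           d2f = fv[, 3])
  structure(list(curves = curves, z_coef = z_coef, f_coef = f_coef,
                 adjoint = NULL, norm_resid = NA_real_,
                 T = period, omega = 2 * pi / period, lc = NULL,
                 params = NULL),
            class = "prc")
}
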