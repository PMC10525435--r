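#' Variational mode decomposition
#'
#' Decomposes a signal into `K` narrow-band modes about adaptively learned
#' center frequencies by ADMM in the frequency domain: each mode's spectrum is
#' updated as a Wiener filter centred on its current frequency, the center
#' frequencies move to their spectral centre of gravity, and an optional dual
#' ascent step (`tau`) enforces exact reconstruction. The signal is mirror-
#' extended by half its length on each side before transforming to suppress
#' boundary effects.
#'
#' @param x Numeric signal (length >= 2K).
#' @param K Number of modes.
#' @param alpha Bandwidth penalty (larger = narrower modes).
#' @param tau Dual ascent step (0 disables the exact-reconstruction dual).
#' @param tol Convergence tolerance on the relative mode update.
#' @param max_iter Iteration cap; non-convergence returns the current
#'   iterate with a warning.
#' @return List with `modes` (length(x) x K matrix, columns ordered by
#'   ascending center frequency) and `omega` (center frequencies as a
#'   fraction of the sampling rate).
#' @export
vmd_decompose <- function(x, K, alpha = 2000, tau = 0, tol = 1e-7,
                          max_iter = 500) {
  n <- length(x)
  if (n < 2 * K)
    transrr_error("transrr_parameter_error",
                  "signal length %d too short for K = %d modes", n, K)
  if (any(!is.finite(x)))
    transrr_error("transrr_data_error", "signal contains non-finite samples")
  # mirror extension: half the signal reflected on each side
  half <- floor(n / 2)
  xm <- c(rev(x[seq_len(half)]), x, rev(x[seq(n - half + 1, n)]))
  res <- cpp_vmd(xm, as.integer(K), alpha, tau, tol, as.integer(max_iter))
  if (!res$converged)
    warning(sprintf(
      "VMD did not converge within %d iterations (update %.3g); returning current iterate",
      max_iter, res$final_update), call. = FALSE)
  # crop the mirror extension; order modes by ascending center frequency
  modes <- res$modes[seq(half + 1, half + n), , drop = FALSE]
  ord <- order(res$omega)
  list(modes = modes[, ord, drop = FALSE], omega = res$omega[ord])
}
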