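#' Canonical double-gamma haemodynamic response function
#'
#' Standard two-gamma impulse response (response peak at 5 s, undershoot
#' peak at 15 s, peak-to-undershoot ratio 6), normalised to unit integral
#' so that a sustained block response plateaus at the neural amplitude.
#'
#' @param t Time in seconds (vector, `t >= 0`; negative values return 0).
#' @param peak Time-to-peak of the positive lobe (s).
#' @param undershoot Time-to-peak of the undershoot lobe (s).
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @return Numeric vector of HRF values, same length as `t`.
#' @export
#' @examples
#' t <- seq(0, 30, 0.1)
#' h <- canonical_hrf(t)
canonical_hrf <- function(t, peak = 5, undershoot = 15, ratio = 6) {
  stopifnot(peak > 0, undershoot > peak, ratio > 1)
  h <- stats::dgamma(t, shape = peak + 1, rate = 1) -
    stats::dgamma(t, shape = undershoot + 1, rate = 1) / ratio
  h[t < 0] <- 0
  # unit integral: each gamma density integrates to 1
  h / (1 - 1 / ratio)
}

#' Convolved block regressor
#'
#' Builds the condition regressor used both by the forward simulator and
#' by the GLM: a boxcar over the stimulus blocks convolved with
#' [canonical_hrf()] on a fine grid, then sampled at the requested times.
#' With the unit-integral HRF a 30-s block plateaus near 1, so GLM betas
#' read in percent signal change per unit neural amplitude.
#'
#' @param onsets Block onsets (s), relative to the start of the sampled
#'   window.
#' @param durations Block durations (s); recycled against `onsets`.
#' @param times Sample times (s) at which the regressor is evaluated.
#' @param dt Fine-grid resolution for the convolution (s).
#' @return Numeric vector, `length(times)`.
#' @export
block_regressor <- function(onsets, durations, times, dt = 0.1) {
  stopifnot(length(onsets) >= 1, all(durations > 0))
  durations <- rep_len(durations, length(onsets))
  t_max <- max(times) + dt
  fine <- seq(0, t_max, by = dt)
  box <- numeric(length(fine))
  for (i in seq_along(onsets)) {
    box[fine >= onsets[i] & fine < onsets[i] + durations[i]] <- 1
  }
  hrf <- canonical_hrf(seq(0, 40, by = dt))
  conv <- stats::convolve(box, rev(hrf), type = "open")[seq_along(fine)] * dt
  stats::approx(fine, conv, xout = times, rule = 2)$y
}

#' Legendre polynomial drift basis
#'
#' Low-order Legendre polynomials on `[-1, 1]`, evaluated over `n` equally
#' spaced points; the per-run drift model shared by the simulator and the
#' GLM nuisance regressors.
#'
#' @param n Number of samples.
#' @param order Highest polynomial order (`>= 0`).
#' @return `n x (order + 1)` matrix; column `j` is the order `j - 1`
#'   polynomial (column 1 is the constant).
#' @export
legendre_basis <- function(n, order = 3) {
  stopifnot(n >= 2, order >= 0)
  x <- seq(-1, 1, length.out = n)
  P <- matrix(0, n, order + 1)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- x
  if (order >= 2) {
    for (k in 2:order) {
      # Bonnet recurrence
      P[, k + 1] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1]) / k
    }
  }
  P
}
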