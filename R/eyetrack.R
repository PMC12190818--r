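#' Preprocess a gaze trace
#'
#' Cleaning pipeline for fixation data sampled at a constant rate:
#' samples within a guard window (default 200 ms) around each invalid
#' (blink) segment are removed and filled by linear interpolation, a
#' linear trend is removed from each coordinate, and the mean of each
#' stimulus block is subtracted. Blocks with no valid samples are dropped
#' with a warning.
#'
#' @param trace Data frame with `time` (ms, strictly increasing at a
#'   constant rate), `x`, `y`, `valid` (logical), and optionally `block`.
#' @param guard_ms Guard window removed before and after each blink (ms).
#' @param hz Sampling rate (Hz).
#' @return Cleaned trace (same columns; all samples valid).
#' @export
preprocess_gaze <- function(trace, guard_ms = 200, hz = 1000) {
  stopifnot(all(c("time", "x", "y", "valid") %in% names(trace)))
  if (is.unsorted(trace$time, strictly = TRUE)) {
    stop("time must be strictly increasing")
  }
  if (is.null(trace$block)) trace$block <- 1L
  # drop fully-invalid blocks
  ok_block <- tapply(trace$valid, trace$block, any)
  if (!all(ok_block)) {
    warning(sprintf("dropping %d fully-invalid block(s)",
                    sum(!ok_block)))
    trace <- trace[trace$block %in% names(ok_block)[ok_block], ,
                   drop = FALSE]
  }
  guard <- round(guard_ms * hz / 1000)
  bad <- !trace$valid
  if (any(bad)) {
    idx <- which(bad)
    ext <- unique(unlist(lapply(idx, function(i) {
      seq(max(1, i - guard), min(nrow(trace), i + guard))
    })))
    keep <- setdiff(seq_len(nrow(trace)), ext)
    if (length(keep) < 2) stop("fewer than 2 valid samples after blink removal")
    for (v in c("x", "y")) {
      trace[[v]][ext] <- stats::approx(trace$time[keep], trace[[v]][keep],
                                       xout = trace$time[ext],
                                       rule = 2)$y
    }
    trace$valid <- TRUE
  }
  for (v in c("x", "y")) {
    fitv <- stats::lm.fit(cbind(1, trace$time), trace[[v]])
    trace[[v]] <- fitv$residuals
    mb <- tapply(trace[[v]], trace$block, mean)
    trace[[v]] <- trace[[v]] - as.numeric(mb[as.character(trace$block)])
  }
  trace
}

#' Bivariate contour ellipse area (BCEA)
#'
#' Area of the ellipse containing a given fraction of gaze samples under
#' a bivariate Gaussian model:
#' `BCEA = 2 pi k sigma_x sigma_y sqrt(1 - rho^2)`, with
#' `k = -ln(1 - P)` (so the 95% area uses k = 2.9957), `sigma` the
#' sample SDs and `rho` the sample correlation.
#'
#' @param x,y Gaze samples (degrees), `length >= 10`; or a data frame
#'   with `x`/`y` columns passed as `x`.
#' @param p Probability content of the ellipse.
#' @return Area in squared input units (deg^2).
#' @export
#' @examples
#' set.seed(1)
#' bcea(rnorm(1000), rnorm(1000)) # ~ 2*pi*2.9957
bcea <- function(x, y = NULL, p = 0.95) {
  if (is.data.frame(x)) {
    y <- x$y
    x <- x$x
  }
  stopifnot(length(x) == length(y), length(x) >= 10, p > 0, p < 1)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    warning("zero variance: BCEA is 0")
    return(0)
  }
  rho <- stats::cor(x, y)
  k <- -log(1 - p)
  2 * pi * k * sx * sy * sqrt(max(0, 1 - rho^2))
}

#' Fraction of samples inside the BCEA ellipse
#'
#' Empirical containment check of the [bcea()] ellipse: the fraction of
#' samples whose Mahalanobis distance (under the sample mean/covariance)
#' is within the `p`-content contour `-2 ln(1 - p)`.
#'
#' @inheritParams bcea
#' @return Fraction in `[0, 1]`.
#' @export
bcea_containment <- function(x, y = NULL, p = 0.95) {
  if (is.data.frame(x)) {
    y <- x$y
    x <- x$x
  }
  xy <- cbind(x, y)
  d2 <- stats::mahalanobis(xy, colMeans(xy), stats::cov(xy))
  mean(d2 <= -2 * log(1 - p))
}
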