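#' Michelson contrast between bar and background luminance
#'
#' `C = (Lbar - L0) / (Lbar + L0)`, the luminance contrast of the texture
#' bars against the uniform background.
#'
#' @param l_bar Bar luminance (cd/m^2), `>= l0`.
#' @param l0 Background luminance (cd/m^2), `> 0`.
#' @return Contrast in `[0, 1)`.
#' @export
#' @examples
#' michelson_contrast(78.9, 43.8)
michelson_contrast <- function(l_bar, l0) {
  if (any(l0 <= 0)) stop("background luminance must be positive")
  if (any(l_bar < l0)) stop("bar luminance must be >= background luminance")
  (l_bar - l0) / (l_bar + l0)
}

#' Simulated 2AFC Weibull observer
#'
#' Returns an observer function mapping contrast to probability correct in
#' a two-alternative forced-choice task,
#' `P(c) = 0.5 + (0.5 - lapse/2) * (1 - exp(-(c/scale)^slope))`,
#' with the Weibull scale calibrated so that `P(threshold_c)` equals the
#' criterion accuracy (80% by default). The range is
#' `[0.5, 1 - lapse/2]`.
#'
#' @param threshold_c Contrast at criterion accuracy (> 0).
#' @param slope Weibull shape parameter (> 0).
#' @param guess Guess rate; fixed at 0.5 for 2AFC.
#' @param lapse Lapse rate in `[0, 0.05]`.
#' @param criterion Criterion accuracy defining the threshold.
#' @return Function `contrast -> P(correct)` with class
#'   `weibull_observer`; parameters in `attr(, "pars")`.
#' @export
#' @examples
#' obs <- make_weibull_observer(0.1, 3)
#' obs(0.1) # 0.80
make_weibull_observer <- function(threshold_c, slope, guess = 0.5,
                                  lapse = 0.01, criterion = 0.80) {
  if (!(threshold_c > 0) || !(slope > 0)) {
    stop("threshold and slope must be positive")
  }
  stopifnot(guess == 0.5, lapse >= 0, lapse <= 0.05,
            criterion > guess, criterion < 1 - lapse / 2)
  scale <- weibull_scale(threshold_c, slope, guess, lapse, criterion)
  f <- function(contrast) {
    weibull_p(contrast, scale = scale, slope = slope,
              guess = guess, lapse = lapse)
  }
  structure(f, pars = list(threshold = threshold_c, slope = slope,
                           scale = scale, guess = guess, lapse = lapse,
                           criterion = criterion),
            class = c("weibull_observer", "function"))
}

# Weibull psychometric function (2AFC with lapse-to-guess convention).
weibull_p <- function(contrast, scale, slope, guess = 0.5, lapse = 0.01) {
  p <- guess + (1 - guess - lapse / 2) *
    (1 - exp(-(pmax(contrast, 0) / scale)^slope))
  p
}

# Scale parameter such that weibull_p(threshold) == criterion.
weibull_scale <- function(threshold, slope, guess = 0.5, lapse = 0.01,
                          criterion = 0.80) {
  q <- (criterion - guess) / (1 - guess - lapse / 2)
  threshold / (-log(1 - q))^(1 / slope)
}

# Threshold at `criterion` implied by a fitted scale/slope.
weibull_threshold <- function(scale, slope, guess = 0.5, lapse = 0.01,
                              criterion = 0.80) {
  q <- (criterion - guess) / (1 - guess - lapse / 2)
  scale * (-log(1 - q))^(1 / slope)
}

#' Adaptive 3-down-1-up staircase
#'
#' Runs one transformed up-down staircase against a simulated observer:
#' contrast steps down after three consecutive correct responses and up
#' after every error, converging on the 79.4% point
#' (`0.5^(1/3)`). Steps are multiplicative on contrast: 0.1 log10 units
#' before the second reversal, 0.05 afterwards. Contrast is clamped to the
#' luminance-feasible range of the display.
#'
#' @param observer A [make_weibull_observer()] function (or any function
#'   contrast -> P(correct)).
#' @param n_trials Number of trials.
#' @param start_contrast Starting contrast, within `bounds`.
#' @param bounds Contrast bounds; default the psychophysics display range
#'   (background 43.8 cd/m^2, maximum bar luminance 78.9 cd/m^2) with a
#'   small positive floor.
#' @param steps Log10 step sizes before and after the second reversal.
#' @param seed Integer seed for the observer's binomial responses.
#' @param staircase_id Identifier stored in the output.
#' @return Data frame: `trial`, `contrast`, `correct`, `reversal`
#'   (logical), `staircase_id`.
#' @export
run_staircase <- function(observer, n_trials = 60, start_contrast = 0.2,
                          bounds = c(1e-3, michelson_contrast(78.9, 43.8)),
                          steps = c(0.1, 0.05), seed = 1L,
                          staircase_id = 1L) {
  stopifnot(n_trials >= 1, start_contrast >= bounds[1],
            start_contrast <= bounds[2], bounds[1] > 0, bounds[2] < 1)
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  contrast <- numeric(n_trials)
  correct <- logical(n_trials)
  reversal <- logical(n_trials)
  c_now <- start_contrast
  run_correct <- 0L
  n_rev <- 0L
  last_dir <- 0L # -1 down, +1 up
  for (i in seq_len(n_trials)) {
    contrast[i] <- c_now
    correct[i] <- stats::runif(1) < observer(c_now)
    dir <- 0L
    if (correct[i]) {
      run_correct <- run_correct + 1L
      if (run_correct == 3L) {
        dir <- -1L
        run_correct <- 0L
      }
    } else {
      dir <- 1L
      run_correct <- 0L
    }
    if (dir != 0L) {
      if (last_dir != 0L && dir != last_dir) {
        n_rev <- n_rev + 1L
        reversal[i] <- TRUE
      }
      last_dir <- dir
      step <- if (n_rev < 2L) steps[1] else steps[2]
      c_now <- min(max(c_now * 10^(dir * step), bounds[1]), bounds[2])
    }
  }
  data.frame(trial = seq_len(n_trials), contrast = contrast,
             correct = correct, reversal = reversal,
             staircase_id = staircase_id)
}

#' Maximum-likelihood Weibull psychometric fit
#'
#' Fits the 2AFC Weibull psychometric function to trial data by binomial
#' maximum likelihood over (scale, slope), with the guess rate fixed at
#' 0.5 and the lapse rate fixed (0.01 by default). The contrast detection
#' threshold is read off at the criterion accuracy (80%) and the contrast
#' sensitivity is its reciprocal, `S = 1/threshold`.
#'
#' @param trials Data frame with columns `contrast` and `correct` (e.g.
#'   pooled [run_staircase()] output).
#' @param lapse Fixed lapse rate.
#' @param criterion Criterion accuracy for the threshold.
#' @param guess Fixed guess rate (2AFC: 0.5).
#' @return Object of class `weibull_fit`: `threshold`, `sensitivity`,
#'   `slope`, `scale`, `guess`, `lapse`, `criterion`, `logLik`, `n`.
#' @export
fit_weibull <- function(trials, lapse = 0.01, criterion = 0.80,
                        guess = 0.5) {
  stopifnot(is.data.frame(trials),
            all(c("contrast", "correct") %in% names(trials)))
  y <- as.logical(trials$correct)
  x <- as.numeric(trials$contrast)
  if (any(!is.finite(x)) || any(x < 0)) stop("invalid contrasts")
  if (length(unique(x)) < 2) {
    stop("non-identifiable data: need >= 2 distinct contrast levels")
  }
  if (all(y) || all(!y)) {
    stop(sprintf(paste0("non-identifiable data: all %d responses are %s; ",
                        "the psychometric slope cannot be estimated"),
                 length(y), if (all(y)) "correct" else "incorrect"))
  }
  nll <- function(par) {
    p <- weibull_p(x, scale = exp(par[1]), slope = exp(par[2]),
                   guess = guess, lapse = lapse)
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    -sum(ifelse(y, log(p), log(1 - p)))
  }
  starts <- expand.grid(scale = log(stats::quantile(x, c(0.25, 0.5, 0.75),
                                                    names = FALSE)),
                        slope = log(c(1, 3)))
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    stats::optim(as.numeric(starts[i, ]), nll, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-10))
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best_val <- min(vals)
  # ties broken by the smallest slope
  cand <- which(vals <= best_val + 1e-8)
  slopes <- vapply(fits[cand], function(f) exp(f$par[2]), numeric(1))
  best <- fits[[cand[which.min(slopes)]]]
  scale <- exp(best$par[1])
  slope <- exp(best$par[2])
  thr <- weibull_threshold(scale, slope, guess, lapse, criterion)
  structure(list(threshold = thr, sensitivity = 1 / thr, slope = slope,
                 scale = scale, guess = guess, lapse = lapse,
                 criterion = criterion, logLik = -best$value,
                 n = length(y)),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(paste0("Weibull 2AFC fit (%d trials): threshold %.4f at %.0f%%",
                     " accuracy, sensitivity %.3f, slope %.2f\n"),
              x$n, x$threshold, 100 * x$criterion, x$sensitivity, x$slope))
  invisible(x)
}

#' @export
coef.weibull_fit <- function(object, ...) {
  c(threshold = object$threshold, slope = object$slope,
    scale = object$scale, sensitivity = object$sensitivity)
}

#' @export
predict.weibull_fit <- function(object, contrast, ...) {
  weibull_p(contrast, scale = object$scale, slope = object$slope,
            guess = object$guess, lapse = object$lapse)
}

#' Behavioural sensitivity to saliency
#'
#' Difference between the contrast sensitivities for localizing the
#' high- and low-orientation-contrast foreground,
#' `SS = S(90 deg) - S(15 deg)`.
#'
#' @param s90,s15 Contrast sensitivities (1/threshold) for the 90 and 15
#'   degree orientation-contrast conditions; finite scalars or vectors.
#' @return `s90 - s15`.
#' @export
behavioral_saliency_sensitivity <- function(s90, s15) {
  stopifnot(all(is.finite(s90)), all(is.finite(s15)))
  s90 - s15
}
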