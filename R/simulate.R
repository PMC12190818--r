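#' Laminar-origin scenario specification
#'
#' Encodes the three candidate origins of the visual saliency signal as
#' region x layer x orientation-contrast activation gains (% signal
#' change) for the synthetic cortex:
#' \describe{
#'   \item{feedback_parietal}{saliency computed in parietal cortex and fed
#'     back: deep-layer dominance in IPS, deep + superficial in V1.}
#'   \item{v1sh}{saliency computed by horizontal connections in V1:
#'     superficial dominance in V1, middle-layer (feedforward-recipient)
#'     dominance in IPS.}
#'   \item{sc_tectothalamic}{saliency of subcortical (tectal) origin
#'     relayed through the thalamus: middle + superficial dominance in
#'     both cortical regions.}
#' }
#' Default gains encode these laminar orderings qualitatively; the 15
#' degree condition is the 90 degree pattern scaled by 0.4 and the 0
#' degree (uniform texture) condition is a flat 0.25.
#'
#' @param name Scenario name (one of the three above).
#' @param gains Optional replacement gain array
#'   (region x layer x theta, dimnames `V1/V2/IPS`,
#'   `deep/middle/superficial`, `90/15/0`); all entries finite and
#'   nonnegative.
#' @param noise_sd Gaussian noise SD (% signal change) per frame.
#' @param drift_amp SD of the per-run Legendre drift coefficients
#'   (% signal change).
#' @param bold_scale BOLD amplitude of the not-nulled channel as a
#'   multiple of the CBV gain; the same BOLD factor multiplies the nulled
#'   channel as T2* contamination that BOLD correction must remove.
#' @param bold_bias Slope of an optional linear-in-depth superficial bias
#'   on the BOLD channel (draining-vein emulation); 0 disables it.
#' @param seed Default seed for simulations driven by this scenario.
#' @return Object of class `scenario_spec`.
#' @export
#' @examples
#' sc <- scenario_spec("v1sh", noise_sd = 0)
#' sc$gains["V1", , "90"]
scenario_spec <- function(name = c("v1sh", "feedback_parietal",
                                   "sc_tectothalamic"),
                          gains = NULL, noise_sd = 0.5, drift_amp = 0.3,
                          bold_scale = 2, bold_bias = 0, seed = 1L) {
  name <- match.arg(name)
  if (is.null(gains)) gains <- default_scenario_gains(name)
  stopifnot(identical(dim(gains), c(3L, 3L, 3L)))
  dimnames(gains) <- list(REGIONS, LAYERS, THETAS)
  if (any(!is.finite(gains)) || any(gains < 0)) {
    stop("gains must be finite and nonnegative")
  }
  g90 <- gains[, , "90"]
  if (name == "v1sh") {
    if (!(g90["V1", "superficial"] > g90["V1", "deep"] &&
          g90["IPS", "middle"] > g90["IPS", "deep"])) {
      stop("v1sh gains must favour V1 superficial and IPS middle over deep")
    }
  }
  if (name == "feedback_parietal" &&
      which.max(g90["IPS", ]) != which(LAYERS == "deep")) {
    stop("feedback_parietal gains must be maximal in IPS deep")
  }
  stopifnot(noise_sd >= 0, drift_amp >= 0, bold_scale >= 0)
  structure(list(name = name, gains = gains, noise_sd = noise_sd,
                 drift_amp = drift_amp, bold_scale = bold_scale,
                 bold_bias = bold_bias, seed = as.integer(seed)),
            class = "scenario_spec")
}

default_scenario_gains <- function(name) {
  g90 <- switch(name,
    v1sh = rbind(V1 = c(0.3, 0.4, 1.0),
                 V2 = c(0.3, 0.85, 0.9),
                 IPS = c(0.3, 1.0, 0.4)),
    feedback_parietal = rbind(V1 = c(1.0, 0.3, 0.8),
                              V2 = c(0.9, 0.3, 0.8),
                              IPS = c(1.0, 0.3, 0.3)),
    sc_tectothalamic = rbind(V1 = c(0.3, 1.0, 0.8),
                             V2 = c(0.3, 1.0, 0.8),
                             IPS = c(0.3, 1.0, 0.8)))
  colnames(g90) <- LAYERS
  gains <- array(0, c(3, 3, 3), dimnames = list(REGIONS, LAYERS, THETAS))
  gains[, , "90"] <- g90
  gains[, , "15"] <- 0.4 * g90
  gains[, , "0"] <- 0.25
  gains
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario '%s': noise %.3g%%, drift %.3g%%, BOLD x%.2g%s\n",
              x$name, x$noise_sd, x$drift_amp, x$bold_scale,
              if (x$bold_bias != 0) sprintf(", depth bias %.2g", x$bold_bias)
              else ""))
  print(round(x$gains[, , "90"], 3))
  invisible(x)
}

#' Simulate an interleaved nulled / not-nulled VASO session
#'
#' Forward model for one scanning session of a synthetic cortical column
#' model under a laminar-origin scenario. Per voxel, the CBV activation
#' amplitude for each condition is the scenario gain mixed through the
#' voxel's grey-matter layer weights. Activation *decreases* the
#' blood-nulled signal (VASO sign convention) and increases the
#' not-nulled (BOLD) signal; the BOLD factor also multiplies the nulled
#' frames, emulating the T2* contamination that BOLD correction removes.
#' Gaussian noise and slow Legendre polynomial drift (orders 1-3, per
#' run, per channel) are added. Condition waveforms are the block
#' regressors of [block_regressor()], centred so that activation is
#' expressed in percent signal change of the run-mean signal.
#'
#' @param model A [build_column_model()].
#' @param design A [block_design()].
#' @param scenario A [scenario_spec()].
#' @param seed Integer seed; defaults to `scenario$seed`.
#' @param baseline Baseline signal level (arbitrary units).
#' @param subject_scale Multiplies all gains (per-subject amplitude).
#' @return A `laminar_series`: list with `data` (voxel x frame matrix),
#'   `frame_times` (s), `frame_labels` (`"nulled"`/`"notnulled"`), `run`
#'   (per frame), `voxel_region`, and `meta` (timing, baseline).
#' @export
simulate_vaso_session <- function(model, design, scenario,
                                  seed = scenario$seed, baseline = 100,
                                  subject_scale = 1) {
  stopifnot(inherits(model, "column_model"),
            inherits(design, "block_design"),
            inherits(scenario, "scenario_spec"))
  frames <- design_frames(design)
  gains <- scenario$gains
  if (!all(unique(model$voxels$region) %in% dimnames(gains)[[1]])) {
    stop("scenario gains missing for some model region")
  }
  W <- layer_weights(model)[, LAYERS, drop = FALSE]
  region <- model$voxels$region
  nv <- nrow(W)
  thetas <- dimnames(gains)[[3]]
  # voxel x theta CBV amplitudes (% signal change)
  amp <- sapply(thetas, function(th) {
    rowSums(W * gains[region, , th, drop = FALSE][, , 1]) * subject_scale
  })
  depth <- pmin(pmax(equivolume_depth(model$voxels$radius,
                                      model$geometry$wm_radius,
                                      model$geometry$pial_radius,
                                      model$geometry$model), 0), 1)
  bamp <- amp * scenario$bold_scale * (1 + scenario$bold_bias * depth)

  rng <- local_rng(seed)
  on.exit(restore_rng(rng))

  n_pairs <- frames$n_pairs
  rel <- frames$rel_times
  t_nulled <- rel[seq(1, 2 * n_pairs, 2)]
  t_not <- rel[seq(2, 2 * n_pairs, 2)]
  runs <- sort(unique(design$run))
  data <- matrix(NA_real_, nv, length(frames$times))
  col0 <- 0L
  for (r in runs) {
    act_n <- matrix(0, nv, n_pairs)   # CBV term on nulled frames
    bold_n <- matrix(0, nv, n_pairs)  # BOLD term on nulled frames
    bold_b <- matrix(0, nv, n_pairs)  # BOLD term on not-nulled frames
    for (th in thetas) {
      blk <- design_run(design, r, th)
      if (nrow(blk) == 0) next
      xn <- cached_block_regressor(blk$onset, blk$duration, t_nulled)
      xb <- cached_block_regressor(blk$onset, blk$duration, t_not)
      cx <- mean(upsample_even(xn, 2 * n_pairs))
      cy <- mean(upsample_odd(xb, 2 * n_pairs))
      act_n <- act_n + amp[, th] %o% (xn - cx)
      bold_n <- bold_n + bamp[, th] %o% (xn - cy)
      bold_b <- bold_b + bamp[, th] %o% (xb - cy)
    }
    nulled <- baseline * (1 - act_n / 100) * (1 + bold_n / 100)
    notnull <- baseline * (1 + bold_b / 100)
    if (scenario$drift_amp > 0) {
      L <- legendre_basis(2 * n_pairs, 3)[, 2:4, drop = FALSE]
      cf_n <- matrix(stats::rnorm(nv * 3, 0, scenario$drift_amp), nv, 3)
      cf_b <- matrix(stats::rnorm(nv * 3, 0, scenario$drift_amp), nv, 3)
      nulled <- nulled +
        baseline / 100 * tcrossprod(cf_n, L[seq(1, 2 * n_pairs, 2), ])
      notnull <- notnull +
        baseline / 100 * tcrossprod(cf_b, L[seq(2, 2 * n_pairs, 2), ])
    }
    if (scenario$noise_sd > 0) {
      sd_abs <- baseline * scenario$noise_sd / 100
      nulled <- nulled + matrix(stats::rnorm(nv * n_pairs, 0, sd_abs),
                                nv, n_pairs)
      notnull <- notnull + matrix(stats::rnorm(nv * n_pairs, 0, sd_abs),
                                  nv, n_pairs)
    }
    idx <- col0 + seq_len(2 * n_pairs)
    data[, idx[seq(1, 2 * n_pairs, 2)]] <- nulled
    data[, idx[seq(2, 2 * n_pairs, 2)]] <- notnull
    col0 <- col0 + 2L * n_pairs
  }
  laminar_series(data, frames$times, frames$labels, frames$run,
                 voxel_region = region,
                 meta = list(paired_tr = attr(design, "paired_tr"),
                             frame_dt = frames$frame_dt,
                             n_pairs = n_pairs, baseline = baseline,
                             run_length = frames$run_length))
}

#' Construct a laminar timeseries container
#'
#' @param data Voxel x frame matrix.
#' @param frame_times Acquisition times (s), strictly increasing.
#' @param frame_labels `"nulled"`/`"notnulled"` per frame; equal counts.
#' @param run Run index per frame.
#' @param voxel_region Optional region label per voxel.
#' @param meta List of timing metadata.
#' @return Object of class `laminar_series`.
#' @export
laminar_series <- function(data, frame_times, frame_labels, run,
                           voxel_region = NULL, meta = list()) {
  data <- as.matrix(data)
  stopifnot(ncol(data) == length(frame_times),
            length(frame_labels) == length(frame_times),
            length(run) == length(frame_times))
  if (any(diff(frame_times) <= 0)) stop("frame times must be strictly increasing")
  if (sum(frame_labels == "nulled") != sum(frame_labels == "notnulled")) {
    stop("unequal counts of nulled and not-nulled frames")
  }
  structure(list(data = data, frame_times = frame_times,
                 frame_labels = frame_labels, run = run,
                 voxel_region = voxel_region, meta = meta),
            class = "laminar_series")
}

#' @export
print.laminar_series <- function(x, ...) {
  cat(sprintf("Laminar series: %d voxels x %d frames (%d runs), %.2f-%.2f s\n",
              nrow(x$data), ncol(x$data), length(unique(x$run)),
              min(x$frame_times), max(x$frame_times)))
  invisible(x)
}

#' Simulate fixation gaze samples with blinks
#'
#' Bivariate Gaussian gaze scatter around fixation at a fixed sampling
#' rate, with Poisson blink events during which samples are invalid
#' (`NA` position, `valid = FALSE`).
#'
#' @param n_samples Number of samples.
#' @param sd_x,sd_y Gaze SD (degrees of visual angle), `>= 0`.
#' @param rho Correlation between x and y, `|rho| < 1`.
#' @param blink_rate Blink events per second.
#' @param blink_dur_ms Blink duration (ms).
#' @param fixation Fixation position `(x, y)` in degrees.
#' @param hz Sampling rate (Hz).
#' @param n_blocks Number of equal stimulus blocks to label.
#' @param seed Integer seed.
#' @return Data frame: `time` (ms), `x`, `y`, `valid`, `block`.
#' @export
simulate_gaze <- function(n_samples, sd_x = 0.3, sd_y = 0.3, rho = 0,
                          blink_rate = 0.1, blink_dur_ms = 150,
                          fixation = c(0, 0), hz = 1000, n_blocks = 1L,
                          seed = 1L) {
  stopifnot(n_samples >= 1, sd_x >= 0, sd_y >= 0, abs(rho) < 1,
            blink_rate >= 0)
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  z1 <- stats::rnorm(n_samples)
  z2 <- stats::rnorm(n_samples)
  x <- fixation[1] + sd_x * z1
  y <- fixation[2] + sd_y * (rho * z1 + sqrt(1 - rho^2) * z2)
  valid <- rep(TRUE, n_samples)
  dur_s <- n_samples / hz
  n_blinks <- stats::rpois(1, blink_rate * dur_s)
  if (n_blinks > 0) {
    onset <- sort(ceiling(stats::runif(n_blinks, 0, n_samples)))
    half <- round(blink_dur_ms * hz / 1000)
    for (o in onset) {
      idx <- seq(o, min(o + half - 1, n_samples))
      valid[idx] <- FALSE
    }
  }
  x[!valid] <- NA_real_
  y[!valid] <- NA_real_
  data.frame(time = (seq_len(n_samples) - 1) * 1000 / hz, x = x, y = y,
             valid = valid,
             block = rep(seq_len(n_blocks),
                         each = ceiling(n_samples / n_blocks))[seq_len(n_samples)])
}

#' Simulate a connectivity target series with known gPPI coupling
#'
#' Generates a target timecourse from a seed timecourse plus
#' condition-specific interaction terms: `self * seed` plus, for each
#' condition, `coupling[theta] * (shifted boxcar x seed)`, plus Gaussian
#' noise. The interaction uses the same one-paired-TR-shifted boxcar as
#' [build_ppi_design()], so the generative coupling contrasts are
#' directly recoverable by [fit_gppi()].
#'
#' @param seed_series Numeric seed timecourse on the frame grid.
#' @param times Frame times (s) of `seed_series` (run-relative grid used
#'   for boxcar evaluation when `run` has several runs).
#' @param run Run index per frame.
#' @param design The [block_design()] defining the condition blocks.
#' @param coupling Named coupling gains per condition, e.g.
#'   `c("90" = 0.5, "15" = 0.2, "0" = 0.2)`.
#' @param self Condition-independent coupling on the seed.
#' @param noise_sd Gaussian noise SD (same units as the series).
#' @param shift Boxcar shift (s); one paired TR by default.
#' @param rng_seed Integer seed for the noise.
#' @return Numeric target series.
#' @export
simulate_coupled_target <- function(seed_series, times, run, design,
                                    coupling, self = 0.8, noise_sd = 0.5,
                                    shift = attr(design, "paired_tr"),
                                    rng_seed = 1L) {
  stopifnot(length(seed_series) == length(times),
            length(run) == length(times))
  rng <- local_rng(rng_seed)
  on.exit(restore_rng(rng))
  target <- self * seed_series
  for (th in names(coupling)) {
    box <- shifted_boxcar(design, th, times, run, shift)
    target <- target + coupling[[th]] * box * seed_series
  }
  target + stats::rnorm(length(target), 0, noise_sd)
}
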