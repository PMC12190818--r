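# Temporal resampling operators for the alternating acquisition.
# A run has n frame pairs on a grid of 2n slots (interval = paired TR / 2);
# the nulled frames occupy the odd slots (1-based: 1, 3, ...), the
# not-nulled frames the even slots. Each stream is up-sampled by 2 onto
# the full grid with linear interpolation (edge-hold at the ends), which
# realises the "upsample x2 and shift by TR/2" alignment.

upsample_even <- function(v, m) {
  # native samples on slots 1, 3, ..., m - 1
  n <- length(v)
  stopifnot(m == 2 * n)
  out <- numeric(m)
  out[seq(1, m, 2)] <- v
  if (n > 1) out[seq(2, m - 2, 2)] <- (v[-n] + v[-1]) / 2
  out[m] <- v[n]
  out
}

upsample_odd <- function(v, m) {
  # native samples on slots 2, 4, ..., m
  n <- length(v)
  stopifnot(m == 2 * n)
  out <- numeric(m)
  out[seq(2, m, 2)] <- v
  out[1] <- v[1]
  if (n > 1) out[seq(3, m - 1, 2)] <- (v[-n] + v[-1]) / 2
  out
}

upsample_rows <- function(mat, m, which = c("even", "odd")) {
  which <- match.arg(which)
  n <- ncol(mat)
  stopifnot(m == 2 * n)
  out <- matrix(NA_real_, nrow(mat), m)
  if (which == "even") {
    out[, seq(1, m, 2)] <- mat
    if (n > 1) {
      out[, seq(2, m - 2, 2)] <- (mat[, -n, drop = FALSE] +
                                    mat[, -1, drop = FALSE]) / 2
    }
    out[, m] <- mat[, n]
  } else {
    out[, seq(2, m, 2)] <- mat
    out[, 1] <- mat[, 1]
    if (n > 1) {
      out[, seq(3, m - 1, 2)] <- (mat[, -n, drop = FALSE] +
                                    mat[, -1, drop = FALSE]) / 2
    }
  }
  out
}

#' Split an interleaved series and align both streams on a common grid
#'
#' Separates the alternating blood-nulled / not-nulled frames of a
#' [laminar_series()] and temporally up-samples each stream by a factor
#' of 2, shifting the lagging stream by half a paired TR, so that both
#' streams are sampled on the full acquisition grid (linear
#' interpolation, edge-hold at run boundaries). Runs are aligned
#' independently.
#'
#' @param series A [laminar_series()] whose labels alternate
#'   nulled / not-nulled starting with a nulled frame.
#' @return An `aligned_series`: list with `nulled` and `notnulled`
#'   (voxel x frame matrices on the common grid), `times`, `run`,
#'   `voxel_region`, `meta`.
#' @export
split_and_align <- function(series) {
  stopifnot(inherits(series, "laminar_series"))
  lab <- series$frame_labels
  n_fr <- length(lab)
  if (n_fr %% 2 != 0 ||
      !all(lab == rep(c("nulled", "notnulled"), n_fr / 2))) {
    stop("frame labels must alternate nulled/notnulled starting with nulled")
  }
  runs <- unique(series$run)
  nulled <- matrix(NA_real_, nrow(series$data), n_fr)
  notnull <- matrix(NA_real_, nrow(series$data), n_fr)
  for (r in runs) {
    idx <- which(series$run == r)
    m <- length(idx)
    dn <- series$data[, idx[lab[idx] == "nulled"], drop = FALSE]
    db <- series$data[, idx[lab[idx] == "notnulled"], drop = FALSE]
    nulled[, idx] <- upsample_rows(dn, m, "even")
    notnull[, idx] <- upsample_rows(db, m, "odd")
  }
  structure(list(nulled = nulled, notnulled = notnull,
                 times = series$frame_times, run = series$run,
                 voxel_region = series$voxel_region, meta = series$meta),
            class = "aligned_series")
}

#' BOLD correction by nulled / not-nulled division (BOCO)
#'
#' Divides the aligned blood-nulled stream by the not-nulled stream
#' frame-by-frame, removing the multiplicative T2* (BOLD) component and
#' leaving the CBV-weighted VASO signal. Voxels with any nonpositive
#' not-nulled sample are masked (`NA`) with a warning.
#'
#' @param aligned An [split_and_align()] result, or separate `nulled` /
#'   `notnulled` matrices via the two-argument form.
#' @param notnulled Optional not-nulled matrix when `aligned` is a
#'   nulled matrix.
#' @return A `vaso_series`: list with `data` (ratio), `times`, `run`,
#'   `voxel_region`, `meta`, `masked` (voxel indices).
#' @export
boco_correct <- function(aligned, notnulled = NULL) {
  if (inherits(aligned, "aligned_series")) {
    nmat <- aligned$nulled
    bmat <- aligned$notnulled
    times <- aligned$times; run <- aligned$run
    region <- aligned$voxel_region; meta <- aligned$meta
  } else {
    nmat <- as.matrix(aligned); bmat <- as.matrix(notnulled)
    stopifnot(identical(dim(nmat), dim(bmat)))
    times <- seq_len(ncol(nmat)); run <- rep(1L, ncol(nmat))
    region <- NULL; meta <- list()
  }
  bad <- which(apply(bmat <= 0 | !is.finite(bmat), 1, any))
  ratio <- nmat / bmat
  if (length(bad)) {
    ratio[bad, ] <- NA_real_
    warning(sprintf("%d voxel(s) masked: nonpositive not-nulled signal",
                    length(bad)))
  }
  structure(list(data = ratio, times = times, run = run,
                 voxel_region = region, meta = meta, masked = bad),
            class = "vaso_series")
}

#' Per-run percent signal change scaling
#'
#' Scales each voxel's timecourse to percent signal change about its
#' run-mean baseline, `100 * (x - m) / m`, independently per run. With
#' `sign = "cbv"` the result is negated, converting the VASO decrease to
#' a positive CBV response.
#'
#' @param x A `vaso_series`, or a numeric voxel x frame matrix.
#' @param run Run index per frame (required for the matrix form).
#' @param sign `"raw"` keeps the native sign; `"cbv"` negates.
#' @return Same shape as the input (`vaso_series` in, `vaso_series` out);
#'   voxels with a zero or non-finite run baseline are masked.
#' @export
percent_signal_change <- function(x, run = NULL, sign = c("raw", "cbv")) {
  sign <- match.arg(sign)
  is_series <- inherits(x, "vaso_series")
  data <- if (is_series) x$data else as.matrix(x)
  run <- if (is_series) x$run else run
  if (is.null(run)) run <- rep(1L, ncol(data))
  stopifnot(length(run) == ncol(data))
  out <- data
  masked <- integer(0)
  for (r in unique(run)) {
    idx <- which(run == r)
    m <- rowMeans(data[, idx, drop = FALSE])
    bad <- which(!is.finite(m) | m == 0)
    m[bad] <- NA_real_
    masked <- union(masked, bad)
    out[, idx] <- 100 * (data[, idx, drop = FALSE] - m) / m
  }
  if (sign == "cbv") out <- -out
  if (is_series) {
    x$data <- out
    x$masked <- union(x$masked, masked)
    x$meta$units <- if (sign == "cbv") "pct_cbv" else "pct"
    x
  } else out
}

# Condition regressors on the analysis grid. For an aligned-grid series
# the regressor is sampled on the native nulled grid and passed through
# the same x2 up-sampling as the data, so resampling cannot bias the
# amplitude estimate; for a native-grid series it is sampled directly.
condition_regressors <- function(design, times, run, aligned = TRUE) {
  conds <- attr(design, "conditions")
  runs <- sort(unique(run))
  run_length <- attr(design, "run_length")
  X <- matrix(0, length(times), length(conds),
              dimnames = list(NULL, paste0("cond_", conds)))
  for (r in runs) {
    idx <- which(run == r)
    rel <- times[idx] - (r - 1) * run_length
    for (j in seq_along(conds)) {
      blk <- design_run(design, r, conds[j])
      if (nrow(blk) == 0) next
      if (aligned) {
        m <- length(idx)
        xn <- cached_block_regressor(blk$onset, blk$duration, rel[seq(1, m, 2)])
        X[idx, j] <- upsample_even(xn, m)
      } else {
        X[idx, j] <- block_regressor(blk$onset, blk$duration, rel)
      }
    }
  }
  X
}

# Per-run intercept + Legendre drift columns.
nuisance_regressors <- function(run, drift_order = 3) {
  runs <- sort(unique(run))
  cols <- list()
  for (r in runs) {
    idx <- which(run == r)
    L <- legendre_basis(length(idx), drift_order)
    B <- matrix(0, length(run), ncol(L))
    B[idx, ] <- L
    colnames(B) <- paste0("run", r, "_drift", seq_len(ncol(L)) - 1)
    cols[[as.character(r)]] <- B
  }
  do.call(cbind, cols)
}

#' Block GLM for condition amplitudes
#'
#' Ordinary least squares fit of HRF-convolved block regressors plus
#' per-run intercept and Legendre drift nuisance regressors (and optional
#' motion columns) to every voxel timecourse.
#'
#' @param series A `vaso_series` (aligned grid; the default regressor
#'   path) or a [laminar_series()]-like list with `data`, `times`/
#'   `frame_times`, `run` on a native grid (`aligned = FALSE`).
#' @param design A [block_design()].
#' @param drift_order Legendre drift order per run.
#' @param motion Optional frame x parameter matrix of motion regressors.
#' @param aligned Whether condition regressors must pass through the
#'   alignment resampling (TRUE for BOCO output).
#' @return A `laminar_glm`: `betas` and `se` (voxel x regressor),
#'   `sigma2`, `df`, `conditions`, `X` (design matrix).
#' @export
fit_glm <- function(series, design, drift_order = 3, motion = NULL,
                    aligned = inherits(series, "vaso_series")) {
  data <- series$data
  times <- series$times %||% series$frame_times
  run <- series$run
  stopifnot(!is.null(data), length(times) == ncol(data))
  Xc <- condition_regressors(design, times, run, aligned = aligned)
  Xn <- nuisance_regressors(run, drift_order)
  X <- cbind(Xc, Xn)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    colnames(motion) <- colnames(motion) %||%
      paste0("motion", seq_len(ncol(motion)))
    X <- cbind(X, motion)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  bet <- qr.coef(qx, t(data))
  res <- t(data) - X %*% bet
  df <- nrow(X) - qx$rank
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(outer(sigma2, diag(xtx_inv)))
  colnames(se) <- colnames(X)
  structure(list(betas = t(bet), se = se, sigma2 = sigma2, df = df,
                 conditions = attr(design, "conditions"),
                 X = X, voxel_region = series$voxel_region),
            class = "laminar_glm")
}

#' @export
coef.laminar_glm <- function(object, ...) object$betas

#' Condition beta matrix from a GLM fit
#'
#' @param fit A [fit_glm()] result.
#' @param conditions Condition labels; defaults to all in the design.
#' @return Voxel x condition matrix of amplitudes.
#' @export
condition_betas <- function(fit, conditions = fit$conditions) {
  out <- fit$betas[, paste0("cond_", conditions), drop = FALSE]
  colnames(out) <- conditions
  out
}

#' @export
print.laminar_glm <- function(x, ...) {
  cat(sprintf("Laminar GLM: %d voxels, %d regressors (%d condition), df = %d\n",
              nrow(x$betas), ncol(x$betas), length(x$conditions), x$df))
  invisible(x)
}
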