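# Stimulus boxcar shifted by one TR (HRF delay surrogate), sampled on the
# acquisition frame grid; run-aware.
shifted_boxcar <- function(design, condition, times, run,
                           shift = attr(design, "paired_tr")) {
  run_length <- attr(design, "run_length")
  out <- numeric(length(times))
  for (r in sort(unique(run))) {
    idx <- which(run == r)
    rel <- times[idx] - (r - 1) * run_length
    blk <- design_run(design, r, condition)
    for (i in seq_len(nrow(blk))) {
      on <- blk$onset[i] + shift
      out[idx][rel >= on & rel < on + blk$duration[i]] <- 1
    }
  }
  out
}

#' Generalized psychophysiological interaction (gPPI) design
#'
#' Builds the gPPI design matrix for a seed timecourse without
#' deconvolution: the psychophysiological interaction regressor of each
#' condition is the elementwise product of the condition boxcar --
#' shifted by one paired TR to account for the haemodynamic delay -- and
#' the seed timecourse. Columns are the seed, one shifted boxcar per
#' condition, one PPI term per condition, and per-run baseline + Legendre
#' drift (plus optional motion) nuisance regressors.
#'
#' @param seed_series Seed ROI/layer mean timecourse on the frame grid.
#' @param design A [block_design()].
#' @param times Frame times (s).
#' @param run Run index per frame.
#' @param shift Boxcar shift (s); one paired TR by default (set to
#'   `attr(design, "frame_dt")` for a single-volume shift).
#' @param drift_order Legendre drift order per run.
#' @param motion Optional motion regressor matrix.
#' @param check_rank Error on a rank-deficient design (default). Disable
#'   only to inspect the constructed columns of a degenerate design.
#' @return A `ppi_design`: list with the design matrix `X`, column role
#'   indices (`seed`, `box`, `ppi`), `conditions`, and the inputs needed
#'   to refit.
#' @export
build_ppi_design <- function(seed_series, design, times, run,
                             shift = attr(design, "paired_tr"),
                             drift_order = 3, motion = NULL,
                             check_rank = TRUE) {
  stopifnot(length(seed_series) == length(times),
            length(run) == length(times))
  conds <- attr(design, "conditions")
  B <- sapply(conds, function(th) shifted_boxcar(design, th, times, run,
                                                 shift))
  colnames(B) <- paste0("box_", conds)
  PPI <- B * seed_series
  colnames(PPI) <- paste0("ppi_", conds)
  Xn <- nuisance_regressors(run, drift_order)
  X <- cbind(seed = seed_series, B, PPI, Xn)
  if (!is.null(motion)) X <- cbind(X, as.matrix(motion))
  qx <- qr(X)
  if (check_rank && qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient PPI design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  structure(list(X = X, conditions = conds,
                 seed_col = 1L,
                 box_cols = 1L + seq_along(conds),
                 ppi_cols = 1L + length(conds) + seq_along(conds),
                 qr = qx),
            class = "ppi_design")
}

#' Fit the gPPI model to a target timecourse
#'
#' Ordinary least squares of the target series on a [build_ppi_design()]
#' matrix; the PPI betas are the condition-specific coupling estimates.
#'
#' @param target_series Target ROI/layer mean timecourse.
#' @param ppi_design A [build_ppi_design()] result.
#' @return A `gppi_fit`: named coefficient vector in `$betas`, PPI betas
#'   per condition in `$ppi_betas`.
#' @export
fit_gppi <- function(target_series, ppi_design) {
  stopifnot(inherits(ppi_design, "ppi_design"),
            length(target_series) == nrow(ppi_design$X))
  beta <- qr.coef(ppi_design$qr, target_series)
  ppi <- beta[ppi_design$ppi_cols]
  names(ppi) <- ppi_design$conditions
  structure(list(betas = beta, ppi_betas = ppi,
                 conditions = ppi_design$conditions),
            class = "gppi_fit")
}

#' @export
coef.gppi_fit <- function(object, ...) object$betas

#' Saliency-dependent connectivity contrast
#'
#' The difference between the PPI coupling estimates of the 90 and 15
#' degree orientation-contrast conditions,
#' `delta = beta_PPI(90) - beta_PPI(15)`.
#'
#' @param fit A [fit_gppi()] result, or a named vector of PPI betas with
#'   elements `"90"` and `"15"`.
#' @return Scalar coupling contrast.
#' @export
saliency_connectivity <- function(fit) {
  b <- if (inherits(fit, "gppi_fit")) fit$ppi_betas else fit
  stopifnot(all(c("90", "15") %in% names(b)))
  unname(b["90"] - b["15"])
}

#' Group test of pathway connectivity contrasts
#'
#' One-sample t tests of the per-subject saliency connectivity contrasts
#' against zero, Holm-corrected across the tested pathways.
#'
#' @param deltas Subject x pathway matrix of connectivity contrasts.
#' @return Data frame: `pathway`, `mean_delta`, `t`, `df`, `p_raw`,
#'   `p_holm`.
#' @export
connectivity_group_test <- function(deltas) {
  D <- as.matrix(deltas)
  paths <- colnames(D) %||% paste0("pathway", seq_len(ncol(D)))
  res <- lapply(seq_len(ncol(D)), function(j) {
    tt <- stats::t.test(D[, j])
    data.frame(pathway = paths[j], mean_delta = mean(D[, j]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value)
  })
  out <- do.call(rbind, res)
  out$p_holm <- holm_correct(out$p_raw)
  out
}
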