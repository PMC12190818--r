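#' Spatial-regression unmixing of layer activity
#'
#' Recovers compartment amplitudes from voxel amplitudes by least squares
#' on the voxel volume-fraction weights: solves
#' `voxel_betas ~ W %*% compartment_betas`. Grey-matter layer estimates
#' (deep, middle, superficial) are returned; WM and CSF act as nuisance
#' compartments. Compartments with no weight anywhere in `W` are dropped
#' from the solve; a rank-deficient weight matrix over the represented
#' compartments is an error naming the unidentifiable ones.
#'
#' @param voxel_betas Numeric vector (one condition) or voxel x condition
#'   matrix of amplitudes.
#' @param W Voxel x compartment weight matrix (columns WM, CSF, deep,
#'   middle, superficial, as from [layer_weights()]).
#' @return Layer x condition matrix (rows deep/middle/superficial); the
#'   full compartment solution, including nuisance rows, is in
#'   `attr(, "compartments")`.
#' @export
#' @examples
#' W <- diag(5); colnames(W) <- c("WM","CSF","deep","middle","superficial")
#' unmix_layers(c(0, 0, 1, 2, 0.5), W)
unmix_layers <- function(voxel_betas, W) {
  B <- if (is.matrix(voxel_betas)) voxel_betas else cbind(beta = voxel_betas)
  W <- as.matrix(W)
  stopifnot(nrow(B) == nrow(W))
  if (is.null(colnames(W))) colnames(W) <- COMPARTMENTS[seq_len(ncol(W))]
  keep <- colSums(abs(W)) > 0
  Wk <- W[, keep, drop = FALSE]
  if (nrow(Wk) < ncol(Wk)) stop("fewer voxels than represented compartments")
  qw <- qr(Wk)
  if (qw$rank < ncol(Wk)) {
    bad <- colnames(Wk)[qw$pivot[(qw$rank + 1):ncol(Wk)]]
    stop("unmixing is rank deficient; unidentifiable compartment(s): ",
         paste(bad, collapse = ", "))
  }
  sol <- qr.coef(qw, B)
  full <- matrix(NA_real_, ncol(W), ncol(B),
                 dimnames = list(colnames(W), colnames(B)))
  full[keep, ] <- sol
  out <- full[intersect(LAYERS, rownames(full)), , drop = FALSE]
  attr(out, "compartments") <- full
  out
}

#' Select the foreground ROI from a localizer GLM
#'
#' Voxels with positive localizer activation from baseline at one-sided
#' `p < alpha` (uncorrected, GLM t statistic with residual degrees of
#' freedom), intersected with an anatomical region.
#'
#' @param fit A [fit_glm()] result for the localizer design.
#' @param condition Localizer condition (or conditions summed via
#'   contrast weights of 1) defining "activation from baseline".
#' @param region Anatomical region label(s) to intersect with; `NULL`
#'   keeps all voxels.
#' @param labels Region label per voxel; defaults to the fit's.
#' @param alpha One-sided significance threshold.
#' @return Integer voxel indices (possibly empty, with a warning).
#' @export
select_foreground_roi <- function(fit, condition, region = NULL,
                                  labels = fit$voxel_region,
                                  alpha = 0.05) {
  stopifnot(inherits(fit, "laminar_glm"))
  cols <- paste0("cond_", condition)
  b <- rowSums(fit$betas[, cols, drop = FALSE])
  # variance of the summed contrast from independent column SEs is not
  # exact under correlated regressors; use the exact contrast variance
  cvec <- as.numeric(colnames(fit$betas) %in% cols)
  xtx_inv <- chol2inv(chol(crossprod(fit$X)))
  cvar <- drop(t(cvec) %*% xtx_inv %*% cvec)
  se <- sqrt(fit$sigma2 * cvar)
  tstat <- b / se
  p <- stats::pt(tstat, df = fit$df, lower.tail = FALSE)
  sel <- which(b > 0 & p < alpha)
  if (!is.null(region) && !is.null(labels)) {
    sel <- sel[labels[sel] %in% region]
  }
  if (length(sel) == 0) warning("empty foreground ROI")
  sel
}

#' Layer x condition response profile for an ROI
#'
#' Unmixes the per-voxel condition amplitudes of the ROI voxels through
#' their layer weights, giving one grey-matter layer x condition response
#' matrix (one subject's profile for one region).
#'
#' @param cond_betas Voxel x condition amplitude matrix (all voxels).
#' @param W Voxel x compartment weight matrix matching `cond_betas` rows.
#' @param roi Integer voxel indices of the ROI (nonempty).
#' @return Layer x condition matrix (deep / middle / superficial).
#' @export
roi_layer_profile <- function(cond_betas, W, roi = seq_len(nrow(W))) {
  if (length(roi) == 0) stop("ROI is empty")
  B <- cond_betas[roi, , drop = FALSE]
  Wr <- W[roi, , drop = FALSE]
  # masked voxels (NA amplitudes) cannot enter the spatial regression
  ok <- stats::complete.cases(B)
  if (!all(ok)) {
    if (sum(ok) < 3) stop("too few unmasked voxels in the ROI")
    B <- B[ok, , drop = FALSE]
    Wr <- Wr[ok, , drop = FALSE]
  }
  unmix_layers(B, Wr)
}

#' Collect per-subject layer profiles into a group array
#'
#' @param profiles List (length = subjects) of layer x condition matrices
#'   as from [roi_layer_profile()].
#' @param region Region label attached to the result.
#' @return `layer_profile` array, subject x layer x condition.
#' @export
layer_profile <- function(profiles, region = NA_character_) {
  stopifnot(length(profiles) >= 1)
  arr <- aperm(simplify2array(profiles), c(3, 1, 2))
  dimnames(arr)[[1]] <- paste0("s", seq_len(dim(arr)[1]))
  structure(arr, region = region, class = c("layer_profile", "array"))
}

#' @export
print.layer_profile <- function(x, ...) {
  cat(sprintf("Layer profile [%s]: %d subjects x %d layers x %d conditions\n",
              attr(x, "region"), dim(x)[1], dim(x)[2], dim(x)[3]))
  print(round(apply(unclass(x), c(2, 3), mean), 4))
  invisible(x)
}
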