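#' Normalize CBV responses across subjects
#'
#' Removes individual differences in overall response amplitude while
#' preserving the group scale: for subject `s`,
#' `S(s, l, theta) = r(s, l, theta) / rnorm(s) * rbar`, where `rnorm(s)`
#' is the root-mean-square of the subject's responses over all layer x
#' condition cells and `rbar` is the group mean of `rnorm`. After
#' normalization every subject's RMS over cells equals `rbar`, and the
#' result is invariant to positive per-subject rescaling of `r`.
#'
#' @param profile A [layer_profile()] (subject x layer x condition
#'   array), or any numeric array with subjects on the first dimension.
#' @return A `normalized_profile` with the same shape; `rnorm` (per
#'   subject) and `rbar` attached as attributes.
#' @export
normalize_responses <- function(profile) {
  arr <- unclass(profile)
  stopifnot(is.array(arr), length(dim(arr)) >= 2)
  n_sub <- dim(arr)[1]
  stopifnot(n_sub >= 1)
  flat <- matrix(arr, nrow = n_sub)
  if (any(!is.finite(flat))) stop("profile contains non-finite responses")
  rnorm_s <- sqrt(rowMeans(flat^2))
  if (any(rnorm_s == 0)) {
    stop("normalization undefined: all-zero response for subject(s) ",
         paste(which(rnorm_s == 0), collapse = ", "))
  }
  rbar <- mean(rnorm_s)
  out <- arr / array(rnorm_s, dim = dim(arr)) * rbar
  structure(out, region = attr(profile, "region"), rnorm = rnorm_s,
            rbar = rbar, class = c("normalized_profile", "array"))
}

#' Saliency-sensitive fMRI response
#'
#' The difference between the (normalized) responses to the 90 degree and
#' 15 degree orientation-contrast foregrounds,
#' `SS(s, l) = S(s, l, 90) - S(s, l, 15)`, computed per subject and
#' layer. Using the 15 degree condition as reference cancels the partial
#' background-suppression component common to both foreground
#' conditions.
#'
#' @param norm A [normalize_responses()] result (or a subject x layer x
#'   condition array with conditions named `"90"` and `"15"`).
#' @return Subject x layer matrix of class `ss_profile`.
#' @export
saliency_sensitive_response <- function(norm) {
  arr <- unclass(norm)
  cn <- dimnames(arr)[[3]]
  stopifnot(all(c("90", "15") %in% cn))
  out <- arr[, , "90", drop = TRUE] - arr[, , "15", drop = TRUE]
  if (is.null(dim(out))) out <- matrix(out, nrow = dim(arr)[1])
  dimnames(out) <- dimnames(arr)[1:2]
  structure(out, region = attr(norm, "region"),
            class = c("ss_profile", "matrix"))
}

#' Layer with the strongest group-mean saliency-sensitive response
#'
#' @param ss An `ss_profile` (subject x layer matrix).
#' @return Layer name at which the group mean SS is maximal.
#' @export
strongest_ss_layer <- function(ss) {
  m <- colMeans(unclass(ss))
  names(m)[which.max(m)]
}
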