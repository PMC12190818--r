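#' Reconstruct visual-field maps from pRF nodes
#'
#' Back-projects per-node responses into visual space: each node
#' contributes its response times an isotropic 2D Gaussian population
#' receptive field (center `x0, y0`, size `sigma`), and contributions are
#' summed over nodes, separately per cortical depth,
#' `map(x, y) = sum_i resp_i * exp(-((x - x0_i)^2 + (y - y0_i)^2) /
#' (2 sigma_i^2))`.
#'
#' @param nodes Data frame with columns `x0`, `y0`, `sigma` (> 0),
#'   `response`, and `depth` (or `layer`) labelling the cortical depth.
#' @param grid List with `x` and `y` lattice vectors (degrees); default
#'   0.1 degree spacing over `[-8, 8] x [-8, 0]` (lower visual field).
#' @param normalize_prf If TRUE each node's Gaussian is scaled to unit
#'   volume; the default keeps unit amplitude.
#' @return A `fieldmap_set`: named list of `length(x) x length(y)`
#'   matrices (one per depth), with the grid attached.
#' @export
reconstruct_fieldmap <- function(nodes,
                                 grid = list(x = seq(-8, 8, 0.1),
                                             y = seq(-8, 0, 0.1)),
                                 normalize_prf = FALSE) {
  stopifnot(is.data.frame(nodes), nrow(nodes) >= 1,
            all(c("x0", "y0", "sigma", "response") %in% names(nodes)))
  if (any(nodes$sigma <= 0)) stop("pRF sizes must be positive")
  depth <- nodes$depth %||% nodes$layer
  if (is.null(depth)) depth <- rep("all", nrow(nodes))
  maps <- lapply(split(seq_len(nrow(nodes)), depth), function(idx) {
    nd <- nodes[idx, , drop = FALSE]
    dx2 <- outer(grid$x, nd$x0, "-")^2          # nx x n
    dy2 <- outer(grid$y, nd$y0, "-")^2          # ny x n
    amp <- nd$response
    if (normalize_prf) amp <- amp / (2 * pi * nd$sigma^2)
    acc <- matrix(0, length(grid$x), length(grid$y))
    for (i in seq_len(nrow(nd))) {
      s2 <- 2 * nd$sigma[i]^2
      acc <- acc + amp[i] * exp(-dx2[, i] / s2) %o% exp(-dy2[, i] / s2)
    }
    acc
  })
  structure(maps, grid = grid, class = "fieldmap_set")
}

#' Normalize field maps across cortical depths
#'
#' Divides every depth's map by the single maximum response across all
#' depths, preserving the between-depth amplitude ordering.
#'
#' @param maps A `fieldmap_set` (one subject).
#' @return A `fieldmap_set` with global maximum 1.
#' @export
normalize_fieldmaps <- function(maps) {
  stopifnot(inherits(maps, "fieldmap_set"))
  gmax <- max(vapply(maps, max, numeric(1)))
  if (!is.finite(gmax) || gmax <= 0) {
    stop("normalization undefined: nonpositive global maximum")
  }
  out <- lapply(maps, function(m) m / gmax)
  attributes(out) <- attributes(maps)
  out
}

#' Group-average normalized field maps
#'
#' Normalizes each subject's maps by their cross-depth maximum, then
#' averages across subjects per depth.
#'
#' @param map_list List of `fieldmap_set`s with identical grids/depths.
#' @return A `fieldmap_set` of group means.
#' @export
group_average_fieldmaps <- function(map_list) {
  stopifnot(length(map_list) >= 1)
  normed <- lapply(map_list, normalize_fieldmaps)
  depths <- names(normed[[1]])
  out <- lapply(depths, function(d) {
    Reduce(`+`, lapply(normed, `[[`, d)) / length(normed)
  })
  names(out) <- depths
  attributes(out) <- attributes(normed[[1]])
  names(out) <- depths
  out
}

#' Peak location of a field map
#'
#' @param map Matrix from a `fieldmap_set`.
#' @param grid Grid list (`x`, `y`) matching the map.
#' @return Named vector `c(x, y)` of the maximum.
#' @export
fieldmap_peak <- function(map, grid) {
  ij <- arrayInd(which.max(map), dim(map))
  c(x = grid$x[ij[1]], y = grid$y[ij[2]])
}

#' Align pRF centers to the localizer peak
#'
#' Translates all node centers by the vector taking the localizer
#' activation peak to the true foreground location, compensating
#' individual differences in atlas-based pRF positions. The transform is
#' a pure translation and is idempotent (a second alignment with the
#' updated peak is the identity).
#'
#' @param nodes Node data frame with `x0`, `y0`.
#' @param localizer_peak `c(x, y)` of the localizer activation peak;
#'   must be finite (a flat localizer has no peak).
#' @param foreground `c(x, y)` of the true foreground center.
#' @return `nodes` with shifted `x0`, `y0`.
#' @export
align_prf_to_localizer <- function(nodes, localizer_peak, foreground) {
  if (any(!is.finite(localizer_peak))) {
    stop("alignment undefined: localizer peak is not defined")
  }
  shift <- c(foreground[1] - localizer_peak[1],
             foreground[2] - localizer_peak[2])
  nodes$x0 <- nodes$x0 + shift[1]
  nodes$y0 <- nodes$y0 + shift[2]
  nodes
}

#' @export
print.fieldmap_set <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("Field maps: depths {%s}, grid %dx%d (%.1f..%.1f, %.1f..%.1f deg)\n",
              paste(names(x), collapse = ", "),
              length(g$x), length(g$y),
              min(g$x), max(g$x), min(g$y), max(g$y)))
  for (d in names(x)) {
    pk <- fieldmap_peak(x[[d]], g)
    cat(sprintf("  %-12s max %.4f at (%+.1f, %+.1f)\n", d, max(x[[d]]),
                pk["x"], pk["y"]))
  }
  invisible(x)
}
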