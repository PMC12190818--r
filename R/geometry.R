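#' Equi-volume laminar boundaries for a curved cortical patch
#'
#' Places laminar boundaries between the white-matter and pial surfaces so
#' that each compartment encloses the requested fraction of cortical
#' volume, compensating for curvature. The cortex is modelled
#' parametrically as an annulus (2D wedge, `model = "annulus"`) or a
#' spherical shell (`model = "shell"`). For the annulus the boundary at
#' cumulative volume fraction `a` is `sqrt(a * pial^2 + (1 - a) * wm^2)`;
#' for the shell the cube-root analogue.
#'
#' In the flat-cortex limit (radii large at fixed thickness) boundaries
#' tend to equidistant depths.
#'
#' @param wm_radius Radius of the white-matter surface (> 0).
#' @param pial_radius Radius of the pial surface (> `wm_radius`).
#' @param fractions Increasing cumulative volume fractions in `[0, 1]`;
#'   defaults to thirds for the deep/middle/superficial compartments.
#' @param model Curvature model, `"annulus"` (default) or `"shell"`.
#' @return Numeric vector of boundary radii, one per fraction.
#' @export
#' @examples
#' equivolume_boundaries(1, 2, c(1/3, 2/3)) # sqrt(2), sqrt(3)
equivolume_boundaries <- function(wm_radius, pial_radius,
                                  fractions = c(1 / 3, 2 / 3),
                                  model = c("annulus", "shell")) {
  model <- match.arg(model)
  if (!(is.finite(wm_radius) && is.finite(pial_radius) &&
        wm_radius > 0 && pial_radius > wm_radius)) {
    stop("invalid geometry: need 0 < wm_radius < pial_radius")
  }
  if (any(fractions < 0 | fractions > 1) || is.unsorted(fractions, strictly = FALSE)) {
    stop("fractions must be nondecreasing and within [0, 1]")
  }
  a <- fractions
  if (model == "annulus") {
    sqrt(a * pial_radius^2 + (1 - a) * wm_radius^2)
  } else {
    (a * pial_radius^3 + (1 - a) * wm_radius^3)^(1 / 3)
  }
}

# Equi-volume depth fraction of radius r (inverse of the boundary map).
equivolume_depth <- function(r, wm_radius, pial_radius, model = "annulus") {
  if (model == "annulus") {
    (r^2 - wm_radius^2) / (pial_radius^2 - wm_radius^2)
  } else {
    (r^3 - wm_radius^3) / (pial_radius^3 - wm_radius^3)
  }
}

#' Synthetic cortical column model on a voxel grid
#'
#' Builds a parametric laminar cortex for the three regions of interest
#' (V1, V2, IPS): each region is an annular wedge of grey matter between a
#' white-matter and a pial radius, divided into equi-volume deep / middle
#' / superficial compartments, intersected with a square voxel grid. Every
#' voxel receives a volume-fraction weight vector over
#' {WM, CSF, deep, middle, superficial} (rows sum to 1), estimated by
#' regular subsampling of the voxel area. A deterministic set of surface
#' vertices with population-receptive-field (pRF) parameters covering the
#' lower visual field is attached for field-map reconstruction.
#'
#' The voxel size starts at a quarter of the cortical thickness and is
#' refined until at least `n_voxels_per_region` voxels contain grey
#' matter, so each region contains voxels dominated by each compartment.
#'
#' @param n_voxels_per_region Minimum number of GM-containing voxels per
#'   region (`>= 3`).
#' @param geometry Optional list overriding `wm_radius`, `pial_radius`,
#'   `wedge_angle` (radians), `subsample` (points per voxel edge for the
#'   area integration), `model` ("annulus"/"shell"),
#'   `n_vertices_per_region`, `foreground_ecc` (deg).
#' @return A `column_model`: list with `voxels` (data frame: region, x, y,
#'   radius, and the five compartment weights `w_WM`, `w_CSF`, `w_deep`,
#'   `w_middle`, `w_superficial`), `vertices` (data frame: region, depth
#'   fraction, layer, x0, y0, sigma), and `geometry`.
#' @export
#' @examples
#' m <- build_column_model(20)
#' range(rowSums(m$voxels[, paste0("w_", c("WM","CSF","deep","middle","superficial"))]))
build_column_model <- function(n_voxels_per_region = 60, geometry = list()) {
  stopifnot(n_voxels_per_region >= 3)
  g <- utils::modifyList(list(wm_radius = 10, pial_radius = 12,
                              wedge_angle = pi / 8, subsample = 10,
                              model = "annulus",
                              n_vertices_per_region = 120,
                              foreground_ecc = 4.3), geometry)
  if (!(g$pial_radius > g$wm_radius && g$wm_radius > 0)) {
    stop("invalid geometry: pial radius must exceed WM radius")
  }
  thickness <- g$pial_radius - g$wm_radius
  bounds <- equivolume_boundaries(g$wm_radius, g$pial_radius,
                                  c(1 / 3, 2 / 3), model = g$model)

  classify <- function(r) {
    # 1 WM, 2 CSF, 3 deep, 4 middle, 5 superficial
    out <- integer(length(r))
    out[r < g$wm_radius] <- 1L
    out[r >= g$pial_radius] <- 2L
    out[r >= g$wm_radius & r < bounds[1]] <- 3L
    out[r >= bounds[1] & r < bounds[2]] <- 4L
    out[r >= bounds[2] & r < g$pial_radius] <- 5L
    out
  }

  voxels_for_size <- function(h) {
    margin <- 0.6 * thickness
    r_lo <- g$wm_radius - margin
    r_hi <- g$pial_radius + margin
    half <- g$wedge_angle / 2
    # bounding box of the wedge (centred on the +x axis)
    xs <- seq(r_lo * cos(half) - h, r_hi + h, by = h)
    ys <- seq(-r_hi * sin(half) - h, r_hi * sin(half) + h, by = h)
    cells <- expand.grid(x = xs, y = ys)
    cr <- sqrt(cells$x^2 + cells$y^2)
    ca <- atan2(cells$y, cells$x)
    keep <- cr >= r_lo & cr <= r_hi & abs(ca) <= half
    cells <- cells[keep, , drop = FALSE]
    if (nrow(cells) == 0) return(NULL)
    s <- g$subsample
    off <- (seq_len(s) - 0.5) / s - 0.5
    sub <- expand.grid(dx = off * h, dy = off * h)
    W <- matrix(0, nrow(cells), 5)
    for (k in seq_len(nrow(sub))) {
      r <- sqrt((cells$x + sub$dx[k])^2 + (cells$y + sub$dy[k])^2)
      cls <- classify(r)
      for (j in 1:5) W[, j] <- W[, j] + (cls == j)
    }
    W <- W / nrow(sub)
    gm <- rowSums(W[, 3:5, drop = FALSE])
    keep <- gm > 0
    list(cells = cells[keep, , drop = FALSE], W = W[keep, , drop = FALSE])
  }

  h <- thickness / 4
  vx <- voxels_for_size(h)
  while (is.null(vx) || nrow(vx$cells) < n_voxels_per_region) {
    h <- h / 1.25
    if (h < thickness / 200) stop("cannot reach requested voxel count")
    vx <- voxels_for_size(h)
  }

  one_region <- function(region) {
    data.frame(region = region,
               x = vx$cells$x, y = vx$cells$y,
               radius = sqrt(vx$cells$x^2 + vx$cells$y^2),
               w_WM = vx$W[, 1], w_CSF = vx$W[, 2],
               w_deep = vx$W[, 3], w_middle = vx$W[, 4],
               w_superficial = vx$W[, 5],
               stringsAsFactors = FALSE)
  }
  voxels <- do.call(rbind, lapply(REGIONS, one_region))
  rownames(voxels) <- NULL

  vertices <- do.call(rbind, lapply(REGIONS, function(region) {
    n <- g$n_vertices_per_region
    nd <- 3L
    nxy <- ceiling(n / nd)
    nxc <- ceiling(sqrt(2 * nxy))
    nyc <- ceiling(nxy / nxc)
    xy <- expand.grid(x0 = seq(-6, 6, length.out = nxc),
                      y0 = seq(-6, -0.3, length.out = nyc))
    xy <- xy[seq_len(min(nxy, nrow(xy))), , drop = FALSE]
    depth <- rep(c(1 / 6, 1 / 2, 5 / 6), each = nrow(xy))
    xy <- xy[rep(seq_len(nrow(xy)), nd), , drop = FALSE]
    ecc <- sqrt(xy$x0^2 + xy$y0^2)
    data.frame(region = region, depth = depth,
               layer = LAYERS[findInterval(depth, c(1 / 3, 2 / 3)) + 1L],
               x0 = xy$x0, y0 = xy$y0,
               sigma = 0.5 + 0.15 * ecc,
               stringsAsFactors = FALSE)
  }))
  rownames(vertices) <- NULL

  structure(list(voxels = voxels, vertices = vertices,
                 geometry = c(g, list(voxel_size = h, boundaries = bounds))),
            class = "column_model")
}

#' Layer-weight matrix of a column model
#'
#' @param model A [build_column_model()] result.
#' @param region Optional region filter.
#' @return Voxel-by-compartment matrix with columns WM, CSF, deep, middle,
#'   superficial; rows sum to 1.
#' @export
layer_weights <- function(model, region = NULL) {
  v <- model$voxels
  if (!is.null(region)) v <- v[v$region %in% region, , drop = FALSE]
  W <- as.matrix(v[, paste0("w_", COMPARTMENTS)])
  colnames(W) <- COMPARTMENTS
  W
}

#' @export
print.column_model <- function(x, ...) {
  cat(sprintf("Column model: %d voxels (%s), %d pRF vertices, voxel %.3g mm\n",
              nrow(x$voxels), paste(unique(x$voxels$region), collapse = "/"),
              nrow(x$vertices), x$geometry$voxel_size))
  cat(sprintf("  WM %.2f / pial %.2f, equi-volume boundaries %.4f, %.4f (%s)\n",
              x$geometry$wm_radius, x$geometry$pial_radius,
              x$geometry$boundaries[1], x$geometry$boundaries[2],
              x$geometry$model))
  invisible(x)
}
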