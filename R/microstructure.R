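# Hole-array opacities on the anterior lens surface: geometry, area
# bookkeeping, and the ray-interaction (block / cone-scatter) model.

#' Specify a hole-array microstructure
#'
#' An N x N array of ~10 um features with center-to-center period P on the
#' anterior lens surface, optionally stacked in L coincident layers.
#'
#' @param array_count N, holes per side (>= 1); e.g. 50 or 100.
#' @param period P, center-to-center spacing in mm (the 0.02-0.07 mm
#'   column of the reference configurations).
#' @param hole_diameter hole diameter in mm (default 0.01 mm = 10 um).
#' @param layers number of stacked layers L (>= 1).
#' @param placement `"periodic"` (centered lattice) or `"random"`
#'   (uniform centers in the footprint, fresh per layer).
#' @param scatter_model `"block"` (hit rays are absorbed, default) or
#'   `"cone"` (hit rays are deflected by a folded-Gaussian polar angle).
#' @param cone_half_angle half-angle sigma of the cone model, degrees.
#' @param seed seed used by random placement.
#' @return object of class `retisim_microspec`.
#' @export
microstructure_spec <- function(array_count, period, hole_diameter = 0.01,
                                layers = 1,
                                placement = c("periodic", "random"),
                                scatter_model = c("block", "cone"),
                                cone_half_angle = 5, seed = 1) {
  placement <- match.arg(placement)
  scatter_model <- match.arg(scatter_model)
  if (array_count < 1 || layers < 1 || period <= 0)
    stop_retisim("need array_count >= 1, layers >= 1, period > 0",
                 "retisim_config_error")
  if (hole_diameter > period)
    stop_retisim("hole_diameter must not exceed the period",
                 "retisim_config_error")
  structure(list(array_count = as.integer(array_count), period = period,
                 hole_diameter = hole_diameter, layers = as.integer(layers),
                 placement = placement, scatter_model = scatter_model,
                 cone_half_angle = cone_half_angle, seed = seed),
            class = "retisim_microspec")
}

#' @export
print.retisim_microspec <- function(x, ...) {
  cat(sprintf("Microstructure: %d x %d holes, period %.3f mm, diameter %.3f mm, %d layer(s), %s placement, %s model\n",
              x$array_count, x$array_count, x$period, x$hole_diameter,
              x$layers, x$placement, x$scatter_model))
  cat(sprintf("  footprint side %.2f mm, distribution area %.2f mm^2\n",
              x$array_count * x$period,
              array_area(x$array_count, x$period, x$layers)))
  invisible(x)
}

#' Distribution area of a hole array
#'
#' `(N * P)^2 * L`: the footprint area of the periodic structure
#' multiplied by the number of layers.
#'
#' @param array_count N, holes per side.
#' @param period P, center spacing (mm).
#' @param layers L, number of layers.
#' @return area in mm^2.
#' @export
#' @examples
#' array_area(100, 0.05, 1)  # 25
#' array_area(50, 0.07, 2)   # 24.5
array_area <- function(array_count, period, layers = 1) {
  stopifnot(array_count >= 1, period > 0, layers >= 1)
  (array_count * period)^2 * layers
}

#' Build the hole-array geometry
#'
#' @param spec a [microstructure_spec()].
#' @param lens_semi_aperture clear semi-aperture of the lens surface the
#'   array sits on (mm); the square footprint of side `N * P` must fit
#'   inside the lens diameter.
#' @return object of class `retisim_microgeom`: `centers` is a list of
#'   per-layer `N^2 x 2` matrices (mm, lens-surface coordinates), plus the
#'   footprint half-side and the spec.
#' @export
build_hole_array <- function(spec, lens_semi_aperture = 5) {
  side <- spec$array_count * spec$period
  if (side > 2 * lens_semi_aperture)
    stop_retisim(sprintf("footprint side %.2f mm exceeds the lens aperture (%.1f mm)",
                         side, 2 * lens_semi_aperture),
                 "retisim_geometry_error")
  N <- spec$array_count; P <- spec$period
  centers <- if (spec$placement == "periodic") {
    ax <- (seq_len(N) - (N + 1) / 2) * P
    lat <- as.matrix(expand.grid(x = ax, y = ax))
    rep(list(lat), spec$layers)
  } else {
    with_seed(spec$seed, lapply(seq_len(spec$layers), function(l)
      cbind(x = runif(N^2, -side / 2, side / 2),
            y = runif(N^2, -side / 2, side / 2))))
  }
  structure(list(spec = spec, centers = centers, half_side = side / 2),
            class = "retisim_microgeom")
}

# TRUE where (x, y) lies inside a hole of one layer.
layer_hit <- function(geom, layer, x, y) {
  sp <- geom$spec
  r2 <- (sp$hole_diameter / 2)^2
  if (sp$placement == "periodic") {
    N <- sp$array_count; P <- sp$period
    kx <- round(x / P + (N + 1) / 2)
    ky <- round(y / P + (N + 1) / 2)
    ok <- kx >= 1 & kx <= N & ky >= 1 & ky <= N
    dx <- x - (kx - (N + 1) / 2) * P
    dy <- y - (ky - (N + 1) / 2) * P
    ok & (dx * dx + dy * dy) <= r2
  } else {
    # period-sized cell hash: compare each point against the centers in
    # its own and the 8 neighboring cells
    cen <- geom$centers[[layer]]
    P <- sp$period
    key <- function(i, j) paste(i, j)
    ci <- floor(cen[, 1] / P); cj <- floor(cen[, 2] / P)
    buckets <- split(seq_len(nrow(cen)), key(ci, cj))
    pi <- floor(x / P); pj <- floor(y / P)
    hit <- logical(length(x))
    for (di in -1:1) for (dj in -1:1) {
      kk <- key(pi + di, pj + dj)
      have <- kk %in% names(buckets)
      if (!any(have)) next
      idxs <- which(have & !hit)
      for (q in idxs) {
        cand <- buckets[[kk[q]]]
        d2 <- (cen[cand, 1] - x[q])^2 + (cen[cand, 2] - y[q])^2
        if (any(d2 <= r2)) hit[q] <- TRUE
      }
    }
    hit
  }
}

#' Microstructure interaction for rays hitting the lens anterior surface
#'
#' Vectorized over rays. A hit outside every hole disc passes unchanged.
#' Inside a disc: block mode absorbs the ray; cone mode perturbs its
#' direction by a folded-Gaussian polar angle (sigma = `cone_half_angle`)
#' with uniform azimuth, renormalized to unit length. The test is repeated
#' independently for each layer.
#'
#' @param geom a [build_hole_array()] geometry.
#' @param x,y hit coordinates on the lens surface (mm).
#' @param dirs n x 3 matrix of unit ray directions.
#' @return list with `status` (`"pass"`, `"absorbed"`, `"deflected"`),
#'   `dirs` (perturbed directions in cone mode) and `hits` (number of
#'   layers whose discs the ray fell inside).
#' @export
microstructure_interact <- function(geom, x, y, dirs) {
  sp <- geom$spec
  n <- length(x)
  hits <- integer(n)
  for (layer in seq_len(sp$layers))
    hits <- hits + layer_hit(geom, layer, x, y)
  status <- rep("pass", n)
  if (sp$scatter_model == "block") {
    status[hits > 0] <- "absorbed"
  } else {
    status[hits > 0] <- "deflected"
    sigma <- sp$cone_half_angle * pi / 180
    for (h in seq_len(max(c(hits, 0)))) {  # one perturbation per layer hit
      idx <- which(hits >= h)
      if (length(idx))
        dirs[idx, ] <- perturb_cone(dirs[idx, , drop = FALSE], sigma)
    }
  }
  list(status = status, dirs = dirs, hits = hits)
}

# Deflect unit vectors by |N(0, sigma)| polar angle, uniform azimuth.
# Caller controls the RNG stream.
perturb_cone <- function(dirs, sigma) {
  n <- nrow(dirs)
  if (n == 0) return(dirs)
  theta <- abs(stats::rnorm(n, 0, sigma))
  phi <- stats::runif(n, 0, 2 * pi)
  # orthonormal basis around each direction
  d <- dirs
  helper <- cbind(ifelse(abs(d[, 1]) < 0.9, 1, 0),
                  ifelse(abs(d[, 1]) < 0.9, 0, 1), 0)
  e1 <- cross3(d, helper)
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cross3(d, e1)
  out <- cos(theta) * d +
    sin(theta) * (cos(phi) * e1 + sin(phi) * e2)
  out / sqrt(rowSums(out^2))
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Hole coverage fraction within the footprint
#'
#' `N^2 * (pi/4) * hole_diameter^2 / (N * P)^2`, the expected fraction of
#' footprint area occupied by holes (single layer, no overlap).
#'
#' @param spec a [microstructure_spec()].
#' @return fraction in `[0, 1]`.
#' @export
hole_coverage <- function(spec) {
  f <- (pi / 4) * (spec$hole_diameter / spec$period)^2
  min(f, 1)
}
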