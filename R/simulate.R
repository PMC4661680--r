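# Retinal irradiance maps: binned landed flux plus exact power accounting.

#' Simulate the retinal irradiance map
#'
#' Launches one ray per source sample, aimed at a uniformly sampled point
#' of the paraxial entrance pupil (importance sampling into the cone
#' subtending the pupil), traces it through the eye and bins the landed
#' power on the retina. Power accounting is exact: launched = landed +
#' vignetted + absorbed; rays crossing the retina outside the map window
#' are counted as vignetted, so the bin sum equals the landed power.
#'
#' @param eye a `retisim_eye`.
#' @param source a [sample_source()] result.
#' @param seed integer seed for pupil sampling (and scatter, if any).
#' @param micro optional [build_hole_array()] geometry on the lens
#'   anterior surface.
#' @param n_bins bins per side of the square retinal window (default 256).
#' @param window half-size of the window (mm); default covers the paraxial
#'   image of the whole chart plus a 20% margin.
#' @return object of class `retisim_irradiance`: `grid` (n_bins x n_bins
#'   flux matrix), `window`, `bin_size`, `totals` (launched, landed,
#'   vignetted, absorbed, landed_count, n_rays), `magnification`, `seed`.
#' @export
simulate_image <- function(eye, source, seed = 1, micro = NULL,
                           n_bins = 256, window = NULL) {
  ep <- entrance_pupil(eye)
  m <- chief_magnification(eye, source$z)
  if (is.null(window)) {
    half_obj <- max(abs(unlist(chart_extent_halves(source))))
    window <- 1.2 * abs(m) * half_obj
  }
  n <- nrow(source$points)
  pup <- with_seed(seed, {
    r <- ep$semi * sqrt(stats::runif(n))
    a <- stats::runif(n, 0, 2 * pi)
    list(x = r * cos(a), y = r * sin(a),
         scatter_seed = stats::runif(1))   # reserve a draw for scatter
  })
  origins <- cbind(source$points[, 1], source$points[, 2], source$z)
  d <- cbind(pup$x - origins[, 1], pup$y - origins[, 2], ep$z - origins[, 3])
  dirs <- d / sqrt(rowSums(d * d))
  tb <- with_seed(derive_seed(seed, 1L),   # scatter-model stream
                  trace_block(eye, origins, dirs, micro))
  w <- source$power_per_point
  launched <- w * n
  inwin <- abs(tb$retina_x) <= window & abs(tb$retina_y) <= window
  status <- tb$status
  status[tb$landed_idx[!inwin]] <- 1L      # out of window -> vignetted
  landed_idx <- tb$landed_idx[inwin]
  rx <- tb$retina_x[inwin]; ry <- tb$retina_y[inwin]
  bin_size <- 2 * window / n_bins
  ix <- pmin(pmax(floor((rx + window) / bin_size) + 1, 1), n_bins)
  iy <- pmin(pmax(floor((ry + window) / bin_size) + 1, 1), n_bins)
  grid <- matrix(0, n_bins, n_bins)
  if (length(ix)) {
    acc <- rowsum(rep(w, length(ix)), group = (iy - 1L) * n_bins + ix)
    grid[as.integer(rownames(acc))] <- acc[, 1]
  }
  totals <- list(launched = launched,
                 landed = w * length(landed_idx),
                 vignetted = w * sum(status == 1L),
                 absorbed = w * sum(status == 2L),
                 landed_count = length(landed_idx),
                 n_rays = n)
  structure(list(grid = grid, window = window, bin_size = bin_size,
                 n_bins = n_bins, totals = totals, magnification = m,
                 seed = seed, region = source$region %||% NA,
                 power_per_ray = w),
            class = "retisim_irradiance")
}

# object-space half extents implied by the source's chart (carried along
# so the window covers the whole-chart image regardless of masking)
chart_extent_halves <- function(source) {
  ex <- attr(source, "chart_extent")
  if (!is.null(ex)) return(ex)
  list(x = max(abs(source$points[, 1])) * 1.05,
       y = max(abs(source$points[, 2])) * 1.05)
}

#' @export
print.retisim_irradiance <- function(x, ...) {
  t <- x$totals
  cat(sprintf("Irradiance map %dx%d over +/-%.3f mm (bin %.4f mm)\n",
              x$n_bins, x$n_bins, x$window, x$bin_size))
  cat(sprintf("  launched %.4g | landed %.4g | vignetted %.4g | absorbed %.4g\n",
              t$launched, t$landed, t$vignetted, t$absorbed))
  invisible(x)
}

#' Retinal region of interest from a chart region
#'
#' The paraxial image of the region's bounding box: the chief-ray
#' magnification of the given eye maps chart coordinates onto the retina
#' (the image is inverted; the box is re-sorted).
#'
#' @param eye a `retisim_eye`.
#' @param chart a rendered `retisim_chart` (whole chart).
#' @param region region name or object from [chart_regions()].
#' @param padding passed to [chart_regions()].
#' @return list with `x` and `y` ranges (mm on the retina) and `name`.
#' @export
retinal_roi <- function(eye, chart, region = "whole", padding = 0.1) {
  if (is.character(region)) {
    regs <- chart_regions(chart, padding)
    if (!region %in% names(regs))
      stop_retisim(sprintf("unknown region '%s'", region),
                   "retisim_region_error")
    region <- regs[[region]]
  }
  m <- chief_magnification(eye, -chart$spec$distance)
  bb <- region$bbox
  list(x = sort(m * c(bb[["x0"]], bb[["x1"]])),
       y = sort(m * c(bb[["y0"]], bb[["y1"]])),
       name = region$name)
}

#' Total flux over a retinal region of interest
#'
#' Sums the bins whose centers fall inside the ROI rectangle (or union of
#' rectangles).
#'
#' @param map a `retisim_irradiance`.
#' @param roi a [retinal_roi()] rectangle, a list of them, or `NULL` for
#'   the full window.
#' @return flux in source units.
#' @export
total_flux <- function(map, roi = NULL) {
  if (is.null(roi)) return(sum(map$grid))
  if (!is.null(roi$x)) roi <- list(roi)
  centers <- -map$window + (seq_len(map$n_bins) - 0.5) * map$bin_size
  inside <- matrix(FALSE, map$n_bins, map$n_bins)
  for (rc in roi) {
    cx <- centers >= rc$x[1] & centers <= rc$x[2]
    cy <- centers >= rc$y[1] & centers <= rc$y[2]
    inside <- inside | outer(cx, cy, `&`)
  }
  sum(map$grid[inside])
}

#' Rasterized view of an irradiance map
#'
#' @param x a `retisim_irradiance`.
#' @param normalize divide by the peak bin (for display).
#' @param ... unused.
#' @return numeric matrix, row 1 = top of the retinal window.
#' @export
as.matrix.retisim_irradiance <- function(x, normalize = FALSE, ...) {
  m <- t(x$grid)[rev(seq_len(x$n_bins)), , drop = FALSE]
  if (normalize && max(m) > 0) m <- m / max(m)
  m
}
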