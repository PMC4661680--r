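# Flux-vs-diopter calibration and equivalent-myopia prediction.

#' Build the flux-vs-diopter calibration curve
#'
#' For each grid diopter the eye is elongated axially, the (possibly
#' region-masked) chart is re-sampled on an independent substream of the
#' master seed, one irradiance map is simulated, and the flux over the
#' region's retinal image is integrated. Fluxes are normalized to 1 at
#' plano. For the whole chart the curve must be strictly decreasing
#' (otherwise it is not invertible and an error is raised); sub-region
#' curves may be perturbed by stray light and are only flagged.
#'
#' @param eye a plano `retisim_eye`.
#' @param chart a rendered whole `retisim_chart`.
#' @param region region name (default `"whole"`).
#' @param diopters myopia grid, starting at 0 (default `0:10`).
#' @param n_rays rays per grid point (>= 1e4; default 2e5).
#' @param seed master seed; each grid point uses a derived substream.
#' @param stray_light if `TRUE`, keep the whole chart lit and integrate
#'   only the sub-region ROI (light from neighboring letters can then
#'   stray into the region, the mechanism behind non-monotone sub-region
#'   curves); if `FALSE` (default) the source is masked to the region, as
#'   in region-wise imaging.
#' @param n_bins,padding forwarded to the simulator / region table.
#' @return object of class `retisim_calibration` with fields `diopters`,
#'   `flux`, `normalized_flux`, `invertible`, `region`, `metadata`.
#' @export
build_calibration <- function(eye, chart, region = "whole",
                              diopters = 0:10, n_rays = 2e5, seed = 1,
                              stray_light = FALSE, n_bins = 256,
                              padding = 0.1) {
  diopters <- as.numeric(diopters)
  if (diopters[1] != 0 || is.unsorted(diopters, strictly = TRUE))
    stop_retisim("diopter grid must start at 0 and increase strictly",
                 "retisim_config_error")
  if (n_rays < 1e4)
    stop_retisim("calibration needs n_rays >= 1e4", "retisim_config_error")
  if (eye$myopia != 0)
    stop_retisim("calibration must start from a plano eye",
                 "retisim_config_error")
  masked <- if (stray_light) chart else select_region(chart, region, padding)
  flux <- se <- numeric(length(diopters))
  for (i in seq_along(diopters)) {
    eye_d <- induce_myopia(eye, diopters[i])
    src <- sample_source(masked, n_rays, seed = derive_seed(seed, 10L + i))
    map <- simulate_image(eye_d, src, seed = derive_seed(seed, 40L + i),
                          n_bins = n_bins)
    roi <- retinal_roi(eye_d, chart, region, padding)
    flux[i] <- total_flux(map, roi)
    se[i] <- flux_se(map)
  }
  normalized <- flux / flux[1]
  drops <- diff(normalized)
  monotone <- all(drops < 0)
  if (!monotone) {
    if (region == "whole")
      stop_retisim("whole-chart calibration curve is non-monotone at this budget",
                   "retisim_nonmonotone_error")
    warning(sprintf(
      "calibration curve for region '%s' is non-monotone (stray light); not invertible",
      region), call. = FALSE)
  }
  structure(list(diopters = diopters, flux = flux,
                 normalized_flux = normalized,
                 flux_se = se, invertible = monotone, region = region,
                 metadata = list(seed = seed, n_rays = n_rays,
                                 n_bins = n_bins, preset = eye$preset,
                                 pupil_diameter = 2 * eye$stop$semi,
                                 chart_distance = chart$spec$distance,
                                 stray_light = stray_light,
                                 version = retisim_version())),
            class = "retisim_calibration")
}

# Monte-Carlo standard error of a map's landed flux (equal-weight rays:
# flux = w * K with K ~ Binomial(n, p)).
flux_se <- function(map) {
  n <- map$totals$n_rays
  k <- map$totals$landed_count
  p <- k / n
  map$power_per_ray * sqrt(n * p * (1 - p))
}

#' @export
print.retisim_calibration <- function(x, ...) {
  cat(sprintf("Calibration curve, region '%s', %s\n", x$region,
              if (x$invertible) "invertible" else "NON-MONOTONE (not invertible)"))
  print(data.frame(diopters = x$diopters,
                   normalized_flux = round(x$normalized_flux, 4)))
  invisible(x)
}

#' Invert the calibration curve: flux -> equivalent myopia
#'
#' Monotone piecewise-linear interpolation of the inverse map, exact at
#' the grid nodes (`flux = 1` maps to 0 D).
#'
#' @param curve an invertible `retisim_calibration`.
#' @param flux_normalized normalized flux value(s) in
#'   `[min(curve), 1]`.
#' @return equivalent myopia in diopters.
#' @export
equivalent_myopia <- function(curve, flux_normalized) {
  if (!inherits(curve, "retisim_calibration"))
    stop_retisim("not a calibration curve", "retisim_config_error")
  if (!curve$invertible)
    stop_retisim("curve is non-monotone and cannot be inverted",
                 "retisim_noninvertible_error")
  lo <- min(curve$normalized_flux)
  if (any(flux_normalized > 1 | flux_normalized < lo))
    stop_retisim(sprintf(
      "normalized flux outside the calibration range [%.4f, 1]", lo),
      "retisim_out_of_range_error")
  # invertible => strictly decreasing, so the reversed vectors are sorted
  stats::approx(x = rev(curve$normalized_flux), y = rev(curve$diopters),
                xout = flux_normalized, method = "linear",
                ties = "ordered")$y
}

#' Predict the equivalent myopia of a microstructure configuration
#'
#' Simulates the plano eye with the hole array in place, measures the
#' whole-chart flux normalized by the curve's plano flux, and inverts the
#' calibration curve. A flux deficit smaller than the detection threshold
#' (default 3 Monte-Carlo standard errors of the plano flux) is reported
#' as `indistinguishable`; a deficit beyond the deepest calibrated flux is
#' `out_of_range`.
#'
#' @param object an invertible whole-chart `retisim_calibration`.
#' @param spec a [microstructure_spec()], or `NULL` for an unmodified eye
#'   (the identity case, expected indistinguishable from 0 D).
#' @param eye,chart the same plano eye / chart used for the curve.
#' @param n_rays rays (default the curve's budget).
#' @param seed integer seed.
#' @param detection_k multiple of the plano-flux standard error below
#'   which a deficit is undetectable (default 3).
#' @param padding region padding forwarded to the ROI.
#' @param ... unused.
#' @return object of class `retisim_prediction`: the measured normalized
#'   flux, `equivalent_myopia` (D), `equivalent_myopia_centi` (the
#'   centi-diopter "degree" convention, 100 per diopter), `status`
#'   (`ok` / `indistinguishable` / `out_of_range`) and metadata.
#' @export
predict.retisim_calibration <- function(object, spec, eye, chart,
                                        n_rays = NULL, seed = 1,
                                        detection_k = 3, padding = 0.1,
                                        ...) {
  if (object$region != "whole" || !object$invertible)
    stop_retisim("prediction needs an invertible whole-chart curve",
                 "retisim_config_error")
  if (eye$myopia != 0)
    stop_retisim("prediction simulates the plano eye plus microstructure",
                 "retisim_config_error")
  n_rays <- n_rays %||% object$metadata$n_rays
  geom <- if (is.null(spec)) NULL else
    build_hole_array(spec, lens_semi_aperture = eye$surfaces[[3]]$semi_aperture)
  masked <- select_region(chart, "whole", padding)
  src <- sample_source(masked, n_rays, seed = derive_seed(seed, 3L))
  map <- simulate_image(eye, src, seed = derive_seed(seed, 4L),
                        micro = geom, n_bins = object$metadata$n_bins)
  roi <- retinal_roi(eye, chart, "whole", padding)
  flux <- total_flux(map, roi)
  f_norm <- flux / object$flux[1]
  se_norm <- flux_se(map) / object$flux[1]
  deficit <- 1 - f_norm
  threshold <- detection_k * se_norm
  lo <- min(object$normalized_flux)
  if (deficit <= threshold) {
    status <- "indistinguishable"
    em <- if (f_norm >= 1) 0 else equivalent_myopia(object, f_norm)
  } else if (f_norm < lo) {
    status <- "out_of_range"
    em <- NA_real_
  } else {
    status <- "ok"
    em <- equivalent_myopia(object, min(f_norm, 1))
  }
  structure(list(spec = spec, normalized_flux = f_norm,
                 flux_deficit = deficit, detection_threshold = threshold,
                 equivalent_myopia = em,
                 equivalent_myopia_centi = if (is.na(em)) NA_real_ else 100 * em,
                 status = status,
                 scatter_model = if (is.null(spec)) "none" else spec$scatter_model,
                 metadata = list(seed = seed, n_rays = n_rays,
                                 curve_seed = object$metadata$seed,
                                 version = retisim_version())),
            class = "retisim_prediction")
}

#' @export
print.retisim_prediction <- function(x, ...) {
  cat(sprintf("Equivalent-myopia prediction (%s model): status %s\n",
              x$scatter_model, x$status))
  cat(sprintf("  normalized flux %.4f (deficit %.4f, threshold %.4f)\n",
              x$normalized_flux, x$flux_deficit, x$detection_threshold))
  if (!is.na(x$equivalent_myopia))
    cat(sprintf("  equivalent myopia %.2f D (%.0f centi-diopter degrees)\n",
                x$equivalent_myopia, x$equivalent_myopia_centi))
  invisible(x)
}

retisim_version <- function() {
  as.character(utils::packageVersion("retisim"))
}
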