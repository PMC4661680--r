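# Schematic eye: geometry, paraxial solves, refractive-error induction.

#' Create an optical surface
#'
#' A spherical (or flat) refracting interface of the schematic eye.
#'
#' @param vertex_z axial vertex position (mm, increasing toward the retina).
#' @param radius signed radius of curvature (mm). Positive when the center
#'   of curvature lies toward the retina; `0` or `Inf` means flat.
#' @param semi_aperture clear semi-aperture (mm, > 0).
#' @param n_after refractive index of the medium following the surface
#'   (>= 1).
#' @param name optional label.
#' @return an object of class `retisim_surface`.
#' @export
optical_surface <- function(vertex_z, radius, semi_aperture, n_after,
                            name = "") {
  if (!is.finite(vertex_z) || semi_aperture <= 0 || n_after < 1)
    stop_retisim("invalid surface parameters (need semi_aperture > 0, n_after >= 1)",
                 "retisim_geometry_error")
  if (radius == 0) radius <- Inf   # 0 is the flat sentinel
  structure(list(vertex_z = vertex_z, radius = radius,
                 semi_aperture = semi_aperture, n_after = n_after,
                 name = name),
            class = "retisim_surface")
}

# Le Grand full theoretical eye (relaxed), four refracting surfaces.
# Corneal center thickness 0.55 mm, corneal diameter 11.5 mm, lens
# diameter 10 mm. The stop (iris) sits just ahead of the lens.
legrand_surfaces <- function() {
  list(
    optical_surface(0.00,  7.8, 5.75, 1.3771, "cornea anterior"),
    optical_surface(0.55,  6.5, 5.75, 1.3374, "cornea posterior"),
    optical_surface(3.60, 10.2, 5.00, 1.4200, "lens anterior"),
    optical_surface(7.60, -6.0, 5.00, 1.3360, "lens posterior"))
}

eye_presets <- function() list(legrand = legrand_surfaces)

#' Build a schematic eye
#'
#' Assembles the four-surface schematic eye, places the retina at the
#' solved paraxial focus (emmetropia by construction), and validates the
#' geometry.
#'
#' @param config either a preset name (currently `"legrand"`) or a list
#'   with any of: `preset`, `surfaces` (list of [optical_surface()]),
#'   `pupil_diameter` (mm, default 4), `stop_z` (mm, default 0.05 mm ahead
#'   of the lens anterior vertex), `emmetropize_at` (object distance in mm
#'   used to define emmetropia; default `Inf`, i.e. parallel rays focused
#'   on the retina).
#' @return an object of class `retisim_eye`.
#' @export
#' @examples
#' eye <- build_schematic_eye("legrand")
#' eye_power(eye)   # ~ 59.9 D
build_schematic_eye <- function(config = "legrand") {
  if (is.character(config)) config <- list(preset = config)
  stopifnot(is.list(config))
  preset <- config$preset %||% "legrand"
  presets <- eye_presets()
  if (is.null(config$surfaces)) {
    if (!preset %in% names(presets))
      stop_retisim(sprintf("unknown eye preset '%s'", preset),
                   "retisim_config_error")
    surfaces <- presets[[preset]]()
  } else surfaces <- config$surfaces

  zs <- vapply(surfaces, `[[`, 0, "vertex_z")
  if (any(diff(zs) <= 0))
    stop_retisim("surface vertices must be strictly increasing in z",
                 "retisim_geometry_error")

  pupil_diameter <- config$pupil_diameter %||% 4
  stop_z <- config$stop_z %||% (zs[3] - 0.05)
  if (stop_z <= zs[2] || stop_z >= zs[3])
    stop_retisim("pupil stop must lie between cornea posterior and lens anterior",
                 "retisim_geometry_error")

  eye <- structure(list(
    surfaces = surfaces,
    stop = list(z = stop_z, semi = pupil_diameter / 2),
    retina_z = NA_real_,
    retina_radius = config$retina_radius %||% Inf,   # flat detector default
    myopia = 0,
    preset = preset,
    emmetropize_at = config$emmetropize_at %||% Inf
  ), class = "retisim_eye")

  v0 <- object_vergence_at_cornea(eye$emmetropize_at)
  eye$retina_z <- paraxial_trace_core(eye, v0)$image_z
  if (!is.finite(eye$retina_z) || eye$retina_z <= zs[length(zs)])
    stop_retisim("retina would lie inside the lens; geometry invalid",
                 "retisim_geometry_error")
  eye
}

# vergence (D) at the cornea of an axial object `dist_mm` in front of it
object_vergence_at_cornea <- function(dist_mm) {
  if (is.infinite(dist_mm)) 0 else -1000 / dist_mm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.retisim_eye <- function(x, ...) {
  cat(sprintf("Schematic eye (preset '%s')\n", x$preset))
  for (s in x$surfaces)
    cat(sprintf("  %-16s z=%7.3f mm  R=%8.3f mm  semi=%5.2f mm  n'=%6.4f\n",
                s$name, s$vertex_z, s$radius, s$semi_aperture, s$n_after))
  cat(sprintf("  pupil stop       z=%7.3f mm  semi=%.2f mm\n",
              x$stop$z, x$stop$semi))
  cat(sprintf("  retina           z=%7.3f mm (flat)   induced myopia %.2f D\n",
              x$retina_z, x$myopia))
  invisible(x)
}

surface_powers <- function(eye) {
  n_before <- c(1, vapply(eye$surfaces, `[[`, 0, "n_after"))
  vapply(seq_along(eye$surfaces), function(i) {
    s <- eye$surfaces[[i]]
    if (is.infinite(s$radius)) 0 else
      1000 * (s$n_after - n_before[i]) / s$radius
  }, 0)
}

# Reduced-vergence trace through all surfaces. Returns the vergence after
# the last surface, the image-plane z, and the image-plane transverse
# magnification (product of V/V' over the refractions).
paraxial_trace_core <- function(eye, object_vergence) {
  P <- surface_powers(eye)
  zs <- vapply(eye$surfaces, `[[`, 0, "vertex_z")
  ns <- vapply(eye$surfaces, `[[`, 0, "n_after")
  V <- object_vergence
  mag <- 1
  for (i in seq_along(P)) {
    V2 <- V + P[i]
    if (V2 != 0) mag <- mag * V / V2
    V <- V2
    if (i < length(P)) {
      t_m <- (zs[i + 1] - zs[i]) / 1000
      V <- V / (1 - t_m * V / ns[i])
    }
  }
  n_last <- ns[length(ns)]
  image_z <- if (V == 0) Inf else zs[length(zs)] + 1000 * n_last / V
  list(vergence_exit = V, image_z = image_z, magnification = mag,
       n_image = n_last)
}

# Paraxial y-nu (reduced angle) trace. Returns per-gap segments so ray
# height can be evaluated at any plane: y(z) = y_i + (z - z_i) * w_i / n_i.
ynu_segments <- function(eye, y0, w0) {
  P <- surface_powers(eye)
  zs <- vapply(eye$surfaces, `[[`, 0, "vertex_z")
  ns <- vapply(eye$surfaces, `[[`, 0, "n_after")
  y <- y0; w <- w0
  seg <- matrix(NA_real_, nrow = length(P), ncol = 4,
                dimnames = list(NULL, c("z", "y", "w", "n")))
  for (i in seq_along(P)) {
    w <- w - y * P[i] / 1000          # refraction, reduced angle n*u
    seg[i, ] <- c(zs[i], y, w, ns[i])
    if (i < length(P)) y <- y + (zs[i + 1] - zs[i]) * w / ns[i]
  }
  seg
}

ynu_height_at <- function(seg, z) {
  i <- max(which(seg[, "z"] <= z))
  unname(seg[i, "y"] + (z - seg[i, "z"]) * seg[i, "w"] / seg[i, "n"])
}

#' Paraxial trace of an axial object through the eye
#'
#' Propagates reduced vergence surface by surface (`P = (n2 - n1)/R` at
#' each interface) and reports the axial image position together with the
#' paraxial ray state at the retina.
#'
#' @param eye a `retisim_eye`.
#' @param object_vergence vergence (D) of the axial object measured at the
#'   cornea (0 = infinity, negative = real object in front of the eye).
#' @return list with `image_z` (mm), `magnification` (image plane), and
#'   `state`: the paraxial ray state at the retina of a marginal ray of
#'   unit height at the cornea — fields `height` (mm), `angle` (reduced
#'   n*u) and `vergence` (D at the retina plane; `Inf` when the image
#'   coincides with the retina).
#' @export
paraxial_trace <- function(eye, object_vergence = 0) {
  stopifnot(is.finite(object_vergence))
  core <- paraxial_trace_core(eye, object_vergence)
  # marginal ray of unit height at the cornea: physical slope is
  # -V0/1000 per mm of height (object vergence V0 = 1000 n0 / l)
  seg <- ynu_segments(eye, 1, -object_vergence / 1000)
  last <- nrow(seg)
  dz_m <- (eye$retina_z - core$image_z)
  # vergence at the retina plane (propagate exit vergence to retina_z)
  zlast <- seg[last, "z"]
  Vex <- core$vergence_exit
  denom <- 1 - (eye$retina_z - zlast) / 1000 * Vex / core$n_image
  vergence_ret <- if (abs(denom) < 1e-300) Inf else Vex / denom
  list(image_z = core$image_z,
       magnification = core$magnification,
       state = list(height = ynu_height_at(seg, eye$retina_z),
                    angle = unname(seg[last, "w"]),
                    vergence = vergence_ret))
}

#' Total paraxial (equivalent) power of the eye
#'
#' @param eye a `retisim_eye`.
#' @return equivalent power in diopters, computed from a unit-height
#'   parallel ray: `P = -1000 * w' / y`.
#' @export
eye_power <- function(eye) {
  seg <- ynu_segments(eye, 1, 0)
  unname(-1000 * seg[nrow(seg), "w"])
}

#' Far point of the eye
#'
#' Solves for the object vergence conjugate to the retina.
#'
#' @param eye a `retisim_eye`.
#' @return list with `vergence` (D at the cornea), `diopters`
#'   (`-vergence`; the magnitude of myopia) and `distance_mm` (signed
#'   object distance, negative in front of the eye).
#' @export
far_point <- function(eye) {
  f <- function(v) paraxial_trace_core(eye, v)$image_z - eye$retina_z
  grid <- seq(-45, 20, by = 0.5)
  vals <- vapply(grid, f, 0)
  ok <- is.finite(vals)
  sc <- which(ok[-1] & ok[-length(ok)] &
                sign(vals[-1]) * sign(vals[-length(vals)]) <= 0)
  if (!length(sc))
    stop_retisim("no far point in [-45, 20] D", "retisim_geometry_error")
  v <- uniroot(f, c(grid[sc[1]], grid[sc[1] + 1]), tol = 1e-12)$root
  list(vergence = v, diopters = -v,
       distance_mm = if (v == 0) -Inf else 1000 / v)
}

#' Induce a prescribed myopic refractive error
#'
#' Default mechanism is axial elongation: the retina is moved back until
#' the far point sits at `1/diopters` meters in front of the cornea; all
#' refracting surfaces are untouched. The alternative `"lens"` mechanism
#' steepens the posterior lens surface instead, with the retina fixed.
#'
#' @param eye a `retisim_eye`.
#' @param diopters magnitude of myopia, in `[0, 15]` D. `0` returns the
#'   eye unchanged.
#' @param method `"axial"` (default) or `"lens"`.
#' @return a `retisim_eye` whose far point is at `1/diopters` m.
#' @export
induce_myopia <- function(eye, diopters, method = c("axial", "lens")) {
  method <- match.arg(method)
  if (!is.finite(diopters) || diopters < 0 || diopters > 15)
    stop_retisim("myopia must be in [0, 15] D", "retisim_range_error")
  if (diopters == 0) return(eye)
  if (method == "axial") {
    eye$retina_z <- paraxial_trace_core(eye, -diopters)$image_z
  } else {
    target <- function(R4) {
      e2 <- eye
      e2$surfaces[[4]]$radius <- R4
      far_point(e2)$diopters - diopters
    }
    eye$surfaces[[4]]$radius <-
      uniroot(target, c(-5.999, -3), tol = 1e-10)$root
  }
  eye$myopia <- diopters
  eye
}

# Entrance pupil: paraxial image of the stop through the corneal surfaces,
# traced leftward (mirrored system: radii negated, indices swapped).
entrance_pupil <- function(eye) {
  zs <- vapply(eye$surfaces, `[[`, 0, "vertex_z")
  left <- which(zs < eye$stop$z)
  n_before <- c(1, vapply(eye$surfaces, `[[`, 0, "n_after"))
  ord <- rev(left)                       # traverse toward the cornea
  n_obj <- eye$surfaces[[max(left)]]$n_after
  t0 <- eye$stop$z - zs[ord[1]]
  V <- 1000 * n_obj / (-t0)              # reduced vergence, mirrored frame
  mag <- 1
  for (k in seq_along(ord)) {
    i <- ord[k]
    s <- eye$surfaces[[i]]
    n_in <- s$n_after                    # right of surface = incident side
    n_out <- n_before[i]
    P <- if (is.infinite(s$radius)) 0 else 1000 * (n_out - n_in) / (-s$radius)
    V2 <- V + P
    mag <- mag * V / V2
    V <- V2
    if (k < length(ord)) {
      t_m <- (zs[i] - zs[ord[k + 1]]) / 1000
      V <- V / (1 - t_m * V / n_out)
    }
  }
  l2 <- 1000 * 1 / V                     # image distance, mirrored frame
  zpp <- zs[ord[length(ord)]]            # cornea anterior = mirrored origin
  # mirrored z'' of the image is (stop_z - z_cornea) + l2; map back to the
  # real frame with z = stop_z - z''
  z_real <- eye$stop$z - ((eye$stop$z - zpp) + l2)
  list(z = z_real, semi = eye$stop$semi * abs(mag), mag = mag)
}

# Chief-ray magnification onto the retina for an axial-field object plane
# at z_obj (mm, negative): y_retina / h for the ray through the stop center.
chief_magnification <- function(eye, z_obj) {
  h <- 1
  z1 <- eye$surfaces[[1]]$vertex_z
  ray <- function(y1, h) {
    u0 <- (y1 - h) / (z1 - z_obj)
    ynu_segments(eye, y1, u0)            # object in air: w = u
  }
  ystop <- function(y1, h) ynu_height_at(ray(y1, h), eye$stop$z)
  a0 <- ystop(0, h); a1 <- ystop(1, h)
  y1_star <- -a0 / (a1 - a0)
  seg <- ray(y1_star, h)
  ynu_height_at(seg, eye$retina_z) / h
}

# Paraxial blur radius on the retina for an axial point at z_obj: height at
# the retina of the marginal ray grazing the stop edge.
paraxial_blur_radius <- function(eye, z_obj) {
  z1 <- eye$surfaces[[1]]$vertex_z
  ray <- function(y1) ynu_segments(eye, y1, y1 / (z1 - z_obj))
  ys <- ynu_height_at(ray(1), eye$stop$z)
  seg <- ray(eye$stop$semi / ys)
  abs(ynu_height_at(seg, eye$retina_z))
}
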