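# Monte-Carlo sequential ray tracing: vector Snell refraction, sphere
# intersection, surface-by-surface propagation to the retina.

#' Vector Snell refraction
#'
#' @param direction unit propagation vector (length-3, or n x 3 matrix).
#' @param normal unit surface normal (matching shape). Orientation is
#'   normalized internally so the normal opposes the incident direction.
#' @param n1,n2 refractive indices before/after the surface (>= 1).
#' @return for a single vector: the refracted unit vector, or `NULL` on
#'   total internal reflection. For matrices: `list(dirs, tir)` where
#'   `tir` flags totally internally reflected rays (their directions are
#'   left untouched; callers mark them absorbed).
#' @export
refract <- function(direction, normal, n1, n2) {
  single <- is.null(dim(direction))
  D <- if (single) matrix(direction, 1) else direction
  if (nrow(D) == 0)
    return(list(dirs = D, tir = logical(0)))
  N <- if (is.null(dim(normal))) matrix(normal, nrow(D), 3, byrow = TRUE)
       else normal
  # flip normals to oppose the incident ray
  ci <- rowSums(D * N)
  N[ci > 0, ] <- -N[ci > 0, , drop = FALSE]
  ci <- -rowSums(D * N)                  # cos(theta_i) > 0
  eta <- n1 / n2
  k <- 1 - eta^2 * (1 - ci^2)
  tir <- k < 0
  ct <- sqrt(pmax(k, 0))
  out <- eta * D + (eta * ci - ct) * N
  out <- out / sqrt(rowSums(out^2))
  if (single) {
    if (tir[1]) return(NULL)
    return(out[1, ])
  }
  list(dirs = out, tir = tir)
}

#' Intersect rays with a spherical or flat surface
#'
#' Nearest forward intersection with the surface cap; hits beyond the
#' semi-aperture are misses (callers mark those rays vignetted).
#'
#' @param origins n x 3 matrix of ray origins (mm).
#' @param dirs n x 3 matrix of unit directions (travelling toward +z).
#' @param surface a `retisim_surface`.
#' @return list with `points` (n x 3 hit coordinates, NA on miss), `t`
#'   (path parameter) and `miss` (logical).
#' @export
intersect_surface <- function(origins, dirs, surface) {
  n <- nrow(origins)
  v <- surface$vertex_z
  if (is.infinite(surface$radius)) {
    t <- (v - origins[, 3]) / dirs[, 3]
  } else {
    R <- surface$radius
    cz <- v + R                           # center of curvature on the axis
    oc <- origins - matrix(c(0, 0, cz), n, 3, byrow = TRUE)
    b <- rowSums(oc * dirs)               # |d| = 1
    cc <- rowSums(oc * oc) - R^2
    disc <- b * b - cc
    s <- sqrt(pmax(disc, 0))
    t1 <- -b - s
    t2 <- -b + s
    # the cap near the vertex: pick the root whose hit point lies on the
    # vertex side of the center (z < cz for R > 0, z > cz for R < 0)
    z1 <- origins[, 3] + t1 * dirs[, 3]
    z2 <- origins[, 3] + t2 * dirs[, 3]
    on_cap1 <- if (R > 0) z1 < cz else z1 > cz
    t <- ifelse(on_cap1 & t1 > 1e-9, t1, t2)
    t[disc < 0] <- NA_real_
  }
  t[!is.na(t) & t <= 1e-9] <- NA_real_
  pts <- origins + t * dirs
  r2 <- pts[, 1]^2 + pts[, 2]^2
  miss <- is.na(t) | r2 > surface$semi_aperture^2
  pts[miss, ] <- NA_real_
  list(points = pts, t = t, miss = miss)
}

surface_normals <- function(points, surface) {
  if (is.infinite(surface$radius))
    return(matrix(rep(c(0, 0, -1), each = nrow(points)), ncol = 3))
  cz <- surface$vertex_z + surface$radius
  nrm <- points - matrix(c(0, 0, cz), nrow(points), 3, byrow = TRUE)
  nrm / surface$radius                    # unit, outward for R > 0
}

# Trace a block of rays through the eye. Statuses: 0 alive, 1 vignetted,
# 2 absorbed, 3 landed. Returns retina hit coordinates for landed rays.
trace_block <- function(eye, origins, dirs, micro = NULL) {
  n <- nrow(origins)
  status <- integer(n)
  pos <- origins
  n_before <- 1
  lens_anterior <- 3                      # surface index carrying the array
  for (i in seq_along(eye$surfaces)) {
    s <- eye$surfaces[[i]]
    alive <- status == 0L
    if (!any(alive)) break
    # pupil stop: plane aperture, no refraction, between surfaces 2 and 3
    if (i == lens_anterior) {
      tz <- (eye$stop$z - pos[alive, 3]) / dirs[alive, 3]
      px <- pos[alive, 1] + tz * dirs[alive, 1]
      py <- pos[alive, 2] + tz * dirs[alive, 2]
      blocked <- px^2 + py^2 > eye$stop$semi^2
      status[which(alive)[blocked]] <- 1L
      alive <- status == 0L
    }
    ia <- which(alive)
    if (!length(ia)) { n_before <- s$n_after; next }
    hit <- intersect_surface(pos[ia, , drop = FALSE],
                             dirs[ia, , drop = FALSE], s)
    status[ia[hit$miss]] <- 1L
    ok <- !hit$miss
    io <- ia[ok]
    pos[io, ] <- hit$points[ok, , drop = FALSE]
    micro_hits <- NULL
    if (i == lens_anterior && !is.null(micro)) {
      act <- microstructure_interact(micro,
                                     pos[io, 1], pos[io, 2],
                                     dirs[io, , drop = FALSE])
      absorbed <- act$status == "absorbed"
      status[io[absorbed]] <- 2L
      io <- io[!absorbed]
      micro_hits <- act$hits[!absorbed]  # deflection applied post-refraction
    }
    nrm <- surface_normals(pos[io, , drop = FALSE], s)
    rf <- refract(dirs[io, , drop = FALSE], nrm, n_before, s$n_after)
    status[io[rf$tir]] <- 2L             # TIR: absorbed, not reflected
    keep <- !rf$tir
    dirs[io[keep], ] <- rf$dirs[keep, , drop = FALSE]
    if (!is.null(micro_hits) && micro$spec$scatter_model == "cone") {
      sigma <- micro$spec$cone_half_angle * pi / 180
      hk <- micro_hits[keep]
      ik <- io[keep]
      for (h in seq_len(max(c(hk, 0L)))) {
        dd <- ik[hk >= h]
        if (length(dd))
          dirs[dd, ] <- perturb_cone(dirs[dd, , drop = FALSE], sigma)
      }
    }
    n_before <- s$n_after
  }
  # retina plane
  alive <- which(status == 0L)
  tz <- (eye$retina_z - pos[alive, 3]) / dirs[alive, 3]
  bad <- tz <= 0
  status[alive[bad]] <- 1L
  alive <- alive[!bad]
  tz <- tz[!bad]
  rx <- pos[alive, 1] + tz * dirs[alive, 1]
  ry <- pos[alive, 2] + tz * dirs[alive, 2]
  status[alive] <- 3L
  list(status = status, retina_x = rx, retina_y = ry, landed_idx = alive)
}

#' Trace a single ray through the eye
#'
#' Sequential trace cornea -> stop -> lens (with optional microstructure
#' interaction at the lens anterior surface) -> retina.
#'
#' @param eye a `retisim_eye`.
#' @param origin length-3 ray origin in object space (mm).
#' @param direction length-3 unit direction (toward +z).
#' @param power ray power (arbitrary units).
#' @param micro optional [build_hole_array()] geometry.
#' @return list with `status` (`"landed"`, `"vignetted"`, `"absorbed"`),
#'   `power`, and `retina_xy` when landed.
#' @export
trace_ray <- function(eye, origin, direction, power = 1, micro = NULL) {
  direction <- direction / sqrt(sum(direction^2))
  tb <- trace_block(eye, matrix(origin, 1), matrix(direction, 1), micro)
  st <- c("vignetted", "absorbed", "landed")[tb$status]
  out <- list(status = st, power = power)
  if (st == "landed") out$retina_xy <- c(tb$retina_x, tb$retina_y)
  out
}
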