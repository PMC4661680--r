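# Independent oracles, implemented from first principles (no calls into
# the package's paraxial or intersection code paths).

# 2x2 reduced ray-transfer matrix of the eye: acts on (y, w) with
# y' = y + (t/n) w and w' = w - y P/1000.
oracle_system_matrix <- function(eye) {
  n_before <- 1
  M <- diag(2)
  zs <- vapply(eye$surfaces, `[[`, 0, "vertex_z")
  for (i in seq_along(eye$surfaces)) {
    s <- eye$surfaces[[i]]
    P <- if (is.infinite(s$radius) || s$radius == 0) 0 else
      1000 * (s$n_after - n_before) / s$radius
    M <- matrix(c(1, -P / 1000, 0, 1), 2, 2) %*% M
    if (i < length(eye$surfaces)) {
      t_over_n <- (zs[i + 1] - zs[i]) / s$n_after
      M <- matrix(c(1, 0, t_over_n, 1), 2, 2) %*% M
    }
    n_before <- s$n_after
  }
  M
}

# equivalent power in D from the system matrix
oracle_power <- function(eye) -oracle_system_matrix(eye)[2, 1] * 1000

# image-plane z (mm) for an axial object of given vergence at the cornea;
# a unit-height marginal ray from an axial object at l = 1000 n0/V0 mm has
# physical slope -1/l = -V0/1000 (n0 = 1)
oracle_image_z <- function(eye, object_vergence) {
  M <- oracle_system_matrix(eye)
  v <- M %*% c(1, -object_vergence / 1000)
  n_last <- eye$surfaces[[length(eye$surfaces)]]$n_after
  z_last <- eye$surfaces[[length(eye$surfaces)]]$vertex_z
  if (v[2] == 0) return(Inf)
  z_last - v[1] * n_last / v[2]
}

# both roots of the ray/sphere quadratic, brute force
oracle_sphere_hit <- function(origin, dir, vertex_z, radius) {
  cz <- vertex_z + radius
  oc <- origin - c(0, 0, cz)
  b <- sum(oc * dir)
  cc <- sum(oc * oc) - radius^2
  disc <- b^2 - cc
  if (disc < 0) return(NULL)
  ts <- c(-b - sqrt(disc), -b + sqrt(disc))
  ts <- ts[ts > 1e-9]
  if (!length(ts)) return(NULL)
  # the cap containing the vertex: hit z on the vertex side of the center
  for (t in sort(ts)) {
    z <- origin[3] + t * dir[3]
    if ((radius > 0 && z < cz) || (radius < 0 && z > cz)) return(t)
  }
  NULL
}

# scalar Snell residual |n1 sin(theta1) - n2 sin(theta2)| for a
# refraction event, angles measured against the normal
oracle_snell_residual <- function(d_in, d_out, normal, n1, n2) {
  sin_angle <- function(d) {
    c2 <- sum(d * normal)^2 / sum(d * d)
    sqrt(max(0, 1 - c2))
  }
  abs(n1 * sin_angle(d_in) - n2 * sin_angle(d_out))
}

# mean of |N(0, sigma)|
oracle_folded_mean <- function(sigma) sigma * sqrt(2 / pi)

# uniform unit vector with positive z (for refraction fuzzing)
random_forward_dir <- function() {
  repeat {
    v <- stats::rnorm(3)
    if (v[3] > 0.05) return(v / sqrt(sum(v^2)))
  }
}
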