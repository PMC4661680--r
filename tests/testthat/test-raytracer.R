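test_that("vector Snell refraction reproduces the scalar law", {
  # normal incidence: direction unchanged, any index pair
  d <- c(0, 0, 1)
  expect_equal(refract(d, c(0, 0, -1), 1, 1.7), d, tolerance = 1e-14)
  # 30 degrees into n = 1.5: closed form arcsin(sin(30)/1.5) = 19.471
  d30 <- c(sin(pi / 6), 0, cos(pi / 6))
  out <- refract(d30, c(0, 0, -1), 1, 1.5)
  theta2 <- asin(out[1]) * 180 / pi
  expect_equal(theta2, 19.4712, tolerance = 0.001 / 19.4712)
  # total internal reflection signalled
  steep <- c(sin(80 * pi / 180), 0, cos(80 * pi / 180))
  expect_null(refract(steep, c(0, 0, -1), 1.5, 1.0))
})

test_that("refraction fuzzing: Snell residual < 1e-12 over 1e4 cases", {
  set.seed(2024)
  worst <- 0
  for (i in 1:1e4) {
    d <- random_forward_dir()
    nrm <- random_forward_dir() * c(1, 1, -1)
    ns <- 1 + stats::runif(2, 0, 0.9)
    out <- refract(d, nrm, ns[1], ns[2])
    if (is.null(out)) next
    expect_equal(sum(out^2), 1, tolerance = 1e-12)
    worst <- max(worst, oracle_snell_residual(d, out, nrm, ns[1], ns[2]))
  }
  expect_lt(worst, 1e-12)
})

test_that("sphere intersection matches the quadratic-root oracle", {
  eye <- build_schematic_eye()
  s <- eye$surfaces[[1]]
  # axial ray hits the vertex
  hit <- intersect_surface(matrix(c(0, 0, -100), 1), matrix(c(0, 0, 1), 1), s)
  expect_equal(unname(hit$points[1, 3]), s$vertex_z, tolerance = 1e-12)
  # marginal ray aimed outside the semi-aperture is a miss
  big <- intersect_surface(matrix(c(5.9, 0, -100), 1),
                           matrix(c(0, 0, 1), 1), s)
  expect_true(big$miss[1])
  # oblique fuzzing vs the brute-force quadratic
  set.seed(99)
  n_ok <- 0
  for (i in 1:1e4) {
    o <- c(stats::runif(2, -3, 3), -stats::runif(1, 5, 50))
    dir <- c(stats::runif(2, -0.05, 0.05), 1)
    dir <- dir / sqrt(sum(dir^2))
    srf <- eye$surfaces[[sample(4, 1)]]
    got <- intersect_surface(matrix(o, 1), matrix(dir, 1), srf)
    want_t <- oracle_sphere_hit(o, dir, srf$vertex_z, srf$radius)
    if (is.null(want_t) || got$miss[1]) next
    n_ok <- n_ok + 1
    expect_lt(max(abs(got$points[1, ] - (o + want_t * dir))), 1e-10)
  }
  expect_gt(n_ok, 9000)   # the fuzz must actually exercise hits
})

test_that("sequential tracing lands, vignettes and absorbs as specified", {
  eye <- build_schematic_eye()
  # on-axis ray from the chart distance lands at the retinal origin
  r <- trace_ray(eye, c(0, 0, -6096), c(0, 0, 1))
  expect_equal(r$status, "landed")
  expect_lt(max(abs(r$retina_xy)), 1e-9)
  # ray aimed at the iris outside the pupil is vignetted
  r2 <- trace_ray(eye, c(0, 3.5, -50), c(0, 0, 1))
  expect_equal(r2$status, "vignetted")
})

test_that("Monte-Carlo axial blur at 5 D matches the paraxial blur disc", {
  # paraxial oracle is a small-aperture statement: use a 1 mm pupil so
  # spherical aberration stays inside the 5% band
  eye <- induce_myopia(build_schematic_eye(list(pupil_diameter = 1)), 5)
  tb <- trace_pencil(eye, n = 1e4, seed = 11)
  rms <- sqrt(mean(tb$retina_x^2 + tb$retina_y^2))
  predicted <- retisim:::paraxial_blur_radius(eye, -6096) / sqrt(2)
  expect_equal(rms, predicted, tolerance = 0.05)
})

test_that("RMS spot radius is non-decreasing in induced myopia", {
  base <- build_schematic_eye()
  rms <- vapply(0:10, function(d) {
    tb <- trace_pencil(induce_myopia(base, d), n = 5e3, seed = 21)
    sqrt(mean(tb$retina_x^2 + tb$retina_y^2))
  }, 0)
  expect_true(all(diff(rms) >= 0))
})

test_that("point-source centroid sits at the paraxial image height (<= 1 bin)", {
  eye <- build_schematic_eye(list(pupil_diameter = 1))
  chart <- default_scene()$chart
  bin <- simulate_image(eye, sample_source(chart, 100, seed = 1))$bin_size
  for (deg in c(0.5, 1, 2)) {
    h <- 6096 * tan(deg * pi / 180)
    tb <- trace_pencil(eye, n = 5e3, seed = 31, field_x = h)
    m <- retisim:::chief_magnification(eye, -6096)
    expect_lt(abs(mean(tb$retina_x) - m * h), bin)
  }
})

test_that("simulation is deterministic and conserves power exactly", {
  sc <- default_scene()
  src <- sample_source(sc$chart, 2e4, seed = 5)
  m1 <- simulate_image(sc$eye, src, seed = 6)
  m2 <- simulate_image(sc$eye, src, seed = 6)
  expect_identical(m1$grid, m2$grid)
  t <- m1$totals
  resid <- abs(t$launched - t$landed - t$vignetted - t$absorbed)
  expect_lt(resid / t$launched, 1e-9)
  expect_equal(sum(m1$grid), t$landed)      # bin sum = landed power
})

test_that("ROI flux is additive and bounded by the landed power", {
  sc <- default_scene()
  src <- sample_source(sc$chart, 2e4, seed = 5)
  map <- simulate_image(sc$eye, src, seed = 6)
  w <- map$window
  expect_equal(total_flux(map, list(x = c(-w, w), y = c(-w, w))),
               map$totals$landed)
  expect_identical(total_flux(map, list(x = c(0.9 * w, w),
                                        y = c(0.9 * w, w))) >= 0, TRUE)
  expect_equal(total_flux(map, list(x = c(0.2, 0.1), y = c(-w, w))), 0)
  quadrants <- list(list(x = c(-w, 0), y = c(-w, 0)),
                    list(x = c(-w, 0), y = c(0, w)),
                    list(x = c(0, w),  y = c(-w, 0)),
                    list(x = c(0, w),  y = c(0, w)))
  expect_equal(sum(vapply(quadrants, function(q) total_flux(map, q), 0)),
               map$totals$landed, tolerance = 1e-12)
})

test_that("whole-chart flux dominates any sub-region at the same budget", {
  sc <- default_scene()
  f <- function(region) {
    src <- sample_source(select_region(sc$chart, region), 1e4, seed = 9)
    map <- simulate_image(sc$eye, src, seed = 10)
    total_flux(map, retinal_roi(sc$eye, sc$chart, region))
  }
  fw <- f("whole")
  for (r in c("E", "EFP", "rows5to8")) expect_gte(fw, f(r))
})

test_that("10 D of myopia strictly reduces the whole-chart ROI flux", {
  sc <- default_scene()
  src <- sample_source(sc$chart, 2e5, seed = 12)
  f0 <- total_flux(simulate_image(sc$eye, src, seed = 13),
                   retinal_roi(sc$eye, sc$chart, "whole"))
  e10 <- induce_myopia(sc$eye, 10)
  f10 <- total_flux(simulate_image(e10, src, seed = 13),
                    retinal_roi(e10, sc$chart, "whole"))
  expect_lt(f10, f0)
})
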