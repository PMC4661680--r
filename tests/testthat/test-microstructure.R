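test_that("periodic lattices are centered; random layers are seeded", {
  g <- build_hole_array(microstructure_spec(2, 1))
  centers <- g$centers[[1]][order(g$centers[[1]][, 1],
                                  g$centers[[1]][, 2]), ]
  expect_equal(unname(centers),
               cbind(c(-0.5, -0.5, 0.5, 0.5), c(-0.5, 0.5, -0.5, 0.5)))
  r1 <- build_hole_array(microstructure_spec(10, 0.1, placement = "random",
                                             layers = 2, seed = 42))
  r2 <- build_hole_array(microstructure_spec(10, 0.1, placement = "random",
                                             layers = 2, seed = 42))
  expect_identical(r1$centers, r2$centers)
  expect_equal(nrow(r1$centers[[1]]) * length(r1$centers), 10^2 * 2)
  expect_true(all(abs(unlist(r1$centers)) <= r1$half_side))
})

test_that("footprints larger than the lens are rejected", {
  expect_error(build_hole_array(microstructure_spec(100, 0.2),
                                lens_semi_aperture = 5),
               class = "retisim_geometry_error")
  # the 100 x 100, 0.05 mm configuration fits a 10 mm lens
  g <- build_hole_array(microstructure_spec(100, 0.05),
                        lens_semi_aperture = 5)
  expect_equal(2 * g$half_side, 5)
  expect_error(microstructure_spec(50, 0.02, hole_diameter = 0.03),
               class = "retisim_config_error")
})

test_that("array_area reproduces every published configuration exactly", {
  cfg <- reference_configs()
  got <- mapply(array_area, cfg$array, cfg$period, cfg$layers)
  expect_identical(round(got, 10), round(cfg$area, 10))
  expect_equal(array_area(1, 0.3, 1), 0.09)   # degenerate single hole
})

test_that("interaction passes, blocks and deflects as configured", {
  g <- build_hole_array(microstructure_spec(2, 1, hole_diameter = 0.2))
  dirs <- matrix(rep(c(0, 0, 1), each = 4), ncol = 3)
  act <- microstructure_interact(g, c(3, 0.5, 0, 0.75), c(3, 0.5, 0, 0.5),
                                 dirs)
  expect_equal(act$status, c("pass", "absorbed", "pass", "pass"))
  # cone mode: empirical mean polar deflection matches the folded-normal
  # mean within 2 standard errors
  sigma_deg <- 5
  gc <- build_hole_array(microstructure_spec(2, 1, hole_diameter = 0.2,
                                             scatter_model = "cone",
                                             cone_half_angle = sigma_deg))
  n <- 1e5
  dirs <- matrix(rep(c(0, 0, 1), each = n), ncol = 3)
  act <- with_seed(17, microstructure_interact(gc, rep(0.5, n), rep(0.5, n),
                                               dirs))
  expect_true(all(act$status == "deflected"))
  theta <- acos(pmin(1, act$dirs[, 3]))
  sigma <- sigma_deg * pi / 180
  se <- stats::sd(theta) / sqrt(n)
  expect_lt(abs(mean(theta) - oracle_folded_mean(sigma)), 2 * se)
  expect_equal(rowSums(act$dirs^2), rep(1, n), tolerance = 1e-12)
})

test_that("Monte-Carlo hit fraction converges to the coverage formula", {
  spec <- microstructure_spec(20, 0.05, hole_diameter = 0.02)
  g <- build_hole_array(spec)
  n <- 1e5
  pts <- with_seed(8, cbind(stats::runif(n, -g$half_side, g$half_side),
                            stats::runif(n, -g$half_side, g$half_side)))
  hit <- retisim:::layer_hit(g, 1, pts[, 1], pts[, 2])
  p <- hole_coverage(spec)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(hit) - p), 3 * se)
  # random placement agrees through the cell-hash lookup; independent
  # random centers overlap, so the expected covered fraction is
  # 1 - (1 - a/A)^(N^2)
  gr <- build_hole_array(microstructure_spec(20, 0.05, hole_diameter = 0.02,
                                             placement = "random", seed = 3))
  hit_r <- retisim:::layer_hit(gr, 1, pts[, 1], pts[, 2])
  a_over_A <- (pi / 4) * 0.02^2 / (20 * 0.05)^2
  p_rand <- 1 - (1 - a_over_A)^(20^2)
  se_r <- sqrt(p_rand * (1 - p_rand) / n)
  expect_lt(abs(mean(hit_r) - p_rand), 4 * se_r)
})

test_that("a block-mode microstructure never increases ROI flux", {
  sc <- default_scene()
  src <- sample_source(sc$chart, 2e4, seed = 14)
  roi <- retinal_roi(sc$eye, sc$chart, "whole")
  base <- total_flux(simulate_image(sc$eye, src, seed = 15), roi)
  for (P in c(0.07, 0.02)) {
    g <- build_hole_array(microstructure_spec(50, P, layers = 2))
    withm <- total_flux(simulate_image(sc$eye, src, seed = 15, micro = g),
                        roi)
    expect_lte(withm, base)
  }
})
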