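# Small-budget calibration and prediction behavior. The default-budget
# sweeps live in test-acceptance.R.

small_curve <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$curve)) {
      sc <- default_scene()
      cache$curve <- build_calibration(sc$eye, sc$chart, diopters = 0:10,
                                       n_rays = 3e4, seed = 3)
    }
    cache$curve
  }
})

test_that("calibration is anchored, deterministic and monotone for the whole chart", {
  cv <- small_curve()
  expect_identical(cv$normalized_flux[1], 1)          # plano anchor, exact
  expect_true(all(diff(cv$normalized_flux) < 0))
  expect_true(cv$invertible)
  sc <- default_scene()
  cv2 <- build_calibration(sc$eye, sc$chart, diopters = 0:10,
                           n_rays = 3e4, seed = 3)
  expect_identical(cv$flux, cv2$flux)                 # same seed, same curve
})

test_that("curve construction validates its inputs", {
  sc <- default_scene()
  expect_error(build_calibration(sc$eye, sc$chart, diopters = 1:5,
                                 n_rays = 1e4),
               class = "retisim_config_error")
  expect_error(build_calibration(sc$eye, sc$chart, n_rays = 100),
               class = "retisim_config_error")
  expect_error(build_calibration(induce_myopia(sc$eye, 2), sc$chart,
                                 n_rays = 1e4),
               class = "retisim_config_error")
})

test_that("equivalent_myopia is the exact right-inverse at the nodes", {
  cv <- small_curve()
  for (i in seq_along(cv$diopters))
    expect_identical(equivalent_myopia(cv, cv$normalized_flux[i]),
                     cv$diopters[i])
  expect_identical(equivalent_myopia(cv, 1), 0)
  # midpoint between the 3 D and 4 D nodes -> 3.5 D by the declared
  # piecewise-linear contract (hand computation)
  f_mid <- (cv$normalized_flux[4] + cv$normalized_flux[5]) / 2
  hand <- 3 + (f_mid - cv$normalized_flux[4]) /
    (cv$normalized_flux[5] - cv$normalized_flux[4])
  expect_equal(hand, 3.5, tolerance = 1e-12)
  expect_lt(abs(equivalent_myopia(cv, f_mid) - 3.5), 1e-9)
})

test_that("fluxes outside the calibrated range are signalled", {
  cv <- small_curve()
  expect_error(equivalent_myopia(cv, 1.01),
               class = "retisim_out_of_range_error")
  expect_error(equivalent_myopia(cv, min(cv$normalized_flux) - 0.01),
               class = "retisim_out_of_range_error")
})

test_that("a non-monotone sub-region curve is flagged, not inverted", {
  # frozen configuration observed to exhibit the straylight-driven
  # non-monotonicity: rows 2-4 ROI with the whole chart lit, minimum
  # budget
  sc <- default_scene()
  expect_warning(
    cv <- build_calibration(sc$eye, sc$chart, region = "rows2to4",
                            n_rays = 1e4, seed = 2, stray_light = TRUE),
    "non-monotone")
  expect_false(cv$invertible)
  expect_error(equivalent_myopia(cv, 0.9),
               class = "retisim_noninvertible_error")
})

test_that("an unmodified eye predicts as indistinguishable from plano", {
  sc <- default_scene()
  rep <- predict(small_curve(), NULL, sc$eye, sc$chart, n_rays = 3e4,
                 seed = 4)
  expect_equal(rep$status, "indistinguishable")
  expect_lt(abs(rep$equivalent_myopia), 0.25)
})

test_that("doubling layers never lowers the predicted severity", {
  sc <- default_scene()
  cv <- small_curve()
  em <- vapply(c(1, 2), function(L) {
    spec <- microstructure_spec(50, 0.02, layers = L, placement = "random",
                                seed = 6)
    predict(cv, spec, sc$eye, sc$chart, n_rays = 5e4,
            seed = 5)$equivalent_myopia
  }, 0)
  expect_gte(em[2], em[1])
})

test_that("prediction requires an invertible whole-chart curve and a plano eye", {
  sc <- default_scene()
  cv <- small_curve()
  expect_error(predict(cv, NULL, induce_myopia(sc$eye, 1), sc$chart),
               class = "retisim_config_error")
  cvE <- withCallingHandlers(
    build_calibration(sc$eye, sc$chart, region = "E", n_rays = 1e4,
                      seed = 1),
    warning = function(w) invokeRestart("muffleWarning"))
  expect_error(predict(cvE, NULL, sc$eye, sc$chart),
               class = "retisim_config_error")
})

test_that("calibration curves survive a CSV/JSON round trip", {
  cv <- small_curve()
  prefix <- file.path(withr_like_tempdir(), "curve")
  write_calibration(cv, prefix)
  back <- read_calibration(prefix)
  expect_equal(back$diopters, cv$diopters)
  expect_equal(back$normalized_flux, cv$normalized_flux, tolerance = 1e-12)
  expect_true(back$invertible)
  expect_lt(abs(equivalent_myopia(back, cv$normalized_flux[3]) - 2), 1e-9)
})
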