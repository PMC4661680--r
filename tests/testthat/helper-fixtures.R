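# Shared scene builders and a lazily built, cached default-budget
# calibration curve (reused across the acceptance criteria so the heavy
# 11-point sweep runs once).

withr_like_tempdir <- function() {
  d <- tempfile("retisim-test-")
  dir.create(d)
  d
}

tiny_chart <- function(distance = "20ft") {
  render_chart(chart_spec(distance,
                          rows = data.frame(denominator = 200,
                                            letters = "E")))
}

default_scene <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$eye)) {
      cache$eye <- build_schematic_eye()
      cache$chart <- render_chart()
    }
    list(eye = cache$eye, chart = cache$chart)
  }
})

# a 1e4-ray pencil from an axial (or field) point aimed at the entrance
# pupil; returns landing coordinates
trace_pencil <- function(eye, n = 1e4, seed = 11, field_x = 0,
                         z_obj = -6096) {
  ep <- retisim:::entrance_pupil(eye)
  with_seed(seed, {
    r <- ep$semi * sqrt(stats::runif(n))
    a <- stats::runif(n, 0, 2 * pi)
    origins <- cbind(field_x, 0, z_obj)[rep(1, n), ]
    d <- cbind(r * cos(a) - field_x, r * sin(a), ep$z - z_obj)
    retisim:::trace_block(eye, origins, d / sqrt(rowSums(d * d)))
  })
}

acceptance_curve <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$curve)) {
      sc <- default_scene()
      cache$curve <- build_calibration(sc$eye, sc$chart, region = "whole",
                                       diopters = 0:10, n_rays = 2e5,
                                       seed = 1)
    }
    cache$curve
  }
})

# Reference opacity configurations D1-D12: (array, layers, period) with
# their published distribution areas
reference_configs <- function() {
  data.frame(
    id = paste0("D", 1:12),
    array = c(100, 100, 100, 100, 50, 50, 50, 50, 50, 50, 100, 50),
    layers = c(1, 1, 1, 1, 2, 2, 2, 2, 2, 2, 2, 3),
    period = c(0.02, 0.03, 0.04, 0.05, 0.07, 0.06, 0.05, 0.04, 0.03,
               0.02, 0.04, 0.04),
    area = c(4.0, 9.0, 16.0, 25.0, 24.5, 18.0, 12.5, 8.0, 4.5, 2.0,
             32.0, 12.0))
}
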