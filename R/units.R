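# Coordinate and unit conventions, stated once and used everywhere:
#   * right-handed frame, optical axis = +z from cornea toward retina
#   * lengths in mm; z = 0 at the anterior corneal vertex; the chart sits
#     at negative z
#   * vergences and refractive powers in diopters (computed in meters)
#   * surface radius sign: positive when the center of curvature lies
#     toward the retina (+z); 0 or Inf means flat

MM_PER_FOOT <- 304.8
ARCMIN <- pi / (180 * 60)          # radians per arc minute
SNELLEN_REF_DISTANCE_MM <- 20 * MM_PER_FOOT   # 20 ft acuity reference

#' Convert diopters to a distance in millimeters
#'
#' @param d vergence in diopters (n / distance-in-meters).
#' @param n refractive index of the medium (default 1, air).
#' @return distance in mm (Inf at d = 0).
#' @keywords internal
diopters_to_mm <- function(d, n = 1) ifelse(d == 0, Inf, 1000 * n / d)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package internals never
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream derivation: one master seed, many independent
# draws, all < 2^31.
derive_seed <- function(seed, i) {
  (as.integer(seed) %% 599479L) * 3581L + as.integer(i) * 7919L
}

stop_retisim <- function(msg, class) {
  stop(structure(class = c(class, "retisim_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
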