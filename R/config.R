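# Run configuration: JSON key-value files with defaults and strict
# unknown-key rejection.

#' Default run configuration
#'
#' @return nested list with sections `eye`, `chart`, `region`, `myopia`,
#'   `microstructure` (NULL = none), `n_rays`, `n_bins`, `seed`, `outdir`.
#' @export
default_config <- function() {
  list(
    eye = list(preset = "legrand", pupil_diameter = 4, stop_z = NULL,
               emmetropize_at = "infinity"),
    chart = list(distance = "20ft", luminance = 1),
    region = "whole",
    myopia = 0:10,
    microstructure = NULL,
    n_rays = 2e5,
    n_bins = 256,
    seed = 1,
    outdir = "."
  )
}

config_known_keys <- function() {
  list(top = names(default_config()),
       eye = c("preset", "pupil_diameter", "stop_z", "emmetropize_at",
               "retina_radius"),
       chart = c("distance", "luminance", "rows"),
       microstructure = c("array_count", "period", "hole_diameter",
                          "layers", "placement", "scatter_model",
                          "cone_half_angle", "seed"))
}

#' Load and validate a run configuration
#'
#' Reads a JSON config, fills every missing key with its default, rejects
#' unknown keys, and validates the resolved values (building the eye and
#' inducing the largest requested myopia, so range errors from the eye
#' model surface here).
#'
#' @param path JSON file; an empty file (or `{}`) yields all defaults.
#' @return resolved configuration list of class `retisim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop_retisim(sprintf("config file '%s' not found", path),
                 "retisim_config_error")
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!nzchar(trimws(txt))) txt <- "{}"
  raw <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
                  error = function(e)
                    stop_retisim(paste("config parse error:",
                                       conditionMessage(e)),
                                 "retisim_parse_error"))
  resolve_config(raw)
}

#' @rdname load_config
#' @param raw configuration list (possibly partial) to resolve in memory.
#' @export
resolve_config <- function(raw = list()) {
  defaults <- default_config()
  known <- config_known_keys()
  unknown <- setdiff(names(raw), known$top)
  if (length(unknown))
    stop_retisim(paste("unknown config key(s):",
                       paste(unknown, collapse = ", ")),
                 "retisim_config_error")
  cfg <- utils::modifyList(defaults, raw, keep.null = TRUE)
  for (sec in c("eye", "chart", "microstructure")) {
    if (is.null(cfg[[sec]])) next
    bad <- setdiff(names(cfg[[sec]]), known[[sec]])
    if (length(bad))
      stop_retisim(paste0("unknown key(s) in '", sec, "': ",
                          paste(bad, collapse = ", ")),
                   "retisim_config_error")
  }
  if (identical(cfg$eye$emmetropize_at, "infinity"))
    cfg$eye$emmetropize_at <- Inf
  # validation via the domain constructors
  eye <- build_schematic_eye(cfg$eye)
  for (m in cfg$myopia) induce_myopia(eye, m)   # propagates range errors
  chart_spec(cfg$chart$distance %||% "20ft",
             rows = if (is.null(cfg$chart$rows)) snellen_rows()
                    else as.data.frame(cfg$chart$rows),
             luminance = cfg$chart$luminance %||% 1)
  if (!is.null(cfg$microstructure))
    do.call(microstructure_spec, cfg$microstructure)
  class(cfg) <- "retisim_config"
  cfg
}

#' Serialize a configuration to JSON
#'
#' `load_config(dump_config(cfg, f))` resolves to an equal configuration.
#'
#' @param config a `retisim_config` (or partial list).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  cfg <- unclass(config)
  if (is.infinite(cfg$eye$emmetropize_at %||% Inf))
    cfg$eye$emmetropize_at <- "infinity"
  cfg <- cfg[!vapply(cfg, is.null, TRUE)]
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# objects the config describes, built once for a run
config_build <- function(cfg) {
  eye <- build_schematic_eye(cfg$eye)
  spec <- chart_spec(cfg$chart$distance %||% "20ft",
                     rows = if (is.null(cfg$chart$rows)) snellen_rows()
                            else as.data.frame(cfg$chart$rows),
                     luminance = cfg$chart$luminance %||% 1)
  chart <- render_chart(spec)
  micro <- if (!is.null(cfg$microstructure))
    build_hole_array(do.call(microstructure_spec, cfg$microstructure),
                     lens_semi_aperture = eye$surfaces[[3]]$semi_aperture)
  list(eye = eye, chart = chart, micro = micro)
}
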