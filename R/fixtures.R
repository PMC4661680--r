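# Tiny deterministic test scenes for sub-second tests.

#' Write the fixture set
#'
#' Emits three small plain-text files: a one-letter chart configuration
#' (`fixture_chart.json`), a three-point diopter grid
#' (`fixture_diopters.csv`) and a 2x2 periodic microstructure
#' (`fixture_micro.json`). Contents are fully determined by `seed`, so a
#' fixed seed reproduces the set byte for byte.
#'
#' @param out_dir writable output directory (created if missing).
#' @param seed integer seed, recorded in each fixture.
#' @return character vector of file paths, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(seed)
  chart_path <- file.path(out_dir, "fixture_chart.json")
  writeLines(c(
    "{",
    sprintf('  "seed": %d,', seed),
    '  "chart": {',
    '    "distance": "20ft",',
    '    "luminance": 1,',
    '    "rows": { "denominator": [200], "letters": ["E"] }',
    "  }",
    "}"), chart_path)
  grid_path <- file.path(out_dir, "fixture_diopters.csv")
  writeLines(c("diopters", "0", "2", "4"), grid_path)
  micro_path <- file.path(out_dir, "fixture_micro.json")
  writeLines(c(
    "{",
    sprintf('  "seed": %d,', seed),
    '  "array_count": 2,',
    '  "period": 1,',
    '  "hole_diameter": 0.5,',
    '  "layers": 1,',
    '  "placement": "periodic",',
    '  "scatter_model": "block"',
    "}"), micro_path)
  invisible(c(chart_path, grid_path, micro_path))
}
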