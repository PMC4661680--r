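# File writers: ASCII PGM images, CSV tables, JSON metadata sidecars.

#' Write a matrix as a plain (P2) PGM image
#'
#' @param m numeric matrix (row 1 = top); values are rescaled to
#'   `0..maxval`.
#' @param path output file.
#' @param maxval maximum gray value (default 255).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(m, path, maxval = 255) {
  mx <- max(m)
  g <- if (mx > 0) round(m / mx * maxval) else m * 0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(g), nrow(g)), as.character(maxval)), con)
  utils::write.table(g, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a plain (P2) PGM image
#'
#' @param path PGM file written by [write_pgm()].
#' @return integer matrix.
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  stopifnot(toks[1] == "P2")
  nc <- as.integer(toks[2]); nr <- as.integer(toks[3])
  matrix(as.integer(toks[-(1:4)]), nrow = nr, ncol = nc, byrow = TRUE)
}

# JSON sidecar carrying the resolved configuration for reproducibility
write_sidecar <- function(path, ..., config = NULL) {
  meta <- list(..., version = retisim_version(),
               created = "retisim run")
  if (!is.null(config)) meta$config <- unclass(config)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Persist an irradiance map
#'
#' Writes `<prefix>.csv` (flux grid), `<prefix>.pgm` (tone-mapped view)
#' and `<prefix>.json` (totals, window, resolved config).
#'
#' @param map a `retisim_irradiance`.
#' @param prefix output path prefix.
#' @param config optional resolved config to embed.
#' @return the sidecar path, invisibly.
#' @export
write_irradiance <- function(map, prefix, config = NULL) {
  utils::write.table(map$grid, paste0(prefix, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  write_pgm(as.matrix(map), paste0(prefix, ".pgm"))
  write_sidecar(paste0(prefix, ".json"),
                totals = map$totals, window = map$window,
                bin_size = map$bin_size, n_bins = map$n_bins,
                magnification = map$magnification, seed = map$seed,
                config = config)
}

#' Persist / reload a calibration curve
#'
#' CSV columns `diopters,flux,normalized_flux,flux_se`; metadata in a JSON
#' sidecar.
#'
#' @param curve a `retisim_calibration`.
#' @param prefix path prefix (`<prefix>.csv` + `<prefix>.json`).
#' @return `write_calibration`: sidecar path invisibly;
#'   `read_calibration`: the curve.
#' @export
write_calibration <- function(curve, prefix) {
  utils::write.csv(data.frame(diopters = curve$diopters, flux = curve$flux,
                              normalized_flux = curve$normalized_flux,
                              flux_se = curve$flux_se),
                   paste0(prefix, ".csv"), row.names = FALSE)
  write_sidecar(paste0(prefix, ".json"),
                region = curve$region, invertible = curve$invertible,
                metadata = curve$metadata)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(prefix) {
  tab <- utils::read.csv(paste0(prefix, ".csv"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  structure(list(diopters = tab$diopters, flux = tab$flux,
                 normalized_flux = tab$normalized_flux,
                 flux_se = tab$flux_se,
                 invertible = isTRUE(meta$invertible),
                 region = meta$region, metadata = meta$metadata),
            class = "retisim_calibration")
}
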