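# Snellen optotype source: block 5x5-grid letters, emissive, with the six
# selection regions used for region-wise flux curves.

# Glyph table: 5x5 binary matrices (row 1 = top). Data, not code; the "E"
# fills 17 of 25 cells.
snellen_glyphs <- function() {
  g <- function(...) matrix(as.integer(unlist(strsplit(c(...), ""))),
                            nrow = 5, byrow = TRUE)
  list(
    E = g("11111", "10000", "11111", "10000", "11111"),
    F = g("11111", "10000", "11111", "10000", "10000"),
    P = g("11111", "10001", "11111", "10000", "10000"),
    T = g("11111", "00100", "00100", "00100", "00100"),
    O = g("11111", "10001", "10001", "10001", "11111"),
    Z = g("11111", "00010", "00100", "01000", "11111"),
    L = g("10000", "10000", "10000", "10000", "11111"),
    D = g("11110", "10001", "10001", "10001", "11110"),
    C = g("11111", "10000", "10000", "10000", "11111"))
}

# Classic 8-row Snellen layout (20/200 at the top down to 20/20).
snellen_rows <- function() {
  data.frame(
    denominator = c(200, 100, 70, 50, 40, 30, 25, 20),
    letters = c("E", "FP", "TOZ", "LPED", "PECFD", "EDFCZP",
                "FELOPZD", "DEFPOTEC"),
    stringsAsFactors = FALSE)
}

#' Specify a Snellen chart
#'
#' Letter sizes follow the acuity definition: the 20/20 row subtends 5 arc
#' minutes at the 20 ft reference distance; a 20/X row is scaled by X/20.
#' Letters are built on a 5x5 stroke grid (stroke = height / 5).
#'
#' @param distance chart-to-cornea distance in mm. The named presets
#'   `"20ft"` (default, consistent with the acuity definition) and `"6ft"`
#'   are also accepted.
#' @param rows data frame with columns `denominator` and `letters`;
#'   defaults to the classic 8-row layout.
#' @param luminance emitted power per unit lit area (arbitrary units/mm^2).
#' @return object of class `retisim_chart_spec`.
#' @export
chart_spec <- function(distance = "20ft", rows = snellen_rows(),
                       luminance = 1) {
  if (is.character(distance))
    distance <- switch(distance,
                       "20ft" = 20 * MM_PER_FOOT,
                       "6ft"  = 6 * MM_PER_FOOT,
                       stop_retisim(sprintf("unknown chart distance preset '%s'",
                                            distance),
                                    "retisim_config_error"))
  if (!is.finite(distance) || distance <= 0)
    stop_retisim("chart distance must be positive", "retisim_config_error")
  stopifnot(is.data.frame(rows),
            all(c("denominator", "letters") %in% names(rows)),
            luminance > 0)
  structure(list(distance = distance, rows = rows, luminance = luminance),
            class = "retisim_chart_spec")
}

# physical letter height (mm) of a 20/X row on a 20 ft-referenced chart
snellen_letter_height <- function(denominator) {
  2 * SNELLEN_REF_DISTANCE_MM * tan(2.5 * ARCMIN * denominator / 20)
}

#' Render the Snellen chart
#'
#' Lays the letters out as lit cells (exact rectangles in chart
#' coordinates, mm, origin on the optical axis, y up) and returns the lit
#' area exactly (count of lit cells times cell area). Rows are centered
#' horizontally; the block is centered vertically. Horizontal letter
#' spacing and vertical row spacing both equal one letter height of the
#' relevant row.
#'
#' @param spec a [chart_spec()].
#' @return object of class `retisim_chart`: fields `cells` (data frame
#'   `x0,x1,y0,y1,letter,row`), `lit_area` (mm^2), `extent`
#'   (`xlim`/`ylim`), `spec`, and per-row geometry.
#' @export
render_chart <- function(spec = chart_spec()) {
  glyphs <- snellen_glyphs()
  rows <- spec$rows
  h <- snellen_letter_height(rows$denominator)
  gap_v <- c(h[-1], 0)                    # gap below row i = next row height
  total_h <- sum(h) + sum(gap_v[-length(gap_v)])
  y_top <- total_h / 2

  cells <- vector("list", nrow(rows))
  row_geom <- vector("list", nrow(rows))
  for (r in seq_len(nrow(rows))) {
    letters <- strsplit(rows$letters[r], "")[[1]]
    bad <- setdiff(letters, names(glyphs))
    if (length(bad))
      stop_retisim(paste("no glyph for letter(s):",
                         paste(bad, collapse = ", ")),
                   "retisim_config_error")
    hr <- h[r]; cell <- hr / 5
    width_total <- length(letters) * hr + (length(letters) - 1) * hr
    x_left <- -width_total / 2
    y0_row <- y_top - hr
    out <- vector("list", length(letters))
    for (k in seq_along(letters)) {
      gm <- glyphs[[letters[k]]]
      lit <- which(gm == 1, arr.ind = TRUE)
      lx <- x_left + (k - 1) * 2 * hr
      out[[k]] <- data.frame(
        x0 = lx + (lit[, "col"] - 1) * cell,
        x1 = lx + lit[, "col"] * cell,
        y0 = y0_row + (5 - lit[, "row"]) * cell,
        y1 = y0_row + (6 - lit[, "row"]) * cell,
        letter = letters[k], letter_index = k, row = r)
    }
    cells[[r]] <- do.call(rbind, out)
    row_geom[[r]] <- list(row = r, height = hr, y0 = y0_row, y1 = y_top,
                          x0 = x_left, x1 = x_left + width_total)
    y_top <- y0_row - gap_v[r]
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  lit_area <- sum((cells$x1 - cells$x0) * (cells$y1 - cells$y0))
  structure(list(
    cells = cells, lit_area = lit_area, spec = spec,
    rows = do.call(rbind, lapply(row_geom, as.data.frame)),
    extent = list(xlim = range(c(cells$x0, cells$x1)),
                  ylim = range(c(cells$y0, cells$y1))),
    region = "whole"
  ), class = "retisim_chart")
}

#' @export
print.retisim_chart <- function(x, ...) {
  cat(sprintf("Snellen chart at %.0f mm: %d lit cells, lit area %.1f mm^2 (region %s)\n",
              x$spec$distance, nrow(x$cells), x$lit_area, x$region))
  invisible(x)
}

#' The six chart selection regions
#'
#' Region bounding boxes over the rendered layout: `whole`, `E` (the top
#' letter), `EFP` (rows 1-2), `EFPTOZ` (rows 1-3), `rows2to4` and
#' `rows5to8`. Boxes are letter/row bounding boxes padded by a fraction of
#' the tallest included letter height (default 10%).
#'
#' @param chart a rendered `retisim_chart`.
#' @param padding padding as a fraction of the tallest included letter.
#' @return named list of regions, each `list(name, bbox = c(x0, x1, y0, y1))`.
#' @export
chart_regions <- function(chart, padding = 0.1) {
  rows <- chart$rows
  box_rows <- function(rr) {
    sel <- chart$cells[chart$cells$row %in% rr, ]
    hmax <- max(rows$height[rows$row %in% rr])
    pad <- padding * hmax
    c(x0 = min(sel$x0) - pad, x1 = max(sel$x1) + pad,
      y0 = min(sel$y0) - pad, y1 = max(sel$y1) + pad)
  }
  ex <- chart$extent
  hmax <- max(rows$height)
  pad <- padding * hmax
  whole <- c(x0 = ex$xlim[1] - pad, x1 = ex$xlim[2] + pad,
             y0 = ex$ylim[1] - pad, y1 = ex$ylim[2] + pad)
  list(
    whole    = list(name = "whole",    bbox = whole),
    E        = list(name = "E",        bbox = box_rows(1)),
    EFP      = list(name = "EFP",      bbox = box_rows(1:2)),
    EFPTOZ   = list(name = "EFPTOZ",   bbox = box_rows(1:3)),
    rows2to4 = list(name = "rows2to4", bbox = box_rows(2:4)),
    rows5to8 = list(name = "rows5to8", bbox = box_rows(5:8)))
}

#' Mask the chart to a selection region
#'
#' Cells whose centers fall outside the region's bounding box are removed
#' (go dark); cells inside are unchanged.
#'
#' @param chart a `retisim_chart`.
#' @param region region name (see [chart_regions()]) or a region object.
#' @param padding passed to [chart_regions()].
#' @return a `retisim_chart` restricted to the region.
#' @export
select_region <- function(chart, region = "whole", padding = 0.1) {
  if (is.character(region)) {
    regs <- chart_regions(chart, padding)
    if (!region %in% names(regs))
      stop_retisim(sprintf("unknown region '%s'", region),
                   "retisim_region_error")
    region <- regs[[region]]
  }
  bb <- region$bbox
  cx <- (chart$cells$x0 + chart$cells$x1) / 2
  cy <- (chart$cells$y0 + chart$cells$y1) / 2
  keep <- cx >= bb["x0"] & cx <= bb["x1"] & cy >= bb["y0"] & cy <= bb["y1"]
  chart$cells <- chart$cells[keep, ]
  chart$lit_area <- sum((chart$cells$x1 - chart$cells$x0) *
                          (chart$cells$y1 - chart$cells$y0))
  chart$region <- region$name
  chart$bbox <- bb
  chart
}

#' Monte-Carlo sample of the emissive chart
#'
#' Uniform samples over the lit area: a cell is drawn with probability
#' proportional to its area, then a point uniformly within it. Total power
#' is `luminance * lit_area`, split equally over the samples so that the
#' per-sample powers sum to it exactly.
#'
#' @param chart a (possibly region-masked) `retisim_chart`.
#' @param n_samples number of source points (>= 1).
#' @param seed integer seed; identical seeds give identical sample sets.
#' @return object of class `retisim_source`: `points` (n x 2 matrix, mm),
#'   `z` (chart plane, mm), `power_per_point`, `total_power`, `lit_area`.
#' @export
sample_source <- function(chart, n_samples, seed = 1) {
  if (nrow(chart$cells) == 0)
    stop_retisim("region has no lit pixels", "retisim_empty_region_error")
  if (n_samples < 1) stop_retisim("n_samples must be >= 1",
                                  "retisim_config_error")
  cells <- chart$cells
  areas <- (cells$x1 - cells$x0) * (cells$y1 - cells$y0)
  pts <- with_seed(seed, {
    idx <- sample.int(nrow(cells), n_samples, replace = TRUE,
                      prob = areas / sum(areas))
    cbind(x = cells$x0[idx] + runif(n_samples) * (cells$x1 - cells$x0)[idx],
          y = cells$y0[idx] + runif(n_samples) * (cells$y1 - cells$y0)[idx],
          cell = idx)
  })
  total <- chart$spec$luminance * chart$lit_area
  structure(list(points = pts[, 1:2, drop = FALSE],
                 cell = pts[, 3],
                 letter = cells$letter[pts[, 3]],
                 row = cells$row[pts[, 3]],
                 z = -chart$spec$distance,
                 power_per_point = total / n_samples,
                 total_power = total,
                 lit_area = chart$lit_area,
                 region = chart$region,
                 seed = seed),
            class = "retisim_source",
            chart_extent = list(x = max(abs(chart$extent$xlim)),
                                y = max(abs(chart$extent$ylim))))
}

#' Rasterize a chart to a binary matrix
#'
#' @param x a `retisim_chart`.
#' @param res pixels along the larger chart dimension.
#' @param ... unused.
#' @return binary integer matrix (row 1 = top of the chart).
#' @export
as.matrix.retisim_chart <- function(x, res = 256, ...) {
  ex <- x$extent
  w <- diff(ex$xlim); h <- diff(ex$ylim)
  px <- max(w, h) / res
  nx <- max(1L, ceiling(w / px)); ny <- max(1L, ceiling(h / px))
  m <- matrix(0L, nrow = ny, ncol = nx)
  xc <- ex$xlim[1] + (seq_len(nx) - 0.5) * px
  yc <- ex$ylim[2] - (seq_len(ny) - 0.5) * px
  for (i in seq_len(nrow(x$cells))) {
    cc <- x$cells[i, ]
    m[yc >= cc$y0 & yc <= cc$y1, xc >= cc$x0 & xc <= cc$x1] <- 1L
  }
  m
}
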