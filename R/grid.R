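#' Create an elevation grid (DTM patch)
#'
#' Centimetre-scale digital terrain model patch. Heights are metres; `NA`
#' marks nodata. The matrix is stored with row 1 at the southern (minimum-y)
#' edge; the origin is the lower-left corner of the lower-left cell.
#'
#' @param heights Numeric matrix of heights, m (`NA` = nodata).
#' @param cell_size Cell edge length, m (default 0.01).
#' @param origin Lower-left corner `c(x, y)`, m.
#' @param transect Transect identifier.
#' @param location Location label (e.g. `"control"`, `"east"`, `"west"`).
#' @return An object of class `elevation_grid`.
#' @export
elevation_grid <- function(heights, cell_size = 0.01, origin = c(0, 0),
                           transect = NA_character_,
                           location = NA_character_) {
  if (!is.matrix(heights) || !is.numeric(heights)) {
    abort("`heights` must be a numeric matrix")
  }
  check_positive(cell_size, "cell_size")
  if (any(is.infinite(heights))) abort("heights must be finite or NA")
  structure(
    list(
      heights = heights,
      cell_size = cell_size,
      origin = c(x = origin[[1]], y = origin[[2]]),
      transect = transect,
      location = location
    ),
    class = "elevation_grid"
  )
}

#' @export
print.elevation_grid <- function(x, ...) {
  cat(sprintf("<elevation_grid> %d x %d cells of %.3f m", nrow(x$heights),
              ncol(x$heights), x$cell_size))
  if (!is.na(x$transect)) cat(sprintf(" | transect %s", x$transect))
  if (!is.na(x$location)) cat(sprintf(" (%s)", x$location))
  cat(sprintf("\n  height range %.4f to %.4f m (%d nodata cells)\n",
              suppressWarnings(min(x$heights, na.rm = TRUE)),
              suppressWarnings(max(x$heights, na.rm = TRUE)),
              sum(is.na(x$heights))))
  invisible(x)
}

#' @exportS3Method generics::tidy
#' @rdname elevation_grid
#' @param x An `elevation_grid`.
#' @param ... Unused.
tidy.elevation_grid <- function(x, ...) {
  cs <- x$cell_size
  ny <- nrow(x$heights)
  nx <- ncol(x$heights)
  tibble(
    x_m = rep(x$origin[["x"]] + (seq_len(nx) - 0.5) * cs, each = ny),
    y_m = rep(x$origin[["y"]] + (seq_len(ny) - 0.5) * cs, times = nx),
    height_m = as.vector(x$heights),
    transect = x$transect,
    location = x$location
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.elevation_grid <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$x_m, .data$y_m)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$height_m)) +
    ggplot2::scale_fill_viridis_c(name = "height (m)", na.value = "grey80") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster interchange format with the standard six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`)
#' followed by rows of cell values from the northern edge southwards.
#'
#' @param path File path (conventionally `.asc`).
#' @param transect,location Optional labels attached to the grid on read.
#' @return `read_ascii_grid()` returns an [elevation_grid()].
#' @export
read_ascii_grid <- function(path, transect = NA_character_,
                            location = NA_character_) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr))) {
    abort(sprintf("not an ESRI ASCII grid: missing header field(s) %s",
                  paste(setdiff(need, names(hdr)), collapse = ", ")))
  }
  vals <- scan(path, skip = 6, quiet = TRUE)
  nx <- hdr$ncols
  ny <- hdr$nrows
  if (length(vals) != nx * ny) {
    abort(sprintf("expected %d cell values, found %d", nx * ny, length(vals)))
  }
  # file rows run north to south; flip so row 1 is the southern edge
  m <- matrix(vals, nrow = ny, ncol = nx, byrow = TRUE)[ny:1, , drop = FALSE]
  m[m == hdr$nodata_value] <- NA_real_
  elevation_grid(m, cell_size = hdr$cellsize,
                 origin = c(hdr$xllcorner, hdr$yllcorner),
                 transect = transect, location = location)
}

#' @rdname read_ascii_grid
#' @param grid An [elevation_grid()].
#' @param nodata Value written for `NA` cells (default -9999).
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "elevation_grid"))
  m <- grid$heights
  m[is.na(m)] <- nodata
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", grid$origin[["x"]]),
    sprintf("yllcorner %.10g", grid$origin[["y"]]),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  # write rows from the northern edge southwards
  for (i in rev(seq_len(nrow(m)))) {
    writeLines(paste(format(m[i, ], digits = 10, trim = TRUE,
                            scientific = FALSE), collapse = " "), con)
  }
  invisible(path)
}
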