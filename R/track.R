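#' Create a collector track polyline
#'
#' @param vertices A data frame (or matrix) with columns `x_m`, `y_m`, local
#'   planar metres (x east, y north).
#' @return A tibble of class `track_path` with columns `x_m`, `y_m`.
#' @export
track_path <- function(vertices) {
  v <- as_tibble(as.data.frame(vertices))
  if (!all(c("x_m", "y_m") %in% names(v))) {
    if (ncol(v) == 2) names(v) <- c("x_m", "y_m") else
      abort("`vertices` needs columns `x_m` and `y_m`")
  }
  v <- v[, c("x_m", "y_m")]
  if (nrow(v) < 2) abort("a track needs at least 2 vertices")
  if (any(!is.finite(v$x_m)) || any(!is.finite(v$y_m))) {
    abort("track vertices must be finite")
  }
  seg <- sqrt(diff(v$x_m)^2 + diff(v$y_m)^2)
  if (any(seg == 0)) abort("consecutive track vertices must be distinct")
  structure(v, class = c("track_path", class(v)))
}

#' Total length of a track polyline, m
#' @param track A [track_path()].
#' @export
track_length <- function(track) {
  sum(sqrt(diff(track$x_m)^2 + diff(track$y_m)^2))
}

#' Reconstruct the collector-test loop track
#'
#' The test vehicle drove roughly one nautical mile north, made a 180-degree
#' looped turn, and returned south on a parallel leg. This builds that loop as
#' a polyline: a northward leg, a semicircular turn discretized at no more
#' than 5 degrees per vertex, and the return leg.
#'
#' @param length_m Length of each straight leg, m (default 1850).
#' @param turn_radius_m Radius of the looped turn, m (default 100). Set to 0
#'   for a single straight leg.
#' @return A [track_path()].
#' @export
#' @examples
#' tr <- gen_track()
#' track_length(tr) # ~ 2 * 1850 + pi * 100
gen_track <- function(length_m = 1850, turn_radius_m = 100) {
  check_positive(length_m, "length_m")
  check_nonnegative(turn_radius_m, "turn_radius_m")
  if (turn_radius_m == 0) {
    return(track_path(tibble(x_m = c(0, 0), y_m = c(0, length_m))))
  }
  # turn centre at (r, length); semicircle from heading north to heading south
  theta <- seq(pi, 0, length.out = ceiling(180 / 5) + 1)
  arc_x <- turn_radius_m + turn_radius_m * cos(theta)
  arc_y <- length_m + turn_radius_m * sin(theta)
  x <- c(0, arc_x, 2 * turn_radius_m)
  y <- c(0, arc_y, 0)
  keep <- c(TRUE, sqrt(diff(x)^2 + diff(y)^2) > 1e-12)
  track_path(tibble(x_m = x[keep], y_m = y[keep]))
}

#' Area enclosed by a (closed or open) track polygon, m^2
#'
#' Shoelace area of the polygon obtained by closing the polyline; used as an
#' order-of-magnitude check of the disturbed area of the looped test track.
#' @param track A [track_path()].
#' @export
track_enclosed_area <- function(track) {
  x <- track$x_m
  y <- track$y_m
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Read / write a track polyline CSV
#'
#' Two-column CSV (`x_m`, `y_m`), header required, local planar metres.
#' @param path File path.
#' @return `read_track_csv()` returns a [track_path()].
#' @export
read_track_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("x_m", "y_m") %in% names(df))) {
    abort("track CSV must have header columns `x_m` and `y_m`")
  }
  track_path(df)
}

#' @rdname read_track_csv
#' @param track A [track_path()].
#' @export
write_track_csv <- function(track, path) {
  readr::write_csv(as_tibble(track)[, c("x_m", "y_m")], path)
  invisible(path)
}

# Discretize the polyline into release points: pieces of at most `spacing`
# metres; a release sits at each piece midpoint and carries the piece length.
# Returns tibble(x, y, len).
track_release_points <- function(track, spacing) {
  x <- track$x_m
  y <- track$y_m
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  n_piece <- max(1L, ceiling(total / spacing))
  bounds <- seq(0, total, length.out = n_piece + 1)
  mids <- (bounds[-1] + bounds[-length(bounds)]) / 2
  lens <- diff(bounds)
  px <- stats::approx(cum, x, xout = mids)$y
  py <- stats::approx(cum, y, xout = mids)$y
  tibble(x = px, y = py, len = lens)
}

# Minimum distance from points (px, py) to the track polyline. Vectorized over
# points, looped over segments (tracks have few segments).
dist_to_track <- function(px, py, track) {
  x <- track$x_m
  y <- track$y_m
  d2 <- rep(Inf, length(px))
  for (i in seq_len(length(x) - 1)) {
    ax <- x[i]; ay <- y[i]
    bx <- x[i + 1]; by <- y[i + 1]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    d2 <- pmin(d2, (px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
  }
  sqrt(d2)
}
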