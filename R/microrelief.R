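# summed-area table with a leading zero row/column, so that the sum over the
# block [i1..i2, j1..j2] is S[i2+1,j2+1] - S[i1,j2+1] - S[i2+1,j1] + S[i1,j1]
.sat <- function(m) {
  s <- apply(m, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  rbind(0, cbind(0, s))
}

.box_sum <- function(sat, half, nr, nc) {
  core_i <- (half + 1):(nr - half)
  core_j <- (half + 1):(nc - half)
  sat[core_i + half + 1, core_j + half + 1, drop = FALSE] -
    sat[core_i - half, core_j + half + 1, drop = FALSE] -
    sat[core_i + half + 1, core_j - half, drop = FALSE] +
    sat[core_i - half, core_j - half, drop = FALSE]
}

#' Moving-window micro-relief (local standard deviation)
#'
#' Micro-relief is the sample standard deviation of DTM heights within a
#' centred square moving window — at the default 9 x 9 cells of a 1 cm DTM,
#' a 9 x 9 cm window, roughly the footprint of a single nodule. It measures
#' how far nodules protrude above the surrounding sediment. Cells whose
#' window extends past the grid margin or covers any nodata cell are set to
#' nodata; windows never shrink.
#'
#' @param grid An [elevation_grid()].
#' @param window_cells Window edge length in cells; odd, default 9.
#' @return An `elevation_grid` whose heights are the windowed standard
#'   deviations (m), same geometry and labels as the input.
#' @export
#' @examples
#' g <- elevation_grid(matrix(rnorm(900), 30), cell_size = 0.01)
#' sd_grid <- local_sd(g)
local_sd <- function(grid, window_cells = 9) {
  stopifnot(inherits(grid, "elevation_grid"))
  w <- as.integer(window_cells)
  if (w < 1 || w %% 2 != 1) abort("`window_cells` must be a positive odd integer")
  h <- grid$heights
  nr <- nrow(h)
  nc <- ncol(h)
  if (w > nr || w > nc) abort("window is larger than the grid")
  valid <- is.finite(h)
  # centre heights to avoid cancellation in the sum-of-squares update
  z <- h - mean(h[valid])
  z[!valid] <- 0
  half <- (w - 1L) %/% 2L
  n_in <- .box_sum(.sat(valid * 1), half, nr, nc)
  s1 <- .box_sum(.sat(z), half, nr, nc)
  s2 <- .box_sum(.sat(z * z), half, nr, nc)
  n <- w * w
  v <- (s2 - s1^2 / n) / (n - 1)
  out_core <- sqrt(pmax(v, 0))
  out_core[n_in < n] <- NA_real_
  out <- matrix(NA_real_, nr, nc)
  out[(half + 1):(nr - half), (half + 1):(nc - half)] <- out_core
  out[!valid] <- NA_real_
  elevation_grid(out, cell_size = grid$cell_size, origin = grid$origin,
                 transect = grid$transect, location = grid$location)
}

#' Subsample maxima of a micro-relief grid
#'
#' Randomly partitions the valid micro-relief cells of one transect into
#' `n_bins` near-equal subsamples without replacement and takes the maximum
#' of each, isolating the largest height contrast between sediment and
#' nodules per subsample. When the cell count is not a multiple of `n_bins`,
#' the first `count %% n_bins` bins receive one extra cell. Deterministic
#' given `seed`.
#'
#' @param micro An [elevation_grid()] of micro-relief values (from
#'   [local_sd()]).
#' @param n_bins Number of subsamples (default 20).
#' @param seed Integer RNG seed.
#' @return A tibble with columns `location`, `transect`, `subsample`
#'   (1..`n_bins`) and `max_m`.
#' @export
subsample_maxima <- function(micro, n_bins = 20, seed = 1) {
  stopifnot(inherits(micro, "elevation_grid"))
  vals <- micro$heights[is.finite(micro$heights)]
  n <- length(vals)
  if (n < n_bins) {
    abort(sprintf("only %d valid cells for %d subsamples", n, n_bins))
  }
  perm <- withr::with_seed(seed, sample.int(n))
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin <- rep(seq_len(n_bins), times = sizes)
  maxima <- vapply(split(vals[perm], bin), max, numeric(1))
  tibble(
    location = micro$location,
    transect = micro$transect,
    subsample = seq_len(n_bins),
    max_m = unname(maxima)
  )
}

#' Micro-relief subsample maxima for a set of transect DTMs
#'
#' Convenience wrapper running [local_sd()] and [subsample_maxima()] over a
#' list of transect DTM patches. Each transect uses its own RNG stream
#' derived from `seed` plus its position in the list.
#'
#' @param grids List of [elevation_grid()] objects (one per transect).
#' @param window_cells Passed to [local_sd()].
#' @param n_bins,seed Passed to [subsample_maxima()].
#' @return A tibble of subsample maxima across all transects.
#' @export
microrelief_maxima <- function(grids, window_cells = 9, n_bins = 20,
                               seed = 1) {
  purrr::imap_dfr(grids, function(g, i) {
    subsample_maxima(local_sd(g, window_cells), n_bins = n_bins,
                     seed = seed + as.integer(i))
  })
}

#' Compare micro-relief between locations
#'
#' Omnibus Kruskal-Wallis test of the subsample maxima across locations,
#' followed by pairwise two-sided rank-sum tests with Holm adjustment.
#'
#' @param maxima A data frame with columns `location` and `max_m` (from
#'   [subsample_maxima()] or [microrelief_maxima()]).
#' @param value,group Column names (strings) of the response and grouping
#'   variables; defaults `"max_m"` and `"location"`.
#' @return A `location_comparison` object; see [tidy()] for the pairwise
#'   table and [glance()] for the omnibus test.
#' @export
compare_locations <- function(maxima, value = "max_m", group = "location") {
  df <- as_tibble(maxima)
  if (!all(c(value, group) %in% names(df))) {
    abort(sprintf("`maxima` needs columns `%s` and `%s`", value, group))
  }
  groups <- split(df[[value]], df[[group]])
  if (length(groups) < 2) abort("need at least 2 locations to compare")
  if (any(lengths(groups) < 2)) abort("every location needs at least 2 values")
  omni <- kruskal_wallis(df, value = value, group = group)
  pairs <- utils::combn(names(groups), 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]
    b <- pairs[2, k]
    rs <- rank_sum(groups[[a]], groups[[b]])
    tibble(group1 = a, group2 = b, statistic = rs$statistic,
           p.value = rs$p.value, method = rs$method)
  })
  pw$p.adjusted <- holm_adjust(pw$p.value)
  structure(list(omnibus = omni, pairwise = pw), class = "location_comparison")
}

#' @export
print.location_comparison <- function(x, ...) {
  cat("Kruskal-Wallis omnibus test\n")
  print(x$omnibus)
  cat("\nPairwise rank-sum tests (Holm-adjusted)\n")
  print(x$pairwise)
  invisible(x)
}

#' @exportS3Method generics::tidy
#' @rdname compare_locations
#' @param x A `location_comparison`.
#' @param ... Unused.
tidy.location_comparison <- function(x, ...) x$pairwise

#' @exportS3Method generics::glance
#' @rdname compare_locations
glance.location_comparison <- function(x, ...) x$omnibus

#' @exportS3Method ggplot2::autoplot
autoplot.location_comparison <- function(object, data = NULL, ...) {
  if (is.null(data)) abort("pass the maxima table via `data` to plot")
  ggplot2::ggplot(data, ggplot2::aes(.data$location, 1e3 * .data$max_m)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "subsample maximum micro-relief (mm)")
}
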