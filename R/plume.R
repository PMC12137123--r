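#' Create an empty deposition map
#'
#' A deposition map is a regular grid of deposited sediment mass per unit
#' area (kg m^-2). Thickness is derived as `mass / rho_dry_deposit`. Cells
#' own the half-open square `[x, x + cell) x [y, y + cell)`; the matrix is
#' stored with row 1 at the southern (minimum-y) edge.
#'
#' @param xmin,ymin Coordinates of the lower-left corner, m.
#' @param nx,ny Number of columns (east) and rows (north).
#' @param cell_size Cell edge length, m.
#' @param rho_dry_deposit Dry bulk density of the fresh deposit, kg m^-3.
#' @return An object of class `deposition_map`.
#' @export
deposition_map <- function(xmin, ymin, nx, ny, cell_size,
                           rho_dry_deposit = 500) {
  check_positive(cell_size, "cell_size")
  check_positive(rho_dry_deposit, "rho_dry_deposit")
  structure(
    list(
      mass = matrix(0, nrow = ny, ncol = nx),
      origin = c(x = xmin, y = ymin),
      cell_size = cell_size,
      rho_dry_deposit = rho_dry_deposit,
      released_mass = 0,
      residual_mass = 0,
      off_grid_mass = 0
    ),
    class = "deposition_map"
  )
}

# map bounding a track, padded on all sides
deposition_map_for_track <- function(track, cell_size, pad = 150,
                                     rho_dry_deposit = 500) {
  xmin <- min(track$x_m) - pad
  xmax <- max(track$x_m) + pad
  ymin <- min(track$y_m) - pad
  ymax <- max(track$y_m) + pad
  deposition_map(xmin, ymin,
                 nx = ceiling((xmax - xmin) / cell_size),
                 ny = ceiling((ymax - ymin) / cell_size),
                 cell_size, rho_dry_deposit)
}

#' @export
print.deposition_map <- function(x, ...) {
  cat(sprintf("<deposition_map> %d x %d cells of %.2f m\n",
              nrow(x$mass), ncol(x$mass), x$cell_size))
  cat(sprintf("  max thickness %.3f mm, deposited %.1f kg (residual %.2f, off-grid %.2f)\n",
              1e3 * max(x$mass) / x$rho_dry_deposit,
              sum(x$mass) * x$cell_size^2, x$residual_mass, x$off_grid_mass))
  invisible(x)
}

#' @exportS3Method generics::tidy
#' @rdname deposition_map
#' @param x A `deposition_map`.
#' @param ... Unused.
tidy.deposition_map <- function(x, ...) {
  cs <- x$cell_size
  ny <- nrow(x$mass)
  nx <- ncol(x$mass)
  tibble(
    x_m = rep(x$origin[["x"]] + (seq_len(nx) - 0.5) * cs, each = ny),
    y_m = rep(x$origin[["y"]] + (seq_len(ny) - 0.5) * cs, times = nx),
    mass_kg_m2 = as.vector(x$mass),
    thickness_mm = as.vector(x$mass) / x$rho_dry_deposit * 1e3
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.deposition_map <- function(object, track = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x_m, .data$y_m)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$thickness_mm)) +
    ggplot2::scale_fill_viridis_c(name = "deposit (mm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)")
  if (!is.null(track)) {
    p <- p + ggplot2::geom_path(
      data = as_tibble(track),
      ggplot2::aes(.data$x_m, .data$y_m),
      colour = "white", linewidth = 0.3
    )
  }
  p
}

# ---------------------------------------------------------------------------
# Axisymmetric fixed-volume box model of one particle-laden release.
#
# State: front radius R, per-class concentrations C_k; volume V constant.
#   h   = V / (pi R^2)
#   g'  = g * sum(C_k) * (rho_s - rho_w) / (rho_w * rho_s)
#   dR/dt  = Fr * sqrt(g' h)
#   dC_k/dt = -w_k C_k / h        (deposit flux w_k C_k under the footprint)
# Integrated with Heun's method and an exponential update for C; the step is
# capped so the front advances < dr_max, < 5% of R, and the fastest class
# loses < 20% of its concentration per step. Terminates when the suspension
# is exhausted (sum C < eps_C * C_d) or the current has collapsed
# (h < h_min). Because R is non-decreasing, the deposit is a monotone radial
# profile: D(r) = sum of per-step deposit increments laid down while the
# front was beyond r.
release_profile <- function(scenario, release_mass, dr_max = 1,
                            eps_C = 1e-6, h_min = 0.01,
                            max_steps = 500000L) {
  check_positive(release_mass, "release_mass")
  Cd <- scenario$discharge_concentration
  V <- release_mass / Cd
  w <- scenario$settling$ws
  C0 <- scenario$settling$fraction * Cd
  C <- C0
  buoy <- .G * (scenario$rho_s - scenario$rho_w) /
    (scenario$rho_w * scenario$rho_s)
  Fr <- scenario$Fr
  R <- scenario$initial_radius
  t <- 0
  wmax <- max(w)

  cap <- 4096L
  Rs <- numeric(cap)
  dDs <- numeric(cap)
  nstep <- 0L
  termination <- "collapsed"

  repeat {
    h <- V / (pi * R^2)
    sC <- sum(C)
    if (sC < eps_C * Cd) {
      termination <- "settled"
      break
    }
    if (h < h_min) break
    u <- Fr * sqrt(buoy * sC * h)
    dt <- min(dr_max / u, 0.05 * R / u,
              if (wmax > 0) 0.2 * h / wmax else Inf)
    # predictor
    R1 <- R + u * dt
    h1 <- V / (pi * R1^2)
    C1 <- C * exp(-w * dt / h)
    u1 <- Fr * sqrt(buoy * sum(C1) * h1)
    # corrector
    Rn <- R + dt * (u + u1) / 2
    Cn <- C * exp(-w * dt * (1 / h + 1 / h1) / 2)
    if (!all(is.finite(Cn)) || !is.finite(Rn)) {
      abort("plume release integration produced non-finite state")
    }
    nstep <- nstep + 1L
    if (nstep > cap) {
      if (nstep > max_steps) abort("plume release integration did not terminate")
      cap <- cap * 2L
      length(Rs) <- cap
      length(dDs) <- cap
    }
    Rs[nstep] <- (R + Rn) / 2
    dDs[nstep] <- sum(w * (C + Cn) / 2) * dt
    R <- Rn
    C <- Cn
    t <- t + dt
  }

  Rs <- Rs[seq_len(nstep)]
  dDs <- dDs[seq_len(nstep)]
  revcum <- if (nstep) rev(cumsum(rev(dDs))) else numeric(0)
  list(
    r = Rs,                        # footprint mid-radius per step (increasing)
    cum = revcum,                  # deposit (kg m^-2) at radius <= r[i]
    r_max = if (nstep) Rs[nstep] else scenario$initial_radius,
    deposited_by_class = V * (C0 - C),
    residual_by_class = V * C,
    deposited = V * sum(C0 - C),
    residual = V * sum(C),
    volume = V,
    duration = t,
    termination = termination
  )
}

# deposit mass-per-area at radius r (vectorized); monotone non-increasing
profile_deposit_at <- function(profile, r) {
  n <- length(profile$r)
  if (n == 0L) return(rep(0, length(r)))
  # number of step radii strictly below r
  idx <- findInterval(r, profile$r, left.open = FALSE)
  # r <= r[1] -> full column; r > r[n] -> 0
  below <- pmin(idx + 1L, n + 1L)
  out <- c(profile$cum, 0)[below]
  # findInterval counts r[i] <= r; at exact breakpoints include that step
  exact <- idx >= 1L & idx <= n & r == profile$r[pmax(idx, 1L)]
  out[exact] <- profile$cum[idx[exact]]
  out
}

# add one release's radial deposit profile onto the map around (cx, cy);
# returns the map with its mass matrix updated and the painted mass.
paint_release <- function(map, profile, cx, cy) {
  cs <- map$cell_size
  ox <- map$origin[["x"]]
  oy <- map$origin[["y"]]
  nx <- ncol(map$mass)
  ny <- nrow(map$mass)
  rmax <- profile$r_max
  jlo <- max(1L, ceiling((cx - rmax - ox) / cs + 0.5 - 1e-9))
  jhi <- min(nx, floor((cx + rmax - ox) / cs + 0.5 + 1e-9))
  ilo <- max(1L, ceiling((cy - rmax - oy) / cs + 0.5 - 1e-9))
  ihi <- min(ny, floor((cy + rmax - oy) / cs + 0.5 + 1e-9))
  if (jlo > jhi || ilo > ihi) return(list(map = map, painted = 0))
  dx2 <- (ox + (jlo:jhi - 0.5) * cs - cx)^2
  dy2 <- (oy + (ilo:ihi - 0.5) * cs - cy)^2
  r <- sqrt(outer(dy2, dx2, "+"))
  d <- matrix(profile_deposit_at(profile, as.vector(r)),
              nrow = length(dy2))
  d[r > rmax] <- 0
  map$mass[ilo:ihi, jlo:jhi] <- map$mass[ilo:ihi, jlo:jhi] + d
  list(map = map, painted = sum(d) * cs^2)
}

#' Deposit a single plume release onto a map
#'
#' Integrates the axisymmetric box model with settling for one fixed-volume
#' release of suspended sediment and accumulates its deposit onto every grid
#' cell whose centre lies within the current front radius. Deposition under
#' the footprint is radially resolved: material laid down while the front was
#' small stays near the centre, so the deposit is non-increasing with
#' distance from the release point.
#'
#' @param map A [deposition_map()].
#' @param scenario A [plume_scenario()].
#' @param release_mass Suspended sediment mass in the release, kg.
#' @param centre Release centre `c(x, y)`, m.
#' @return The updated `deposition_map`; diagnostics (runout radius, painted,
#'   residual and off-grid mass) in `attr(, "diagnostics")`.
#' @export
#' @examples
#' sc <- plume_scenario(0.05, 0.05, 2.6)
#' m <- deposition_map(-60, -60, 60, 60, cell_size = 2)
#' m <- single_release_deposit(m, sc, release_mass = 800, centre = c(0, 0))
#' attr(m, "diagnostics")
single_release_deposit <- function(map, scenario, release_mass,
                                   centre = c(0, 0)) {
  stopifnot(inherits(map, "deposition_map"), inherits(scenario, "plume_scenario"))
  prof <- release_profile(scenario, release_mass, dr_max = map$cell_size)
  res <- paint_release(map, prof, centre[[1]], centre[[2]])
  map <- res$map
  off <- prof$deposited - res$painted
  map$released_mass <- map$released_mass + release_mass
  map$residual_mass <- map$residual_mass + prof$residual
  map$off_grid_mass <- map$off_grid_mass + off
  if (off > 0.01 * release_mass) {
    warn(sprintf("%.1f%% of release mass fell outside the grid",
                 100 * off / release_mass))
  }
  attr(map, "diagnostics") <- tibble(
    runout_m = prof$r_max,
    deposited_kg = prof$deposited,
    painted_kg = res$painted,
    residual_kg = prof$residual,
    off_grid_kg = off,
    duration_s = prof$duration,
    termination = prof$termination
  )
  map
}

#' Simulate plume deposition along a collector track
#'
#' Represents the moving collector as a superposition of discrete axisymmetric
#' releases spaced `release_spacing` metres apart along the track, each
#' carrying the sediment mass mobilized over its track piece
#' (see [mass_per_metre()]). Overlapping deposition from neighbouring
#' releases sums additively.
#'
#' @param track A [track_path()].
#' @param scenario A [plume_scenario()].
#' @param cell_size Grid cell size, m (default 2).
#' @param pad Padding of the grid beyond the track bounding box, m
#'   (default 150).
#' @return A [deposition_map()] covering the padded track bounding box.
#' @export
#' @examples
#' tr <- gen_track(length_m = 100, turn_radius_m = 0)
#' sc <- plume_scenario(0.05, 0.05, 2.6)
#' m <- simulate_track_plume(tr, sc, cell_size = 4)
#' summarize_deposition(m, tr)
simulate_track_plume <- function(track, scenario, cell_size = 2, pad = 150) {
  stopifnot(inherits(track, "track_path"), inherits(scenario, "plume_scenario"))
  map <- deposition_map_for_track(track, cell_size, pad,
                                  scenario$rho_dry_deposit)
  mpm <- mass_per_metre(scenario)
  if (mpm == 0) return(map)
  rel <- track_release_points(track, scenario$release_spacing)
  # release masses are identical except possibly the final short piece:
  # integrate each distinct mass once and reuse the radial profile
  masses <- mpm * rel$len
  keys <- signif(masses, 12)
  profiles <- lapply(unique(keys), function(k) {
    release_profile(scenario, k, dr_max = cell_size)
  })
  names(profiles) <- format(unique(keys), digits = 15)
  painted_total <- 0
  residual_total <- 0
  deposited_total <- 0
  for (i in seq_len(nrow(rel))) {
    prof <- profiles[[format(keys[i], digits = 15)]]
    res <- paint_release(map, prof, rel$x[i], rel$y[i])
    map <- res$map
    painted_total <- painted_total + res$painted
    residual_total <- residual_total + prof$residual
    deposited_total <- deposited_total + prof$deposited
  }
  map$released_mass <- sum(masses)
  map$residual_mass <- residual_total
  map$off_grid_mass <- deposited_total - painted_total
  map
}

#' Summarize a deposition map relative to the track
#'
#' @param map A [deposition_map()].
#' @param track The [track_path()] that generated it (same coordinate frame).
#' @param thickness_floor Thickness below which cells are ignored when
#'   measuring extent, m (default 1e-4, i.e. 0.1 mm).
#' @return One-row tibble: maximum thickness (m and mm), maximum distance from
#'   the track at which thickness reaches the floor (m), deposited mass on the
#'   grid (kg), and the release/residual/off-grid mass balance.
#' @export
summarize_deposition <- function(map, track, thickness_floor = 1e-4) {
  stopifnot(inherits(map, "deposition_map"))
  thick <- map$mass / map$rho_dry_deposit
  max_th <- if (length(thick)) max(thick) else 0
  extent <- 0
  hot <- which(thick >= thickness_floor & thick > 0)
  if (length(hot) && !is.null(track)) {
    cs <- map$cell_size
    ny <- nrow(map$mass)
    i <- (hot - 1L) %% ny + 1L
    j <- (hot - 1L) %/% ny + 1L
    px <- map$origin[["x"]] + (j - 0.5) * cs
    py <- map$origin[["y"]] + (i - 0.5) * cs
    extent <- max(dist_to_track(px, py, track))
  }
  tibble(
    max_thickness_m = max_th,
    max_thickness_mm = 1e3 * max_th,
    extent_m = extent,
    deposited_mass_kg = sum(map$mass) * map$cell_size^2,
    residual_mass_kg = map$residual_mass,
    off_grid_mass_kg = map$off_grid_mass,
    released_mass_kg = map$released_mass
  )
}
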