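#' Build a particle settling-velocity distribution
#'
#' The field measurements behind the plume scenarios report only the modal
#' settling velocity of the resuspended sediment, not its full distribution.
#' This helper expands a modal velocity into `n` log-spaced settling classes
#' spanning one decade centred on the mode, with triangular mass weights, so
#' that fine and coarse tails are both represented.
#'
#' @param mode_ws Modal settling velocity, m s^-1 (e.g. `0.6e-3` for
#'   0.6 mm s^-1).
#' @param n Number of classes (odd, default 5).
#' @param span Total span in decades (default 1, i.e. mode / sqrt(10) to
#'   mode * sqrt(10)).
#' @return A tibble with columns `ws` (m s^-1) and `fraction` (sums to 1).
#' @export
#' @examples
#' settling_classes(0.6e-3)
settling_classes <- function(mode_ws, n = 5, span = 1) {
  check_positive(mode_ws, "mode_ws")
  if (n %% 2 != 1 || n < 1) abort("`n` must be a positive odd integer")
  ws <- 10^seq(log10(mode_ws) - span / 2, log10(mode_ws) + span / 2,
               length.out = n)
  w <- (n + 1) / 2 - abs(seq_len(n) - (n + 1) / 2)
  tibble(ws = ws, fraction = w / sum(w))
}

#' Define a plume-deposition scenario
#'
#' Bundles the physical parameters of one sediment-mobilization scenario for
#' the moving-collector plume model: how much seabed the rake and the
#' propulsion furrows resuspend, the discharge concentration of the resulting
#' suspension, and the settling-velocity distribution of its particles.
#'
#' @param mobilization_depth Depth of seabed resuspended by the rake, m
#'   (scenario values 0.03, 0.05, 0.07).
#' @param furrow_fraction Fraction of the propulsion-furrow cross-section
#'   resuspended, in `[0, 1]` (scenario values 0.01, 0.05, 0.10).
#' @param discharge_concentration Suspension discharge concentration C_d,
#'   kg m^-3 (scenario values 2.31, 2.6, 5.1).
#' @param settling Data frame with columns `ws` (m s^-1) and `fraction`
#'   (non-negative, summing to 1); see [settling_classes()].
#' @param rake_width Width of the collector rake swath, m.
#' @param furrow_width,furrow_depth Width and depth of one propulsion furrow,
#'   m; there are two furrows per track.
#' @param vehicle_speed Collector speed over ground, m s^-1 (0.25-1).
#' @param Fr Frontal Froude number of the spreading gravity current.
#' @param rho_s Particle density, kg m^-3.
#' @param rho_w Ambient water density, kg m^-3.
#' @param rho_dry_insitu Dry bulk density of the undisturbed seabed, kg m^-3.
#' @param rho_dry_deposit Dry bulk density of the fresh deposit, kg m^-3
#'   (converts deposited mass per area to thickness).
#' @param release_spacing Along-track spacing of discrete plume releases, m.
#' @param initial_radius Initial radius R0 of each release, m; default
#'   `rake_width / 2 + 1`.
#' @return An object of class `plume_scenario` (a named list).
#' @export
#' @examples
#' plume_scenario(0.05, 0.05, 2.6, settling_classes(0.6e-3))
plume_scenario <- function(mobilization_depth,
                           furrow_fraction,
                           discharge_concentration,
                           settling = settling_classes(0.6e-3),
                           rake_width = 4.5,
                           furrow_width = 2.0,
                           furrow_depth = 0.5,
                           vehicle_speed = 0.5,
                           Fr = 1.19,
                           rho_s = 2650,
                           rho_w = 1025,
                           rho_dry_insitu = 500,
                           rho_dry_deposit = 500,
                           release_spacing = 5,
                           initial_radius = rake_width / 2 + 1) {
  check_nonnegative(mobilization_depth, "mobilization_depth")
  check_nonnegative(furrow_fraction, "furrow_fraction")
  if (furrow_fraction > 1) abort("`furrow_fraction` must be <= 1")
  check_positive(discharge_concentration, "discharge_concentration")
  for (nm in c("rake_width", "furrow_width", "furrow_depth", "vehicle_speed",
               "Fr", "rho_s", "rho_w", "rho_dry_insitu", "rho_dry_deposit",
               "release_spacing", "initial_radius")) {
    check_positive(get(nm), nm)
  }
  if (rho_s <= rho_w) abort("`rho_s` must exceed `rho_w`")
  settling <- as_tibble(settling)
  if (!all(c("ws", "fraction") %in% names(settling))) {
    abort("`settling` needs columns `ws` and `fraction`")
  }
  check_nonnegative(settling$ws, "settling$ws")
  check_nonnegative(settling$fraction, "settling$fraction")
  if (abs(sum(settling$fraction) - 1) > 1e-9) {
    abort("settling mass fractions must sum to 1")
  }
  structure(
    list(
      mobilization_depth = mobilization_depth,
      furrow_fraction = furrow_fraction,
      discharge_concentration = discharge_concentration,
      settling = settling,
      rake_width = rake_width,
      furrow_width = furrow_width,
      furrow_depth = furrow_depth,
      vehicle_speed = vehicle_speed,
      Fr = Fr,
      rho_s = rho_s,
      rho_w = rho_w,
      rho_dry_insitu = rho_dry_insitu,
      rho_dry_deposit = rho_dry_deposit,
      release_spacing = release_spacing,
      initial_radius = initial_radius
    ),
    class = "plume_scenario"
  )
}

#' @export
print.plume_scenario <- function(x, ...) {
  cat("<plume_scenario>\n")
  cat(sprintf("  mobilization: %.3f m rake x %.1f m + %.0f%% of 2 x %.1f x %.1f m furrows\n",
              x$mobilization_depth, x$rake_width, 100 * x$furrow_fraction,
              x$furrow_width, x$furrow_depth))
  cat(sprintf("  discharge concentration: %.3g kg m^-3\n",
              x$discharge_concentration))
  cat(sprintf("  settling classes (mm/s): %s\n",
              paste(signif(1e3 * x$settling$ws, 3), collapse = ", ")))
  cat(sprintf("  mobilized mass: %.1f kg per metre of track\n",
              mass_per_metre(x)))
  invisible(x)
}

#' Sediment mass mobilized per metre of track
#'
#' Cross-sectional sediment volume disturbed per metre of collector travel
#' (rake swath to `mobilization_depth`, plus `furrow_fraction` of the two
#' propulsion-furrow cross-sections) times the in-situ dry bulk density.
#'
#' @param scenario A [plume_scenario()].
#' @return Mass per metre of track, kg m^-1.
#' @export
#' @examples
#' mass_per_metre(plume_scenario(0.05, 0.05, 2.6)) # 162.5 kg per metre
mass_per_metre <- function(scenario) {
  stopifnot(inherits(scenario, "plume_scenario"))
  vol <- scenario$mobilization_depth * scenario$rake_width +
    scenario$furrow_fraction * 2 * scenario$furrow_width * scenario$furrow_depth
  vol * scenario$rho_dry_insitu
}

#' The three mobilization scenarios of the collector-test study design
#'
#' Returns the 3 x 3 scenario grid used for plume-envelope runs: three
#' sediment-mobilization amounts (3/5/7 cm rake depth paired with 1/5/10%
#' furrow resuspension and discharge concentrations 2.31/2.6/5.1 kg m^-3)
#' crossed with three settling distributions whose modes are 0.1, 0.6 and
#' 3.5 mm s^-1.
#'
#' @param ... Passed on to [plume_scenario()] to override shared defaults.
#' @return A tibble with columns `mobilization`, `settling_mode` and
#'   `scenario` (a list-column of [plume_scenario()] objects).
#' @export
scenario_grid <- function(...) {
  mob <- tibble(
    mobilization = c("low", "intermediate", "high"),
    depth = c(0.03, 0.05, 0.07),
    fraction = c(0.01, 0.05, 0.10),
    cd = c(2.31, 2.6, 5.1)
  )
  ws <- tibble(
    settling_mode = c("slow", "intermediate", "fast"),
    mode_ws = c(0.1e-3, 0.6e-3, 3.5e-3)
  )
  grid <- tidyr::crossing(mob, ws)
  grid$scenario <- purrr::pmap(
    list(grid$depth, grid$fraction, grid$cd, grid$mode_ws),
    function(d, f, cd, w) {
      plume_scenario(d, f, cd, settling = settling_classes(w), ...)
    }
  )
  select(grid, "mobilization", "settling_mode", "scenario")
}
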