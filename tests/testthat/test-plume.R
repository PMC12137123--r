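test_that("nothing settles when all settling velocities are zero", {
  still <- tibble::tibble(ws = c(0, 0), fraction = c(0.5, 0.5))
  sc <- toy_scenario(settling = still)
  m <- deposition_map(-60, -60, 60, 60, cell_size = 2)
  m <- single_release_deposit(m, sc, release_mass = 500)
  expect_equal(sum(m$mass), 0)
  expect_equal(m$residual_mass, 500, tolerance = 1e-12)
})

test_that("single-release deposit matches an independent stiff ODE solution", {
  skip_if_not_installed("deSolve")
  # one class, w = 0.6 mm/s, V = 10 m^3 at C_d = 2.6 -> 26 kg released
  sc <- toy_scenario(settling = tibble::tibble(ws = 6e-4, fraction = 1),
                     initial_radius = 1)
  prof <- trackrec:::release_profile(sc, 26, dr_max = 0.5)
  expect_equal(prof$deposited + prof$residual, 26, tolerance = 1e-9)
  expect_equal(prof$deposited, 26, tolerance = 0.005 * 26)

  V <- 10
  w <- sc$settling$ws
  buoy <- 9.81 * (sc$rho_s - sc$rho_w) / (sc$rho_w * sc$rho_s)
  rhs <- function(t, y, p) {
    h <- V / (pi * y[1]^2)
    list(c(sc$Fr * sqrt(buoy * y[2] * h), -w * y[2] / h, w * y[2]))
  }
  out <- deSolve::lsoda(c(R = 1, C = 2.6, D = 0),
                        seq(0, prof$duration, length.out = 5000),
                        rhs, rtol = 1e-10, atol = 1e-13)
  fin <- out[nrow(out), ]
  # per-class totals within 0.5% of the oracle
  expect_equal(prof$deposited, V * (2.6 - fin[["C"]]), tolerance = 0.005)
  expect_equal(prof$r_max, fin[["R"]], tolerance = 0.005)
  # centre deposit (full time integral of w*C) agrees too
  expect_equal(prof$cum[1], fin[["D"]], tolerance = 0.005)
})

test_that("a multi-class release agrees per class with a fine-timestep rerun", {
  sc <- toy_scenario()
  coarse <- trackrec:::release_profile(sc, 800, dr_max = 2)
  fine <- trackrec:::release_profile(sc, 800, dr_max = 0.2)
  expect_equal(coarse$deposited_by_class, fine$deposited_by_class,
               tolerance = 0.005)
  expect_equal(coarse$r_max, fine$r_max, tolerance = 0.005)
})

test_that("single-release deposit decreases with distance from the centre", {
  for (mode in c(1e-4, 6e-4, 3.5e-3)) {
    sc <- toy_scenario(settling = settling_classes(mode))
    prof <- trackrec:::release_profile(sc, 800, dr_max = 1)
    r <- seq(0, prof$r_max, by = 0.5)
    d <- trackrec:::profile_deposit_at(prof, r)
    expect_true(all(diff(d) <= 1e-12))
    expect_true(all(d >= 0))
  }
})

test_that("released mass is conserved on a grid containing the runout", {
  sc <- toy_scenario()
  m <- deposition_map(-120, -120, 240, 240, cell_size = 1)
  m <- single_release_deposit(m, sc, release_mass = 812.5)
  painted <- sum(m$mass) * m$cell_size^2
  bal <- abs(painted + m$residual_mass - 812.5) / 812.5
  expect_lt(bal, 1e-3)
})

test_that("increasing every settling velocity never increases the runout", {
  sc1 <- toy_scenario(settling = settling_classes(0.3e-3))
  sc2 <- toy_scenario(settling = settling_classes(1.2e-3))
  p1 <- trackrec:::release_profile(sc1, 800, dr_max = 1)
  p2 <- trackrec:::release_profile(sc2, 800, dr_max = 1)
  expect_lte(p2$r_max, p1$r_max)
  # and the extent of >= 0.1 mm deposit shrinks as well
  ext <- function(p, rho = 500) {
    r <- seq(0, p$r_max, by = 0.25)
    d <- trackrec:::profile_deposit_at(p, r) / rho
    max(c(0, r[d >= 1e-4]))
  }
  expect_lte(ext(p2), ext(p1))
})

test_that("track simulation conserves mass and honours zero mobilization", {
  tr <- gen_track(length_m = 120, turn_radius_m = 0)
  sc <- toy_scenario()
  m <- simulate_track_plume(tr, sc, cell_size = 2, pad = 120)
  expected <- mass_per_metre(sc) * track_length(tr)
  expect_equal(m$released_mass, expected, tolerance = 1e-9)
  painted <- sum(m$mass) * m$cell_size^2
  expect_lt(abs(painted + m$residual_mass + m$off_grid_mass - expected) /
              expected, 1e-6)
  # the grid pad exceeds the runout, so nearly nothing leaves the grid
  expect_lt(abs(m$off_grid_mass) / expected, 1e-3)

  silent <- plume_scenario(0, 0, 2.6)
  m0 <- simulate_track_plume(tr, silent, cell_size = 4)
  expect_equal(sum(m0$mass), 0)
})

test_that("halving the cell size barely changes the maximum thickness", {
  tr <- gen_track(length_m = 100, turn_radius_m = 0)
  sc <- toy_scenario()
  s2 <- summarize_deposition(simulate_track_plume(tr, sc, cell_size = 2,
                                                  pad = 80), tr)
  s1 <- summarize_deposition(simulate_track_plume(tr, sc, cell_size = 1,
                                                  pad = 80), tr)
  expect_equal(s1$max_thickness_mm, s2$max_thickness_mm, tolerance = 0.05)
})

test_that("deposition summaries read off the map correctly", {
  tr <- track_path(data.frame(x_m = c(0, 0), y_m = c(0, 100)))
  m <- deposition_map(-50, -50, 50, 40, cell_size = 2)
  s0 <- summarize_deposition(m, tr)
  expect_equal(s0$max_thickness_m, 0)
  expect_equal(s0$extent_m, 0)

  # one cell, 4 mm thickness, east of the track line beside its middle
  j <- which.min(abs(-50 + (seq_len(50) - 0.5) * 2 - 30))
  i <- which.min(abs(-50 + (seq_len(40) - 0.5) * 2 - 20))
  px <- -50 + (j - 0.5) * 2  # the cell centre's offset is the distance
  m$mass[i, j] <- 0.004 * m$rho_dry_deposit
  s <- summarize_deposition(m, tr)
  expect_equal(s$max_thickness_mm, 4)
  expect_equal(s$extent_m, px)
  expect_equal(s$deposited_mass_kg, sum(m$mass) * 4)
})

test_that("deposition maps tidy to per-cell tibbles in map units", {
  m <- deposition_map(0, 0, 3, 2, cell_size = 2, rho_dry_deposit = 400)
  m$mass[2, 3] <- 2
  df <- tidy(m)
  expect_equal(nrow(df), 6)
  hot <- dplyr::filter(df, mass_kg_m2 > 0)
  expect_equal(hot$x_m, 5)
  expect_equal(hot$y_m, 3)
  expect_equal(hot$thickness_mm, 2 / 400 * 1e3)
})
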