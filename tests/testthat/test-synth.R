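test_that("generators are deterministic given a seed", {
  cfg <- small_synth_config()
  expect_identical(gen_dtm(cfg, seed = 4)$heights, gen_dtm(cfg, seed = 4)$heights)
  a <- gen_annotations(cfg, seed = 4)
  b <- gen_annotations(cfg, seed = 4)
  expect_identical(a, b)
  expect_identical(gen_biogeochem(cfg, seed = 4), gen_biogeochem(cfg, seed = 4))
  expect_false(identical(gen_dtm(cfg, seed = 4)$heights,
                         gen_dtm(cfg, seed = 5)$heights))
})

test_that("a noiseless nodule-free patch is perfectly flat", {
  cfg <- small_synth_config(noise_sd_m = 0, nodule_density_m2 = 0)
  g <- gen_dtm(cfg, seed = 1)
  expect_true(all(g$heights == 0))
  lifted <- gen_dtm(small_synth_config(noise_sd_m = 0, nodule_density_m2 = 0,
                                       infill_depth_m = 0.004), seed = 1)
  expect_true(all(lifted$heights == 0.004))
})

test_that("nodule cover matches the Poisson placement geometry", {
  # zero noise: a cell is raised iff a nodule cap covers it, so the raised
  # fraction estimates Boolean-model coverage 1 - exp(-density * E[footprint])
  cfg <- synth_config(dtm_extent_m = c(3, 3), noise_sd_m = 0)
  g <- gen_dtm(cfg, seed = 2)
  frac <- mean(g$heights > 0)
  erho2 <- (0.25 - (0.5 - cfg$protrusion_fraction)^2) *
    (cfg$nodule_size_mean_mm^2 + cfg$nodule_size_sd_mm^2) / 1e6
  expected <- 1 - exp(-cfg$nodule_density_m2 * pi * erho2)
  expect_equal(frac, expected, tolerance = 0.1)
  # and nodules protrude by about protrusion_fraction x diameter
  expect_gt(max(g$heights), 0.015)
  expect_lt(max(g$heights), 0.4 * 0.152 + 1e-6)
})

test_that("heavy infill buries nodule relief down to the noise floor", {
  cfg0 <- small_synth_config(nodule_density_m2 = 0)
  deep <- 0.4 * (72 + 4 * 19) / 1e3   # infill above any protrusion
  cfg1 <- small_synth_config(infill_depth_m = deep)
  noise_only <- subsample_maxima(local_sd(gen_dtm(cfg0, seed = 6)), seed = 6)
  buried <- subsample_maxima(local_sd(gen_dtm(cfg1, seed = 6)), seed = 6)
  res <- rank_sum(noise_only$max_m, buried$max_m, exact_threshold = 12)
  expect_gt(res$p.value, 0.01)
})

test_that("annotation tables honour densities, composition and filters", {
  cfg <- small_synth_config()
  ia <- gen_annotations(cfg, seed = 3)
  expect_equal(nrow(ia$images),
               length(cfg$treatment_densities) * 4 * cfg$images_per_transect)
  expect_true(all(ia$images$area_m2 > 0))
  # consumed without error downstream
  kept <- filter_annotations(ia$annotations, ia$images)
  expect_true(all(kept$size_mm > 20))
  expect_false(any(kept$tube_or_shell_dweller))

  # a zero-density treatment generates no annotations at all
  cfg0 <- small_synth_config(
    treatment_densities = c(control = 0.33, empty = 0)
  )
  cfg0$composition <- list(control = c(mt01 = 1), empty = c(mt01 = 1))
  ia0 <- gen_annotations(cfg0, seed = 3)
  imgs_empty <- ia0$images$image_id[ia0$images$treatment == "empty"]
  expect_equal(sum(ia0$annotations$image_id %in% imgs_empty), 0)
})

test_that("biogeochemical generators round-trip through the conversions", {
  cfg <- synth_config()
  means_bio <- matrix(NA_real_, 50, 2)
  means_assim <- matrix(NA_real_, 50, 2)
  dens <- numeric(50)
  for (s in 1:50) {
    bio <- gen_biogeochem(cfg, seed = s)
    bm <- tapply(bacterial_biomass(bio$plfa$plfa_c_mg_m2),
                 bio$plfa$site_class, mean)
    as <- tapply(c_assimilation(bio$plfa$inc13c_mg_m2),
                 bio$plfa$site_class, mean)
    means_bio[s, ] <- bm[c("track", "off_track")]
    means_assim[s, ] <- as[c("track", "off_track")]
    dens[s] <- nodule_metrics(bio$nodules)$pooled$pooled_density_m2
  }
  se <- function(x) sd(x) / sqrt(length(x))
  expect_lt(abs(mean(means_bio[, 1]) - 92), 3 * se(means_bio[, 1]))
  expect_lt(abs(mean(means_bio[, 2]) - 52), 3 * se(means_bio[, 2]))
  expect_lt(abs(mean(means_assim[, 1]) - 0.032), 3 * se(means_assim[, 1]))
  expect_lt(abs(mean(means_assim[, 2]) - 0.012), 3 * se(means_assim[, 2]))
  expect_lt(abs(mean(dens) - 155), 3 * se(dens))

  # zero-assimilation configuration propagates exact zeros
  bio0 <- gen_biogeochem(synth_config(assim_mean_track = 0,
                                      assim_mean_off = 0), seed = 1)
  expect_true(all(c_assimilation(bio0$plfa$inc13c_mg_m2) == 0))
})

test_that("macrofauna phylum composition matches the configured shares", {
  cfg <- synth_config(n_cores_per_treatment = 40)
  bio <- gen_biogeochem(cfg, seed = 9)
  shares <- bio$macrofauna |>
    dplyr::group_by(phylum) |>
    dplyr::summarise(n = sum(count)) |>
    dplyr::mutate(p = n / sum(n))
  target <- cfg$phylum_composition[shares$phylum]
  expect_true(all(abs(shares$p - target) < 0.03))
})
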