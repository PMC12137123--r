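make_images <- function(n, area = 1.132, altitude = 2.5, treatment = "control") {
  tibble::tibble(
    image_id = sprintf("img%04d", seq_len(n)),
    transect = rep(sprintf("tr%d", 1:4), length.out = n),
    treatment = treatment,
    area_m2 = area,
    altitude_m = altitude,
    year = 2023L
  )
}

test_that("annotation filtering applies size, altitude and habit rules", {
  img <- make_images(3)
  img$altitude_m <- c(2.5, 3.4, 4.0)
  ann <- tibble::tibble(
    image_id = c("img0001", "img0001", "img0002", "img0003"),
    morphotype = c("a", "b", "c", "d"),
    size_mm = c(15, 25, 30, 40),
    tube_or_shell_dweller = c(FALSE, FALSE, TRUE, FALSE)
  )
  kept <- filter_annotations(ann, img)
  # 15 mm too small; tube dweller dropped; 4.0 m image dropped entirely
  expect_equal(kept$morphotype, "b")
  # without the habit exclusion the tube dweller on a good image returns
  kept2 <- filter_annotations(ann, img, exclude_tube_dwellers = FALSE)
  expect_setequal(kept2$morphotype, c("b", "c"))
  # filtering is idempotent
  expect_identical(filter_annotations(kept, img), kept)
  # dangling references are an error that names the culprit
  bad <- dplyr::mutate(ann, image_id = sub("img0003", "imgXXXX", image_id))
  expect_error(filter_annotations(bad, img), "imgXXXX")
  expect_equal(nrow(filter_annotations(ann[0, ], img)), 0)
})

test_that("sample units respect the fixed-area stopping rule", {
  img <- make_images(3000, area = 1.132)
  units <- build_sample_units(img, target_area_m2 = 1200, seed = 5)
  per_unit <- dplyr::count(units, unit_id)
  # ceil(1200 / 1.132) = 1061 images close each unit
  expect_true(all(per_unit$n == 1061))
  expect_equal(nrow(per_unit), 2)       # 3000 images -> 2 full units
  expect_equal(anyDuplicated(units$image_id), 0)

  # variable areas: every unit lands in [target, target + max image area)
  set.seed(8)
  img2 <- make_images(4000)
  img2$area_m2 <- runif(4000, 0.5, 2)
  units2 <- build_sample_units(img2, target_area_m2 = 1200, seed = 5)
  totals <- dplyr::summarise(dplyr::group_by(units2, unit_id),
                             area = sum(area_m2))
  expect_true(all(totals$area >= 1200))
  expect_true(all(totals$area < 1200 + max(img2$area_m2)))
  expect_identical(units2, build_sample_units(img2, target_area_m2 = 1200,
                                              seed = 5))
  expect_error(build_sample_units(make_images(5), target_area_m2 = 1200),
               "cannot fill")
})

test_that("densities are counts over area at unit and core level", {
  img <- make_images(1200, area = 1)
  units <- build_sample_units(img, target_area_m2 = 1200, seed = 1)
  ann <- tibble::tibble(
    image_id = sample(img$image_id, 396, replace = TRUE),
    morphotype = "mt01",
    size_mm = 50,
    tube_or_shell_dweller = FALSE
  )
  d <- unit_densities(units, ann)
  expect_equal(d$count, 396)
  expect_equal(d$density_m2, 0.33)

  cores <- tibble::tibble(sample_id = "bc1", area_m2 = 0.25, count = 12)
  expect_equal(core_densities(cores)$density_m2, 48)
  expect_error(unit_densities(dplyr::mutate(units, area_m2 = 0), ann),
               "unit area")
})

test_that("assemblage summaries report richness and dominance shares", {
  ann <- tibble::tibble(
    treatment = "propulsion_track",
    morphotype = rep(c("A", "B", "C"), c(42, 33, 25)),
    phylum = rep(c("echinoderm", "echinoderm", "cnidarian"), c(42, 33, 25))
  )
  s <- assemblage_summary(ann)
  expect_equal(s$relative_abundance_pct, c(42, 33, 25))
  expect_equal(sum(s$relative_abundance_pct), 100)
  expect_equal(unique(s$richness), 3)
  expect_equal(unique(s$phylum_richness), 2)
  expect_equal(s$rank, 1:3)

  solo <- assemblage_summary(tibble::tibble(treatment = "t", morphotype = "A"))
  expect_equal(solo$relative_abundance_pct, 100)
  expect_equal(solo$richness, 1)
})

test_that("unit density estimation is unbiased for Poisson annotations", {
  lambda <- 0.33
  est <- vapply(1:50, function(s) {
    withr::with_seed(s, {
      img <- make_images(1400, area = 1)
      n <- rpois(nrow(img), lambda * img$area_m2)
      ann <- tibble::tibble(
        image_id = rep(img$image_id, n),
        morphotype = "mt01", size_mm = 50, tube_or_shell_dweller = FALSE
      )
      units <- build_sample_units(img, target_area_m2 = 1200, seed = s)
      mean(unit_densities(units, ann)$density_m2)
    })
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - lambda), 3 * se)
})
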