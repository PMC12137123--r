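#' Filter image annotations to consistently detectable megafauna
#'
#' Applies the detectability rules used for photo-transect counts: only
#' annotations larger than `min_size_mm` (specimens above ~20 mm are
#' consistently detectable), only images collected below `max_altitude_m`,
#' and, optionally, exclusion of taxa living in a closed shell or tube
#' (their live/dead status cannot be established from imagery).
#'
#' @param annotations Data frame with columns `image_id`, `morphotype`,
#'   `size_mm` and (if `exclude_tube_dwellers`) logical `tube_or_shell_dweller`.
#' @param images Data frame with columns `image_id`, `altitude_m` (plus any
#'   metadata such as `treatment`, `area_m2`).
#' @param min_size_mm Keep annotations strictly larger than this, mm.
#' @param max_altitude_m Keep images strictly below this altitude, m.
#' @param exclude_tube_dwellers Drop annotations flagged
#'   `tube_or_shell_dweller`.
#' @return The filtered annotation tibble (same columns as `annotations`).
#' @export
filter_annotations <- function(annotations, images, min_size_mm = 20,
                               max_altitude_m = 3.5,
                               exclude_tube_dwellers = TRUE) {
  ann <- as_tibble(annotations)
  img <- as_tibble(images)
  dangling <- setdiff(unique(ann$image_id), img$image_id)
  if (length(dangling)) {
    abort(sprintf("annotations reference unknown image id(s): %s",
                  paste(utils::head(dangling, 10), collapse = ", ")))
  }
  keep_img <- img$image_id[img$altitude_m < max_altitude_m]
  out <- filter(ann, .data$image_id %in% keep_img,
                .data$size_mm > min_size_mm)
  if (exclude_tube_dwellers) {
    if (!"tube_or_shell_dweller" %in% names(out)) {
      abort("`annotations` lacks the `tube_or_shell_dweller` column")
    }
    out <- filter(out, !.data$tube_or_shell_dweller)
  }
  out
}

#' Compose fixed-area sample units from images
#'
#' Builds replicate sample units for density estimation by drawing images of
#' one treatment uniformly at random without replacement, closing a unit as
#' soon as its cumulative seabed area reaches `target_area_m2` (so each unit
#' covers `[target, target + max single image area)`), and repeating until
#' the remaining images cannot complete another unit; leftovers are
#' discarded. Deterministic given `seed`.
#'
#' @param images Data frame with columns `image_id`, `area_m2` and, if
#'   `stratify_by_transect`, `transect`.
#' @param target_area_m2 Seabed area per unit, m^2 (default 1200).
#' @param seed Integer RNG seed.
#' @param stratify_by_transect Draw units within transects rather than
#'   pooling the whole treatment (default FALSE).
#' @return Tibble with columns `unit_id`, `image_id`, `area_m2` mapping each
#'   selected image to its unit.
#' @export
build_sample_units <- function(images, target_area_m2 = 1200, seed = 1,
                               stratify_by_transect = FALSE) {
  img <- as_tibble(images)
  check_positive(img$area_m2, "images$area_m2")
  if (stratify_by_transect) {
    if (!"transect" %in% names(img)) abort("no `transect` column to stratify by")
    parts <- split(img, img$transect)
    out <- purrr::imap_dfr(parts, function(part, tr) {
      u <- draw_units(part, target_area_m2, seed + match(tr, names(parts)))
      if (nrow(u)) u$unit_id <- paste(tr, u$unit_id, sep = "_")
      u
    })
    return(out)
  }
  draw_units(img, target_area_m2, seed)
}

draw_units <- function(img, target_area_m2, seed) {
  if (sum(img$area_m2) < target_area_m2) {
    abort(sprintf("total image area %.1f m^2 cannot fill one %.0f m^2 unit",
                  sum(img$area_m2), target_area_m2))
  }
  ord <- withr::with_seed(seed, sample.int(nrow(img)))
  shuffled <- img[ord, ]
  unit_id <- integer(nrow(shuffled))
  uid <- 1L
  acc <- 0
  for (i in seq_len(nrow(shuffled))) {
    unit_id[i] <- uid
    acc <- acc + shuffled$area_m2[i]
    if (acc >= target_area_m2) {
      uid <- uid + 1L
      acc <- 0
    }
  }
  # the last unit is complete only if it closed; otherwise discard leftovers
  complete <- if (acc == 0) unit_id <= uid else unit_id < uid
  tibble(
    unit_id = sprintf("unit%02d", unit_id[complete]),
    image_id = shuffled$image_id[complete],
    area_m2 = shuffled$area_m2[complete]
  )
}

#' Per-unit faunal densities
#'
#' Counts filtered annotations per sample unit (optionally per morphotype)
#' and divides by unit seabed area to give individuals per square metre.
#'
#' @param units Unit membership table from [build_sample_units()].
#' @param annotations Filtered annotations ([filter_annotations()]).
#' @param by_morphotype Also break densities down by morphotype.
#' @return Tibble with `unit_id`, `area_m2`, (`morphotype`,) `count`,
#'   `density_m2`.
#' @export
unit_densities <- function(units, annotations, by_morphotype = FALSE) {
  u <- as_tibble(units)
  areas <- u |>
    group_by(.data$unit_id) |>
    summarise(area_m2 = sum(.data$area_m2), .groups = "drop")
  check_positive(areas$area_m2, "unit area")
  ann <- inner_join(as_tibble(annotations), select(u, "image_id", "unit_id"),
                    by = "image_id")
  keys <- if (by_morphotype) c("unit_id", "morphotype") else "unit_id"
  counts <- ann |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(count = n(), .groups = "drop")
  out <- left_join(areas, counts, by = "unit_id")
  if (by_morphotype) {
    out <- tidyr::complete(out, .data$unit_id, .data$morphotype,
                           fill = list(count = 0)) |>
      group_by(.data$unit_id) |>
      mutate(area_m2 = max(.data$area_m2, na.rm = TRUE)) |>
      ungroup() |>
      filter(!is.na(.data$morphotype))
  }
  out$count[is.na(out$count)] <- 0
  mutate(out, density_m2 = .data$count / .data$area_m2)
}

#' Per-core faunal densities
#'
#' @param cores Data frame with `sample_id`, `area_m2` and `count` (or
#'   per-phylum counts in long form with a `phylum` column).
#' @return The input with a `density_m2 = count / area_m2` column.
#' @export
core_densities <- function(cores) {
  df <- as_tibble(cores)
  check_positive(df$area_m2, "cores$area_m2")
  check_nonnegative(df$count, "cores$count")
  mutate(df, density_m2 = .data$count / .data$area_m2)
}

#' Summarise densities by treatment
#'
#' @param densities Output of [unit_densities()] or [core_densities()] with a
#'   `treatment` column (join it from the image/core metadata first).
#' @return Per-treatment mean, median, quartiles, n.
#' @export
density_summary <- function(densities) {
  df <- as_tibble(densities)
  if (!"treatment" %in% names(df)) abort("`densities` needs a `treatment` column")
  df |>
    group_by(.data$treatment) |>
    summarise(
      n = n(),
      mean_m2 = mean(.data$density_m2),
      median_m2 = median(.data$density_m2),
      q1_m2 = quantile(.data$density_m2, 0.25, names = FALSE),
      q3_m2 = quantile(.data$density_m2, 0.75, names = FALSE),
      .groups = "drop"
    )
}

#' Assemblage richness, composition and dominance
#'
#' Per treatment: morphotype and phylum richness, per-morphotype relative
#' abundance (percent of total individuals, summing to 100), and rank order
#' of dominance.
#'
#' @param annotations Filtered annotations with columns `treatment`,
#'   `morphotype` and (optionally) `phylum`.
#' @return A list-free tibble: one row per treatment x morphotype with
#'   `count`, `relative_abundance_pct`, `rank`, plus per-treatment `richness`
#'   and `phylum_richness` repeated on each row.
#' @export
assemblage_summary <- function(annotations) {
  ann <- as_tibble(annotations)
  if (!all(c("treatment", "morphotype") %in% names(ann))) {
    abort("`annotations` needs `treatment` and `morphotype` columns")
  }
  out <- ann |>
    group_by(.data$treatment, .data$morphotype) |>
    summarise(
      count = n(),
      phylum = if ("phylum" %in% names(ann)) dplyr::first(.data$phylum)
               else NA_character_,
      .groups = "drop_last"
    ) |>
    mutate(
      relative_abundance_pct = 100 * .data$count / sum(.data$count),
      rank = rank(-.data$count, ties.method = "min"),
      richness = dplyr::n_distinct(.data$morphotype),
      phylum_richness = dplyr::n_distinct(.data$phylum[!is.na(.data$phylum)])
    ) |>
    ungroup() |>
    arrange(.data$treatment, .data$rank)
  out
}
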