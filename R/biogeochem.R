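#' Bacterial biomass from PLFA carbon
#'
#' Converts summed bacterial phospholipid fatty acid carbon to total living
#' bacterial biomass using the average fraction-specific bacterial-to-PLFA
#' carbon ratio for bacteria-dominated sediment, r = 0.017:
#' `biomass = plfa_c / r`. Linear and positively homogeneous.
#'
#' @param plfa_c Bacterial PLFA carbon, mg C m^-2 (vectorized).
#' @param r Bacterial-to-PLFA carbon ratio (default 0.017).
#' @return Bacterial biomass, mg C m^-2.
#' @export
#' @examples
#' bacterial_biomass(1.564) # ~92 mg C m^-2
bacterial_biomass <- function(plfa_c, r = 0.017) {
  check_nonnegative(plfa_c, "plfa_c")
  check_positive(r, "r")
  plfa_c / r
}

#' Daily carbon assimilation from incorporated 13C
#'
#' Converts 13C incorporated into bacterial fatty acids during a pulse-chase
#' incubation with labelled algae into a daily carbon assimilation rate:
#' `(inc13c / atom_fraction) / duration_divisor`, where the atom fraction is
#' the fractional abundance of 13C in the added algae (3.9 atom%) and the
#' divisor converts the ~70 h incubation to days.
#'
#' @param inc13c Incorporated 13C, mg 13C m^-2 (vectorized).
#' @param atom_fraction Fractional 13C abundance of the added algae
#'   (default 0.039).
#' @param duration_divisor Incubation length divisor, days (default 2.8).
#' @return Carbon assimilation rate, mg C m^-2 day^-1.
#' @export
#' @examples
#' c_assimilation(0.0035) # ~0.032 mg C m^-2 day^-1
c_assimilation <- function(inc13c, atom_fraction = 0.039,
                           duration_divisor = 2.8) {
  check_nonnegative(inc13c, "inc13c")
  check_positive(atom_fraction, "atom_fraction")
  if (atom_fraction >= 1) abort("`atom_fraction` must be < 1")
  check_positive(duration_divisor, "duration_divisor")
  (inc13c / atom_fraction) / duration_divisor
}

#' Nodule abundance, mass and size metrics
#'
#' Per-boxcore and pooled polymetallic nodule metrics. The pooled density is
#' total count over total sampled area (not the mean of per-core densities);
#' both are reported, and they differ whenever core areas differ.
#'
#' @param nodules Data frame with one row per nodule: `boxcore_id`,
#'   `size_mm` (largest dimension), `mass_g`, `area_m2` (sampled area of the
#'   core, constant within a core; boxcores are 0.25 m^2). Cores that
#'   contained no nodules can be supplied as rows with `size_mm = NA` and
#'   `mass_g = 0`.
#' @return A list with `per_core` (tibble: count, density m^-2, kg m^-2 per
#'   core) and `pooled` (one-row tibble: pooled density and mass density,
#'   mean density across cores, size mean/sd/max, totals).
#' @export
#' @examples
#' nodule_metrics(data.frame(boxcore_id = "b1", size_mm = c(60, 80),
#'                           mass_g = c(100, 140), area_m2 = 0.25))
nodule_metrics <- function(nodules) {
  df <- as_tibble(nodules)
  if (nrow(df) == 0) {
    warn("no nodule records; returning zero metrics")
    return(list(
      per_core = tibble(boxcore_id = character(), count = integer(),
                        density_m2 = numeric(), mass_kg_m2 = numeric()),
      pooled = tibble(n_cores = 0L, total_count = 0L, total_area_m2 = 0,
                      pooled_density_m2 = 0, mean_core_density_m2 = 0,
                      pooled_mass_kg_m2 = 0, size_mean_mm = NA_real_,
                      size_sd_mm = NA_real_, size_max_mm = NA_real_)
    ))
  }
  check_positive(df$area_m2, "nodules$area_m2")
  per_core <- df |>
    group_by(.data$boxcore_id) |>
    summarise(
      count = sum(!is.na(.data$size_mm)),
      area_m2 = dplyr::first(.data$area_m2),
      mass_kg = sum(.data$mass_g, na.rm = TRUE) / 1e3,
      .groups = "drop"
    ) |>
    mutate(density_m2 = .data$count / .data$area_m2,
           mass_kg_m2 = .data$mass_kg / .data$area_m2)
  sizes <- df$size_mm[!is.na(df$size_mm)]
  pooled <- tibble(
    n_cores = nrow(per_core),
    total_count = sum(per_core$count),
    total_area_m2 = sum(per_core$area_m2),
    pooled_density_m2 = sum(per_core$count) / sum(per_core$area_m2),
    mean_core_density_m2 = mean(per_core$density_m2),
    pooled_mass_kg_m2 = sum(per_core$mass_kg) / sum(per_core$area_m2),
    size_mean_mm = if (length(sizes)) mean(sizes) else NA_real_,
    size_sd_mm = if (length(sizes) > 1) sd(sizes) else NA_real_,
    size_max_mm = if (length(sizes)) max(sizes) else NA_real_
  )
  list(per_core = per_core, pooled = pooled)
}

#' Box-plot statistics for sediment chemistry groups
#'
#' Per-group median, quartiles (linear interpolation between order
#' statistics) and whisker range under the 1.5 x IQR outlier rule, for
#' surface-sediment chemistry summaries (TOC, TN, grain size, ...).
#'
#' @param records Data frame of measurements.
#' @param value Column name (string) of the measured variable.
#' @param group Column name (string) of the grouping key (e.g. `treatment`).
#' @return Per-group tibble: `n`, `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`, `n_outliers`.
#' @export
sediment_summary <- function(records, value, group = "treatment") {
  df <- as_tibble(records)
  if (!all(c(value, group) %in% names(df))) {
    abort(sprintf("`records` needs columns `%s` and `%s`", value, group))
  }
  df |>
    group_by(across(dplyr::all_of(group))) |>
    summarise(
      n = n(),
      median = median(.data[[value]]),
      q1 = quantile(.data[[value]], 0.25, names = FALSE),
      q3 = quantile(.data[[value]], 0.75, names = FALSE),
      whisker_low = {
        lo <- quantile(.data[[value]], 0.25, names = FALSE) -
          1.5 * stats::IQR(.data[[value]])
        min(.data[[value]][.data[[value]] >= lo])
      },
      whisker_high = {
        hi <- quantile(.data[[value]], 0.75, names = FALSE) +
          1.5 * stats::IQR(.data[[value]])
        max(.data[[value]][.data[[value]] <= hi])
      },
      n_outliers = {
        lo <- quantile(.data[[value]], 0.25, names = FALSE) -
          1.5 * stats::IQR(.data[[value]])
        hi <- quantile(.data[[value]], 0.75, names = FALSE) +
          1.5 * stats::IQR(.data[[value]])
        sum(.data[[value]] < lo | .data[[value]] > hi)
      },
      .groups = "drop"
    )
}
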