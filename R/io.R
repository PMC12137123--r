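#' Write a deposition map as an ESRI ASCII grid
#'
#' @param map A [deposition_map()].
#' @param path Output path (`.asc`).
#' @param what `"thickness_m"` or `"mass_kg_m2"`.
#' @export
write_deposition_asc <- function(map, path, what = c("thickness_m",
                                                     "mass_kg_m2")) {
  what <- match.arg(what)
  m <- if (what == "thickness_m") map$mass / map$rho_dry_deposit else map$mass
  g <- elevation_grid(m, cell_size = map$cell_size, origin = map$origin)
  write_ascii_grid(g, path)
}

#' Import worksheets from a spreadsheet workbook into typed CSV tables
#'
#' Reads the named worksheets of an `.xlsx` workbook (e.g. the data workbook
#' accompanying a field campaign, with worksheets such as `Metadata`,
#' `TOC_TN`, `Grain Size`, `SedimentMacrofauna`, `Microbes`, `Megafauna`),
#' normalizes the headers to lower snake_case, and optionally writes one CSV
#' per worksheet. Unmapped columns pass through untouched.
#'
#' @param path Workbook path.
#' @param sheets Character vector of worksheet names; default all.
#' @param out_dir If non-NULL, write `<sheet>.csv` files there.
#' @return Named list of tibbles, one per worksheet.
#' @export
import_xlsx <- function(path, sheets = NULL, out_dir = NULL) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    abort("the `readxl` package is required to import workbooks")
  }
  have <- readxl::excel_sheets(path)
  sheets <- sheets %||% have
  missing <- setdiff(sheets, have)
  if (length(missing)) {
    abort(sprintf("workbook has no worksheet(s): %s",
                  paste(missing, collapse = ", ")))
  }
  norm <- function(x) {
    x <- gsub("[^A-Za-z0-9]+", "_", trimws(x))
    tolower(gsub("^_|_$", "", x))
  }
  tables <- lapply(sheets, function(s) {
    df <- readxl::read_xlsx(path, sheet = s)
    names(df) <- norm(names(df))
    as_tibble(df)
  })
  names(tables) <- sheets
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (s in sheets) {
      readr::write_csv(tables[[s]],
                       file.path(out_dir, paste0(norm(s), ".csv")))
    }
  }
  tables
}

#' Run the full synthetic end-to-end pipeline
#'
#' Generates a synthetic study system, then runs every analysis stage over
#' it: plume deposition along the generated track, micro-relief and location
#' comparison over control and infilled DTM patches, sample-unit megafauna
#' densities and assemblage summaries, and the biogeochemical conversions.
#' Writes the stage outputs (CSV tables, ASCII grids) and a provenance
#' manifest (`manifest.json` with package version, seed, configuration hash
#' and file list) into `out_dir`. Reruns with the same configuration and
#' seed are bit-identical for all deterministic stages.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [synth_config()].
#' @param scenario A [plume_scenario()] for the deposition stage.
#' @param seed Integer seed driving every stochastic stage.
#' @param stages Character vector of stages to run; subset of
#'   `c("synth", "plume", "microrelief", "community", "biogeochem")`.
#' @param cell_size Plume grid cell size, m.
#' @param target_area_m2 Seabed area per community sample unit, m^2.
#' @return Invisibly, a list of the in-memory stage results plus the
#'   manifest.
#' @export
run_pipeline <- function(out_dir,
                         config = synth_config(),
                         scenario = plume_scenario(0.05, 0.05, 2.6),
                         seed = 1,
                         stages = c("synth", "plume", "microrelief",
                                    "community", "biogeochem"),
                         cell_size = 2,
                         target_area_m2 = 1200) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  if ("synth" %in% stages) {
    track <- gen_track(config$track_length_m, config$turn_radius_m)
    imgann <- gen_annotations(config, seed)
    bio <- gen_biogeochem(config, seed + 1)
    write_track_csv(track, file.path(out_dir, "track.csv"))
    readr::write_csv(imgann$images, file.path(out_dir, "images.csv"))
    readr::write_csv(imgann$annotations, file.path(out_dir, "annotations.csv"))
    readr::write_csv(bio$plfa, file.path(out_dir, "plfa.csv"))
    readr::write_csv(bio$nodules, file.path(out_dir, "nodules.csv"))
    readr::write_csv(bio$macrofauna, file.path(out_dir, "macrofauna.csv"))
    readr::write_csv(bio$sedchem, file.path(out_dir, "sedchem.csv"))
    results$synth <- c(list(track = track), imgann, bio)
  }
  if ("plume" %in% stages) {
    track <- results$synth$track %||%
      gen_track(config$track_length_m, config$turn_radius_m)
    map <- simulate_track_plume(track, scenario, cell_size = cell_size)
    summ <- summarize_deposition(map, track)
    write_deposition_asc(map, file.path(out_dir, "deposit_thickness.asc"))
    jsonlite::write_json(as.list(summ),
                         file.path(out_dir, "deposit_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    results$plume <- list(map = map, summary = summ)
  }
  if ("microrelief" %in% stages) {
    locs <- c(control = 0, east = config$infill_depth_m %||% 0.005,
              west = config$infill_depth_m %||% 0.005)
    if (all(locs == 0)) locs[c("east", "west")] <- 0.005
    grids <- purrr::imap(locs, function(infill, loc) {
      cfg <- config
      cfg$infill_depth_m <- infill
      lapply(1:3, function(tr) {
        gen_dtm(cfg, seed = seed + 100 * match(loc, names(locs)) + tr,
                transect = sprintf("%s_t%d", loc, tr), location = loc)
      })
    })
    maxima <- microrelief_maxima(purrr::flatten(grids), seed = seed)
    cmp <- compare_locations(maxima)
    readr::write_csv(maxima, file.path(out_dir, "microrelief_maxima.csv"))
    readr::write_csv(tidy(cmp), file.path(out_dir, "microrelief_pairwise.csv"))
    results$microrelief <- list(maxima = maxima, comparison = cmp)
  }
  if ("community" %in% stages) {
    imgann <- results$synth[c("images", "annotations")] %||% NULL
    if (is.null(imgann$images)) imgann <- gen_annotations(config, seed)
    kept <- filter_annotations(imgann$annotations, imgann$images)
    usable <- filter(imgann$images, .data$altitude_m < 3.5)
    dens <- purrr::imap_dfr(
      split(usable, usable$treatment),
      function(img, tr) {
        units <- build_sample_units(img, target_area_m2 = target_area_m2,
                                    seed = seed)
        mutate(unit_densities(units, kept), treatment = tr)
      }
    )
    summ <- assemblage_summary(
      inner_join(kept, select(imgann$images, "image_id", "treatment"),
                 by = "image_id")
    )
    readr::write_csv(dens, file.path(out_dir, "unit_densities.csv"))
    readr::write_csv(summ, file.path(out_dir, "assemblage_summary.csv"))
    results$community <- list(densities = dens, assemblage = summ)
  }
  if ("biogeochem" %in% stages) {
    bio <- results$synth[c("plfa", "nodules", "macrofauna", "sedchem")]
    if (is.null(bio$plfa)) bio <- gen_biogeochem(config, seed + 1)
    plfa <- bio$plfa |>
      mutate(biomass_mg_c_m2 = bacterial_biomass(.data$plfa_c_mg_m2),
             assimilation_mg_c_m2_d = c_assimilation(.data$inc13c_mg_m2))
    nod <- nodule_metrics(bio$nodules)
    sed <- sediment_summary(bio$sedchem, "toc_pct")
    readr::write_csv(plfa, file.path(out_dir, "plfa_converted.csv"))
    readr::write_csv(nod$pooled, file.path(out_dir, "nodule_pooled.csv"))
    readr::write_csv(sed, file.path(out_dir, "sedchem_toc_summary.csv"))
    results$biogeochem <- list(plfa = plfa, nodules = nod, sedchem = sed)
  }
  cfg_for_hash <- config
  cfg_for_hash$composition <- lapply(cfg_for_hash$composition, unclass)
  manifest <- list(
    package = "trackrec",
    version = as.character(utils::packageVersion("trackrec")),
    seed = seed,
    stages = stages,
    config_hash = rlang::hash(cfg_for_hash),
    scenario_hash = rlang::hash(unclass(scenario)),
    files = sort(unique(c(list.files(out_dir), "manifest.json")))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
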