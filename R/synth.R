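#' Configuration for the synthetic data generator
#'
#' Bundles every tunable of the synthetic study system: a nodule-studded
#' abyssal seafloor crossed by a collector track, photographed along
#' transects in five treatments, sampled with boxcores, and incubated for
#' pulse-chase isotope measurements. Defaults reproduce the statistical
#' structure of the field system: nodule density 155 m^-2 with largest
#' dimensions of 72 +/- 19 mm, megafauna densities of 0.33 (control),
#' 0.28 (predisturbance), <0.1 (collection track) individuals m^-2,
#' sediment macrofauna dominated by annelids (43%), arthropods (34%) and
#' molluscs (18%), and on/off-track bacterial biomass around 92 and
#' 52 mg C m^-2.
#'
#' @param track_length_m,turn_radius_m Loop geometry for [gen_track()].
#' @param nodule_density_m2 Nodules per m^2 of seabed.
#' @param nodule_size_mean_mm,nodule_size_sd_mm Largest-dimension
#'   distribution (normal, truncated above 10 mm).
#' @param nodule_mass_coef_g_mm3 Nodule mass per cubed largest dimension,
#'   g mm^-3 (default matches 18.6 kg m^-2 at 155 nodules m^-2).
#' @param protrusion_fraction Fraction of a nodule's diameter protruding
#'   above the sediment.
#' @param dtm_extent_m DTM patch extent `c(width, height)`, m.
#' @param dtm_cell_m DTM cell size, m.
#' @param noise_sd_m Gaussian small-scale sediment roughness, m.
#' @param infill_depth_m Uniform sediment infill raising the inter-nodule
#'   matrix, m.
#' @param treatment_densities Named vector of detectable megafauna densities
#'   (individuals m^-2) per treatment.
#' @param composition Named list of per-treatment morphotype probability
#'   vectors; defaults encode the low-richness, high-dominance propulsion
#'   track assemblage (top two taxa at 42% and 33% of individuals).
#' @param images_per_transect,transects_per_treatment Imaging effort.
#' @param image_area_mean_m2,image_area_cv Gamma-distributed image footprint.
#' @param altitude_mean_m,altitude_sd_m,altitude_high_fraction Image
#'   altitudes; a small fraction is drawn above the 3.5 m usability cutoff.
#' @param undersize_rate,tube_dweller_rate Contamination rates (relative to
#'   the detectable density) of sub-20 mm annotations and tube/shell
#'   dwellers, included to exercise the filtering rules.
#' @param plfa_mean_track,plfa_mean_off Mean bacterial PLFA carbon,
#'   mg C m^-2, on and off track.
#' @param assim_mean_track,assim_mean_off Target carbon assimilation rates,
#'   mg C m^-2 day^-1.
#' @param n_chambers_per_class,n_cores_per_chamber Incubation design.
#' @param n_boxcores Number of nodule boxcores (0.25 m^2 each).
#' @param macrofauna_density_m2 Sediment macrofauna density, m^-2.
#' @param phylum_composition Named phylum proportions for macrofauna.
#' @param n_cores_per_treatment Sediment chemistry and macrofauna cores per
#'   treatment.
#' @param toc_mean_pct,tn_mean_pct,grain_mean_um Sediment chemistry levels.
#' @return A `synth_config` list.
#' @export
synth_config <- function(track_length_m = 1850,
                         turn_radius_m = 100,
                         nodule_density_m2 = 155,
                         nodule_size_mean_mm = 72,
                         nodule_size_sd_mm = 19,
                         nodule_mass_coef_g_mm3 = 2.66e-4,
                         protrusion_fraction = 0.4,
                         dtm_extent_m = c(2, 10),
                         dtm_cell_m = 0.01,
                         noise_sd_m = 0.003,
                         infill_depth_m = 0,
                         treatment_densities = c(
                           control = 0.33,
                           predisturbance = 0.28,
                           collection_track = 0.05,
                           propulsion_track = 0.15,
                           plume = 0.45
                         ),
                         composition = default_composition(),
                         images_per_transect = 350,
                         transects_per_treatment = 4,
                         image_area_mean_m2 = 1.13,
                         image_area_cv = 0.25,
                         altitude_mean_m = 2.5,
                         altitude_sd_m = 0.35,
                         altitude_high_fraction = 0.05,
                         undersize_rate = 0.25,
                         tube_dweller_rate = 0.1,
                         plfa_mean_track = 1.564,
                         plfa_mean_off = 0.884,
                         assim_mean_track = 0.032,
                         assim_mean_off = 0.012,
                         n_chambers_per_class = 2,
                         n_cores_per_chamber = 3,
                         n_boxcores = 14,
                         macrofauna_density_m2 = 120,
                         phylum_composition = c(
                           annelid = 0.43, arthropod = 0.34,
                           mollusc = 0.18, other = 0.05
                         ),
                         n_cores_per_treatment = 6,
                         toc_mean_pct = 0.45,
                         tn_mean_pct = 0.06,
                         grain_mean_um = 20) {
  check_nonnegative(treatment_densities, "treatment_densities")
  check_nonnegative(infill_depth_m, "infill_depth_m")
  if (abs(sum(phylum_composition) - 1) > 1e-9) {
    abort("`phylum_composition` must sum to 1")
  }
  for (tr in names(composition)) {
    if (abs(sum(composition[[tr]]) - 1) > 1e-9) {
      abort(sprintf("composition for treatment `%s` must sum to 1", tr))
    }
  }
  cfg <- as.list(environment())
  structure(cfg, class = "synth_config")
}

#' Default per-treatment morphotype compositions
#'
#' Geometric-series relative abundances, except the propulsion track, whose
#' top two morphotypes are pinned at 42% and 33% with the remaining mass
#' spread geometrically over 33 further taxa (35 taxa in total, mirroring a
#' low-richness, high-dominance disturbed assemblage).
#'
#' @param n_taxa Taxon pool size for the undisturbed treatments.
#' @return Named list of named probability vectors.
#' @export
default_composition <- function(n_taxa = 40) {
  geom_comp <- function(n, ratio = 0.85, prefix = "mt") {
    p <- ratio^(seq_len(n) - 1)
    setNames(p / sum(p), sprintf("%s%02d", prefix, seq_len(n)))
  }
  base <- geom_comp(n_taxa)
  prop_rest <- geom_comp(33, ratio = 0.9, prefix = "pt")
  propulsion <- c(
    P_globulosum = 0.42,
    Elpidiidae_sp = 0.33,
    prop_rest * 0.25
  )
  list(
    control = base,
    predisturbance = base,
    collection_track = geom_comp(12, ratio = 0.7),
    propulsion_track = propulsion,
    plume = geom_comp(n_taxa, ratio = 0.8)
  )
}

# normal truncated below at `lower` by resampling
rnorm_trunc <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

#' Generate a synthetic nodule-field DTM patch
#'
#' Builds a centimetre-resolution elevation grid emulating the photogrammetry
#' input: a flat sediment plane with Gaussian roughness, polymetallic nodules
#' placed by a Poisson process and shaped as spherical caps (protrusion =
#' `protrusion_fraction` x diameter), and optional uniform sediment infill
#' that raises the inter-nodule matrix while clipping against nodule
#' surfaces — the signature left by plume deposition settling between
#' nodules. Deterministic given `seed`.
#'
#' @param config A [synth_config()].
#' @param seed Integer RNG seed.
#' @param transect,location Labels for the grid.
#' @return An [elevation_grid()].
#' @export
gen_dtm <- function(config = synth_config(), seed = 1,
                    transect = "t1", location = "control") {
  stopifnot(inherits(config, "synth_config"))
  cs <- config$dtm_cell_m
  if (cs < 0.005 || cs > 0.05) abort("`dtm_cell_m` must be in [0.005, 0.05]")
  wx <- config$dtm_extent_m[[1]]
  wy <- config$dtm_extent_m[[2]]
  if (wx * wy < 1) abort("DTM extent must cover at least 1 m^2")
  nx <- round(wx / cs)
  ny <- round(wy / cs)
  withr::with_seed(seed, {
    noise <- matrix(rnorm(nx * ny, 0, config$noise_sd_m), nrow = ny)
    matrix_level <- noise + config$infill_depth_m
    n_nod <- rpois(1, config$nodule_density_m2 * wx * wy)
    nod_surface <- matrix(-Inf, nrow = ny, ncol = nx)
    covered <- 0
    if (n_nod > 0) {
      px <- runif(n_nod, 0, wx)
      py <- runif(n_nod, 0, wy)
      diam <- rnorm_trunc(n_nod, config$nodule_size_mean_mm,
                          config$nodule_size_sd_mm, lower = 10) / 1e3
      for (k in seq_len(n_nod)) {
        a <- diam[k] / 2
        p <- config$protrusion_fraction * diam[k]
        p <- min(p, a)                       # cap height cannot exceed radius
        rho_max <- sqrt(a^2 - (a - p)^2)
        jlo <- max(1L, ceiling((px[k] - rho_max) / cs + 0.5))
        jhi <- min(nx, floor((px[k] + rho_max) / cs + 0.5))
        ilo <- max(1L, ceiling((py[k] - rho_max) / cs + 0.5))
        ihi <- min(ny, floor((py[k] + rho_max) / cs + 0.5))
        if (jlo > jhi || ilo > ihi) next
        dx2 <- ((jlo:jhi - 0.5) * cs - px[k])^2
        dy2 <- ((ilo:ihi - 0.5) * cs - py[k])^2
        rho2 <- outer(dy2, dx2, "+")
        z <- sqrt(pmax(a^2 - rho2, 0)) - (a - p)
        z[rho2 > rho_max^2] <- -Inf
        nod_surface[ilo:ihi, jlo:jhi] <- pmax(nod_surface[ilo:ihi, jlo:jhi], z)
        covered <- covered + pi * rho_max^2
      }
      # Boolean-model coverage: footprints overlap, so expected covered
      # fraction is 1 - exp(-total footprint / area)
      if (1 - exp(-covered / (wx * wy)) > 0.5) {
        warn("nodule density so high that nodules cover > 50% of the patch")
      }
    }
    heights <- pmax(matrix_level, nod_surface)
    elevation_grid(heights, cell_size = cs, transect = transect,
                   location = location)
  })
}

#' Generate synthetic photo-transect images and annotations
#'
#' Emulates the image-annotation worksheets: per treatment,
#' `transects_per_treatment` transects of `images_per_transect` images with
#' gamma-distributed footprints and near-target altitudes; per image, a
#' Poisson number of detectable megafauna (density x area) assigned to
#' morphotypes by the treatment's composition with lognormal sizes above
#' 20 mm. Sub-threshold specimens and tube/shell dwellers are added at the
#' configured contamination rates so the filtering rules have work to do.
#' Deterministic given `seed`.
#'
#' @param config A [synth_config()].
#' @param seed Integer RNG seed.
#' @return List of two tibbles: `images` (image_id, transect, treatment,
#'   area_m2, altitude_m, year) and `annotations` (image_id, morphotype,
#'   phylum, size_mm, mobile, tube_or_shell_dweller).
#' @export
gen_annotations <- function(config = synth_config(), seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(seed, {
    shape <- 1 / config$image_area_cv^2
    imgs <- purrr::imap_dfr(config$treatment_densities, function(dens, tr) {
      n <- config$images_per_transect * config$transects_per_treatment
      tibble(
        image_id = sprintf("%s_img%05d", tr, seq_len(n)),
        transect = sprintf("%s_tr%d", tr,
                           rep(seq_len(config$transects_per_treatment),
                               each = config$images_per_transect)),
        treatment = tr,
        area_m2 = rgamma(n, shape = shape,
                         rate = shape / config$image_area_mean_m2),
        altitude_m = ifelse(
          runif(n) < config$altitude_high_fraction,
          runif(n, 3.6, 5),
          pmin(abs(rnorm(n, config$altitude_mean_m, config$altitude_sd_m)),
               3.49)
        ),
        year = if (tr == "predisturbance") 1978L else 2023L
      )
    })
    phyla_of <- function(morphos) {
      # deterministic morphotype -> phylum lookup spread over common phyla
      pool <- c("echinoderm", "cnidarian", "arthropod", "porifera",
                "bryozoan", "annelid")
      pool[(vapply(morphos, function(m) sum(utf8ToInt(m)), numeric(1)) %%
              length(pool)) + 1]
    }
    lambda <- unname(config$treatment_densities[imgs$treatment]) * imgs$area_m2
    blocks <- list(
      detectable = rpois(nrow(imgs), lambda),
      undersize = rpois(nrow(imgs), config$undersize_rate * lambda),
      tube = rpois(nrow(imgs), config$tube_dweller_rate * lambda)
    )
    ann <- purrr::imap_dfr(blocks, function(n_per_img, kind) {
      total <- sum(n_per_img)
      if (total == 0) return(NULL)
      treatment <- rep(imgs$treatment, n_per_img)
      morph <- character(total)
      for (tr in unique(treatment)) {
        idx <- which(treatment == tr)
        comp <- config$composition[[tr]]
        morph[idx] <- sample(names(comp), length(idx), replace = TRUE,
                             prob = comp)
      }
      size <- if (kind == "undersize") runif(total, 5, 20) else
        20 + rlnorm(total, meanlog = log(25), sdlog = 0.5)
      tibble(
        image_id = rep(imgs$image_id, n_per_img),
        morphotype = morph,
        phylum = phyla_of(morph),
        size_mm = size,
        mobile = runif(total) < 0.7,
        tube_or_shell_dweller = kind == "tube"
      )
    })
    list(images = imgs, annotations = ann)
  })
}

#' Generate synthetic biogeochemistry and core tables
#'
#' Emulates the biogeochemical worksheets: PLFA carbon and incorporated 13C
#' per incubation core (lognormal around the configured on/off-track means,
#' so that [bacterial_biomass()] and [c_assimilation()] recover the targets),
#' per-boxcore nodule inventories (Poisson counts at the configured density,
#' truncated-normal sizes, cubic size-mass relation), sediment macrofauna
#' counts with the configured phylum composition, and surface-sediment
#' TOC/TN/grain-size records. Deterministic given `seed`.
#'
#' @param config A [synth_config()].
#' @param seed Integer RNG seed.
#' @return List of tibbles: `plfa`, `nodules`, `macrofauna`, `sedchem`.
#' @export
gen_biogeochem <- function(config = synth_config(), seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(seed, {
    lmean <- function(m, cv) log(m) - log(1 + cv^2) / 2
    lsd <- function(cv) sqrt(log(1 + cv^2))
    classes <- c(track = config$plfa_mean_track, off_track = config$plfa_mean_off)
    assim <- c(track = config$assim_mean_track, off_track = config$assim_mean_off)
    plfa <- purrr::imap_dfr(classes, function(m, cls) {
      n <- config$n_chambers_per_class * config$n_cores_per_chamber
      inc_mean <- assim[[cls]] * 2.8 * 0.039
      tibble(
        chamber_id = sprintf("%s_ch%d", cls,
                             rep(seq_len(config$n_chambers_per_class),
                                 each = config$n_cores_per_chamber)),
        core = rep(seq_len(config$n_cores_per_chamber),
                   config$n_chambers_per_class),
        site_class = cls,
        plfa_c_mg_m2 = rlnorm(n, lmean(m, 0.3), lsd(0.3)),
        inc13c_mg_m2 = rlnorm(n, lmean(inc_mean, 0.15), lsd(0.15))
      )
    })
    nodules <- purrr::map_dfr(seq_len(config$n_boxcores), function(b) {
      k <- rpois(1, config$nodule_density_m2 * 0.25)
      if (k == 0) {
        return(tibble(boxcore_id = sprintf("bc%02d", b), size_mm = NA_real_,
                      mass_g = 0, area_m2 = 0.25))
      }
      d <- rnorm_trunc(k, config$nodule_size_mean_mm,
                       config$nodule_size_sd_mm, lower = 10)
      tibble(
        boxcore_id = sprintf("bc%02d", b),
        size_mm = d,
        mass_g = config$nodule_mass_coef_g_mm3 * d^3 *
          rlnorm(k, lmean(1, 0.1), lsd(0.1)),
        area_m2 = 0.25
      )
    })
    treatments <- c("control", "disturbed", "plume")
    macrofauna <- purrr::map_dfr(treatments, function(tr) {
      purrr::map_dfr(seq_len(config$n_cores_per_treatment), function(cno) {
        total <- rpois(1, config$macrofauna_density_m2 * 0.25)
        counts <- as.vector(stats::rmultinom(1, total,
                                             config$phylum_composition))
        tibble(
          sample_id = sprintf("%s_core%d", tr, cno),
          gear = "boxcore",
          treatment = tr,
          area_m2 = 0.25,
          phylum = names(config$phylum_composition),
          count = counts
        )
      })
    })
    sedchem <- purrr::map_dfr(treatments, function(tr) {
      n <- config$n_cores_per_treatment
      tibble(
        core_id = sprintf("%s_sed%d", tr, seq_len(n)),
        treatment = tr,
        layer = "top_5mm",
        toc_pct = pmax(rnorm(n, config$toc_mean_pct, 0.05), 0),
        tn_pct = pmax(rnorm(n, config$tn_mean_pct, 0.008), 0),
        grain_um = pmax(rnorm(n, config$grain_mean_um, 3), 1)
      )
    })
    list(plfa = plfa, nodules = nodules, macrofauna = macrofauna,
         sedchem = sedchem)
  })
}
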