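# trackrec

Quantitative tools for assessing the seafloor footprint of a deep-sea
polymetallic-nodule collector test and the state of the benthic system
decades later. The package is aimed at benthic ecologists and environmental
modellers working with collector-track surveys in abyssal nodule provinces:
it bundles the near-field sediment-plume deposition model, the
DTM micro-relief statistics, the photo-transect density estimators and the
biogeochemical conversions such an assessment needs, together with a
deterministic synthetic-data generator so everything runs and is testable
with no external data.

## What it computes

**Plume deposition.** A moving collector is modelled as discrete
axisymmetric turbidity-current releases along its track (spacing Δs = 5 m),
each a fixed-volume box with front condition dR/dt = Fr·√(g′h), per-class
settling dC_k/dt = −w_k·C_k/h, and uniform deposition flux w_k·C_k under
the footprint; releases superpose additively on a metre-scale grid. The
mobilized mass per metre of track is
(d_rake·W_rake + f·2·W_furrow·D_furrow)·ρ_dry.

**Micro-relief.** Moving-window (9 × 9 cm) sample standard deviation of
centimetre DTM heights, the 20-bin random subsample-maximum procedure per
transect, and Kruskal–Wallis + pairwise rank-sum (Holm) comparisons between
locations — the signal that detects sediment infill between nodules.

**Community.** Detectability filtering (> 20 mm, altitude < 3.5 m, no
closed-shell/tube dwellers), fixed-area sample units (1,200 m², images drawn
without replacement until the area closes), densities per unit/core, and
assemblage richness/dominance summaries.

**Biogeochemistry.** Bacterial biomass = PLFA-C / 0.017; daily carbon
assimilation = (¹³C incorporated / 0.039) / 2.8; nodule density/mass/size
metrics (pooled and per-core); box-plot statistics for sediment chemistry.

**Statistics.** Self-contained tie-corrected Kruskal–Wallis, exact
(enumeration) and normal-approximation rank-sum tests, and Holm adjustment,
cross-checked in the test suite against independent implementations.

## Worked example

```r
library(trackrec)

track <- gen_track()                        # 1,850 m legs + 100 m looped turn
sc <- plume_scenario(mobilization_depth = 0.05, furrow_fraction = 0.05,
                     discharge_concentration = 2.6,
                     settling = settling_classes(0.6e-3))
mass_per_metre(sc)
#> [1] 162.5

map <- simulate_track_plume(track, sc, cell_size = 2)
summarize_deposition(map, track)
#> # A tibble: 1 x 7
#>   max_thickness_m max_thickness_mm extent_m deposited_mass_kg residual_mass_kg
#>             <dbl>            <dbl>    <dbl>             <dbl>            <dbl>
#> 1         0.00869             8.69     37.1           652118.            0.645
#> # i 2 more variables: off_grid_mass_kg <dbl>, released_mass_kg <dbl>
```

162.5 kg of sediment is mobilized per metre of track in this intermediate
scenario; over the whole ~4 km loop the model deposits it in a band along
the track with a maximum thickness of 8.7 mm, and no cell with at least
0.1 mm of deposit lies more than ~37 m from the track. `autoplot(map,
track = track)` draws the deposition footprint.

The synthetic pipeline end to end, with all tables, grids and a provenance
manifest written to a directory:

```r
run_pipeline("run1", config = synth_config(), seed = 1)
```

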