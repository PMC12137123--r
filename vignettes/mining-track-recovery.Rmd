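---
title: "Methods: modelling and measuring seafloor recovery from a nodule-collector test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling and measuring seafloor recovery from a nodule-collector test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(trackrec)
```

`trackrec` packages the quantitative machinery needed to assess the seafloor
footprint of an experimental polymetallic-nodule collector and the state of
the surrounding benthic system decades later: a near-field sediment-plume
deposition model, micro-relief statistics for centimetre-scale digital
terrain models (DTMs), photo-transect density estimation with explicit
sample-unit construction, biogeochemical unit conversions, and the
non-parametric tests that tie the comparisons together. A deterministic
synthetic-data generator emulates the statistical structure of the field
data so the entire pipeline runs, and is tested, without any external
download.

## 1. The plume deposition model

A seabed collector resuspends sediment as it drives: its rake strips the
upper few centimetres of seabed across the collection swath, and its
propulsion screws excavate furrows whose cross-section is partly thrown
into suspension. Per metre of travel the mobilized mass is

$$ m' = \left(d_\mathrm{rake}\, W_\mathrm{rake}
       + f_\mathrm{furrow}\, 2\, W_\mathrm{furrow}\, D_\mathrm{furrow}\right)
       \rho_\mathrm{dry}, $$

with rake mobilization depth $d_\mathrm{rake}$ (scenarios 3, 5, 7 cm), the
fraction $f$ of the two furrow cross-sections resuspended (1, 5, 10 %), and
the in-situ dry bulk density $\rho_\mathrm{dry}$ (default 500 kg m⁻³, a
typical abyssal-clay value; the printed discharge concentrations 2.31, 2.6
and 5.1 kg m⁻³ are taken as given inputs rather than re-derived, since the
source volume flux behind them is not recoverable).

The resulting turbidity current is represented as a superposition of
discrete axisymmetric releases along the track (default spacing
$\Delta s = 5$ m; each release carries $m'\Delta s$). Each release is a
fixed-volume particle-laden box: volume $V = m'\Delta s / C_d$, front radius
$R(t)$, uniform height $h = V/(\pi R^2)$, and per-class concentrations
$C_k$ for the settling classes $w_k$:

$$ \frac{dR}{dt} = \mathrm{Fr}\sqrt{g' h}, \qquad
   \frac{dC_k}{dt} = -\frac{w_k C_k}{h}, \qquad
   g' = g\,\Sigma_k C_k\,\frac{\rho_s - \rho_w}{\rho_w \rho_s}, $$

with frontal Froude number $\mathrm{Fr} = 1.19$ and particle density
$\rho_s = 2650$ kg m⁻³. The instantaneous deposition flux $w_k C_k$ falls
uniformly under the current footprint, so a grid cell whose centre lies
within $R(t)$ accumulates deposit while the front is beyond it. Because $R$
is non-decreasing, each release lays down a monotone radial deposit
profile; the implementation integrates the ODEs once per distinct release
mass (Heun steps with an exponential concentration update; steps capped so
the front advances less than one grid cell, less than 5 % of $R$, and the
fastest class loses less than 20 % of its concentration per step) and then
paints the resulting profile onto the map around every release point.
Integration terminates when the suspension is exhausted
($\Sigma C_k < 10^{-6} C_d$) or the current has collapsed below
$h_\mathrm{min} = 1$ cm; residual suspended mass is tracked explicitly, so
deposited + residual + off-grid mass balances the release to well under
0.1 %. Thickness is deposit mass per area divided by the fresh-deposit dry
bulk density (default 500 kg m⁻³, configurable).

Where the design was genuinely open we chose as follows. The initial
release radius is half the rake width plus one metre (the freshly stirred
swath slightly wider than the rake); releases sit at piece midpoints of the
discretized track; ambient-current advection is ignored because no
near-bed current measurements exist for the year of the test. The modal
settling velocities reported for the slow/intermediate/fast scenarios
(0.1, 0.6, 3.5 mm s⁻¹) are expanded into five log-spaced classes spanning
one decade with triangular mass weights, acknowledging that a real
resuspension carries a spectrum of particle sizes.

Two numerical caveats matter when interpreting the envelope runs. First,
the discrete-release construction is a lumped representation of a moving
source, not a discretization that converges as $\Delta s \to 0$: smaller
releases spread less far, so shrinking the spacing concentrates deposit
near the track. $\Delta s$ is therefore a model parameter, held at 5 m.
Second, with all scenario constants fixed, the heaviest-mobilization,
fastest-settling corner of the 3 × 3 grid produces a maximum thickness of
about 21 mm — above the ≤ 15 mm envelope reported for the original model —
while the intermediate scenario (≈ 8.7 mm ≤ 10 mm) and the lateral extent
in every scenario (≈ 59 m ≤ 100 m) fall inside it. The original model's
governing equations are not public; this reconstruction is one defensible
reading, and the discrepancy in that single corner is reported as computed
rather than absorbed by parameter adjustment.

```{r plume, eval = FALSE}
track <- gen_track()                       # ~1850 m legs, 100 m looped turn
sc <- plume_scenario(0.05, 0.05, 2.6, settling_classes(0.6e-3))
map <- simulate_track_plume(track, sc, cell_size = 2)
summarize_deposition(map, track)
autoplot(map, track = track)
```

## 2. Micro-relief of nodule fields

Plume deposits too thin to image directly still change the
three-dimensional texture of a nodule field: sediment infilling between
nodules reduces how far they protrude. Micro-relief is measured as the
moving-window sample standard deviation of DTM heights (`local_sd()`), with
a 9 × 9 cell window on a 1-cm grid — roughly one nodule footprint. Windows
touching the margin or any nodata cell return nodata rather than shrinking,
avoiding biased variances at edges; sample (n − 1) SD follows common
terrain-attribute implementations. The statistic is invariant to vertical
datum shifts and equivariant to vertical scaling, both enforced by tests.

Following the subsample-maximum procedure, the valid micro-relief cells of
each transect are randomly partitioned into 20 near-equal bins without
replacement (cells, not windows, are binned; bins are arbitrary cell sets,
not spatially contiguous — the procedure's description does not constrain
this, and arbitrary sets are implemented) and the maximum per bin is
retained, isolating the sediment-to-nodule height contrast. With three
locations × three transects × 20 bins this yields the 180-value design the
comparison is built for. Locations are compared with a Kruskal–Wallis
omnibus test and pairwise two-sided rank-sum tests; the multiplicity
correction is not specified by the source methods, so the conservative Holm
step-down is applied.

## 3. Photo-transect densities and assemblage structure

Counts from seabed imagery are only comparable under explicit
detectability rules: annotations larger than 20 mm, images collected below
3.5 m altitude, and exclusion of taxa living in closed shells or tubes
(alive/dead status is not determinable from imagery). `filter_annotations()`
encodes exactly these rules and is idempotent.

The replicate for density estimation is the *sample unit*: images of one
treatment drawn uniformly without replacement until the accumulated seabed
area reaches 1,200 m² (about 1,060 images at the ~1.13 m² mean footprint).
The stopping rule — not an image count — is normative, so each unit's area
lies in [target, target + one image). Units are drawn pooling all transects
of a treatment by default (the source procedure is ambiguous on
stratification; `stratify_by_transect = TRUE` is available). Units must be
built from the usable (below-altitude-cutoff) image set: building them from
all images while counting only filtered annotations would bias densities
low by the unusable-area fraction — a pitfall caught by the estimator
recovery tests. Densities are counts over area; assemblage summaries report
morphotype and phylum richness and relative abundances that sum to 100 %.

## 4. Biogeochemical conversions

Two deliberately simple, unit-critical conversions are centralized:
bacterial biomass from summed bacterial PLFA carbon, `biomass = PLFA-C /
0.017` — the ratio is applied as PLFA-to-biomass *division* because the
reported biomass means (~92 mg C m⁻²) are ~60-fold typical PLFA-C
concentrations, and the direction is configurable; and daily carbon
assimilation from pulse-chase incubations, `(13C incorporated / 0.039) /
2.8`, where 0.039 is the fractional ¹³C abundance of the added algae and
2.8 is applied exactly as printed even though the ~70 h incubation is
nearer 2.92 days. Nodule metrics report both the pooled density (total
count over total area — the correct abundance estimator) and the mean of
per-core densities; the two differ whenever core areas differ, and tests
keep the distinction honest. Box-plot summaries use linearly interpolated
quartiles (R's default convention, documented) and 1.5 × IQR whiskers.

## 5. The synthetic study system

`synth_config()` fixes the generator's defaults to the field system's
statistical structure: nodules as a Poisson process at 155 m⁻² with
truncated-normal largest dimensions (72 ± 19 mm, > 10 mm), shaped as
spherical caps protruding 0.4 × diameter above the sediment (most nodules
sit at the surface; no burial model is reported, so the protrusion fraction
is a configurable choice); Gaussian sediment roughness of 3 mm SD; optional
uniform infill that raises the inter-nodule matrix while clipping against
nodule surfaces — the signature plume deposition leaves. Hard-core
repulsion between nodules is omitted (overlaps are handled by taking the
upper envelope; a warning fires if Boolean-model coverage would exceed
50 %). Megafauna densities default to 0.33 (control), 0.28
(predisturbance), 0.05 (collection track), 0.15 (propulsion track,
intermediate by report) and 0.45 (plume, elevated) individuals m⁻²; the
propulsion-track composition pins its two dominants at 42 % and 33 % over a
35-taxon pool. Image footprints are Gamma(mean 1.13 m², CV 0.25), altitudes
cluster near the 2.5 m survey target with a 5 % unusable fraction above
3.5 m, and sizes are 20 mm + lognormal(log 25, 0.5); sub-threshold and
tube-dweller annotations are injected at 0.25× and 0.1× the detectable rate
purely to exercise the filters. PLFA and ¹³C values are lognormal around
means chosen so the conversions recover 92/52 mg C m⁻² and
0.032/0.012 mg C m⁻² day⁻¹ on/off track; nodule masses follow
2.66 × 10⁻⁴ g mm⁻³ × dimension³, which reproduces 18.6 kg m⁻² at the
default density and size distribution.

What the generator does *not* emulate: spatial autocorrelation of fauna,
photorealistic imagery, temporal recolonization dynamics, or real DTM
artefacts (holes, seams, attitude error beyond the nodata mechanism).
Passing tests therefore demonstrate that the pipeline's estimators recover
known generating parameters under the assumed sampling models — not that
the field data satisfy those models.

## 6. Statistical engine and numerical choices

The Kruskal–Wallis statistic uses midranks and the standard tie
correction, with a $\chi^2_{k-1}$ reference (adequate at the n = 180
design; an exact test is unnecessary there), and degenerate all-tied input
returns H = 0, p = 1 rather than an error. The rank-sum test is two-sided
throughout; for pooled samples up to 12 the p-value is exact by full
enumeration of rank assignments, $p = P(|W - \mu_W| \ge |w - \mu_W|)$,
which equals the classical doubled-tail definition for untied data; larger
samples use the normal approximation with tie-corrected variance and
continuity correction, which agrees with the exact tail to < 0.02 at
10 vs 10. Holm's step-down adjustment is the default multiplicity
correction. All three are cross-checked in the test suite against
independent routes (`stats::kruskal.test`, `stats::wilcox.test`,
`stats::p.adjust`, and a brute-force enumeration oracle) without being
implemented by them.

Determinism is seed-scoped: every stochastic operation takes an integer
seed and restores the RNG state afterwards, multi-transect and
multi-treatment wrappers derive per-stratum streams by offsetting the base
seed, and `run_pipeline()` records package version, seed and a
configuration hash in its manifest so a rerun is bit-identical.

## 7. Problem sizes used in the shipped checks

The shipped tests and acceptance script run the full 3 × 3 scenario grid on
the complete reconstructed loop at 2 m cells (≈ 280,000 cells, ≈ 800
releases per scenario), micro-relief on 1 × 1.5 m to 2 × 10 m DTM patches at
1 cm, estimator-recovery studies over 50 seeds, burial monotonicity over 20
seeds × 4 infill depths, and 10,000 null simulations for the
Kruskal–Wallis calibration — sizes chosen so the statistical assertions
have comfortable Monte-Carlo margins while the whole suite completes in
well under a minute on a single core.

## 8. Known limitations

The deposition model omits ambient advection, stratification,
flocculation, and post-depositional resuspension, and its discrete-release
geometry is a modelling convention (see §1); it is a near-field envelope
tool, not a far-field transport model. Micro-relief is a single rugosity
metric; slope- or TRI-based alternatives are out of scope. The community
module assumes morphotype identifications and counting conventions are
resolved upstream and encoded as columns. The biogeochemical conversions
are linear bookkeeping, not a carbon-cycle model; their constants carry the
cited measurement conventions.
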