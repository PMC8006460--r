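---
title: "Methods: per-tree evapotranspiration phenotyping from airborne rasters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-tree evapotranspiration phenotyping from airborne rasters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orchardet)
```

This vignette documents the scientific and numerical choices behind
`orchardet`: what each stage computes, which parameters matter and why they
default to the values they do, what the synthetic campaign generator does
and does not emulate, and where the method's real limits are. It states no
empirical number that the test suite or the analysis scripts do not
themselves compute.

## Data model and geometry

Rasters are plain matrices with square-or-rectangular cells, an upper-left
map origin, and a nodata sentinel that is only ever consulted through a
mask. Pixel `(i, j)` has its center at `origin + ((j - 0.5) dx, -(i - 0.5)
dy)`, and every cell-membership test is half-open (min edge in, max edge
out), so the per-tree 4.5 m × 5.0 m sampling rectangles partition the
orchard without ever sharing a pixel. The 4.5 m side is aligned with the
row direction; the row orientation of the original trial is not published,
and an axis-aligned grid makes zonal counts unambiguous. Thermal (0.25 m)
and multispectral (0.10 m here; 0.03 m in real campaigns) layers are
processed at native resolution; nearest-neighbor resampling is applied only
when a per-pixel operation needs both grids at once (the class mask over
the thermal layer). On-disk format is the Esri ASCII grid with a `.prj`
sidecar: a text format any GIS reads, and one whose write-read roundtrip is
bit-exact at 17 significant digits.

## Solar geometry and psychrometrics

Declination and the equation of time come from the Spencer day-angle
Fourier series; no refraction correction is applied. Against the two
printed flight zeniths of the source trial the series agrees to ~0.3-0.5°,
which is the accuracy ceiling of any simple declination model and is
inconsequential for radiation partitioning (cos θ changes by < 1%).
Acquisition clock times are interpreted as decimal hours UTC, with the
longitude correction (+lon/15 h) and the equation of time producing
apparent solar time; `time_ref = "local_solar"` bypasses both.
Psychrometrics are standard FAO-56: Tetens saturation pressure, linear
λ(T), γ = C_p P/(0.622 λ), and moist-air density from virtual temperature.
One caveat a user should know: the linear λ(T) formula dips to
2.3948 MJ kg⁻¹ at 45 °C, marginally below the often-quoted 2.4 MJ kg⁻¹
floor; the tests assert the formula's true endpoints.

## Structure stage

CHM = max(DSM − DTM, 0), nodata propagating. The semi-automatic
classification of the original workflow is replaced by a deterministic
threshold rule — vegetation if NDVI ≥ 0.4 and CHM ≥ 0.3 m, weed if green
but low, soil split into sunlit/shaded at NIR reflectance 0.15 — because a
reproducible pipeline cannot depend on an operator-in-the-loop plugin. The
thresholds are configuration, not constants of nature; 0.4 is a
conservative NDVI for woody canopies over bright dry soil, 0.15 separates
the roughly 2.5:1 brightness ratio between sunlit soil and cast shadow.

Crowns are delineated by a marker-controlled watershed (seeded region
growing on the inverted CHM restricted to vegetation pixels, via
`EBImage::propagate`), one marker per mapped tree position, snapped to the
nearest vegetation pixel within 1 m when the position falls on background.
Ties resolve by ascending tree id, and each crown is clipped to 1.5× its
own grid cell — trees in a managed orchard do not reach into the
next-but-one row, and the cap prevents a vigorous tree from swallowing a
failed neighbor. Crown area is pixel count × cell area; total volume sums
CHM over crown pixels; net volume subtracts the prism
`crown_area × insertion_height` (the only raster-consistent reading of
"volume between the ground and the branch insertion"), floored at zero.

## Spectral traits

The five vegetation indices (NDVI, GNDVI, MCARI, NDRE, MSRre) follow their
standard six-band formulations with guarded denominators. MCARI has no
closed range and is flagged rather than clipped.

The Norman–Jarvis gap-fraction model links LAI and PAR transmittance
through the ellipsoidal extinction coefficient K(χ, θ) and the absorptivity
polynomial A(a) = 0.283 + 0.785a − 0.159a², at the ceptometer default
a = 0.9. χ defaults to 1 (spherical), the LP-80 convention; an average
leaf angle maps to χ by Campbell's closed-form approximation
ALA(rad) = 9.65(3 + χ)^−1.65. The beam fraction defaults to 0.85, a
clear-sky midsummer value; it is not observable from the imagery and is
exposed in the call signature. Forward and inverse are exact algebraic
inverses, which the tests verify to 1e-9 across LAI ∈ [0.1, 6],
θ ∈ [0°, 60°], fb ∈ [0.2, 1].

Daily intercepted fraction uses an hourly hedgerow-shadow model: the shaded
ground fraction S(t) = min(1, (w + h tanθ_s |sin(az_sun − az_row)|)/L) for
hedge width w, height h and row spacing L, attenuated by a porosity p
solved in closed form so that S(noon)(1 − p) equals the observed
instantaneous interception, then integrated with clear-sky irradiance
weights. This hedgerow formulation is this package's own stand-in for the
(unpublished) hourly model used with field ceptometry; it preserves the
calibrate-at-noon-then-integrate structure, which is the part that matters
for the daily value.

### Reflectance-model inversion and its identifiability limit

Trait retrieval trains one regressor per target (LAI, fiPAR) on spectra
simulated by a forward canopy reflectance model over uniform, independent
parameter ranges (leaf structure index 1.2–2.2, chlorophyll 0–90 µg cm⁻²,
brown pigment 0–1, water and dry matter 0.003–0.011 g cm⁻², LAI 0–6,
average leaf angle 30–80°, hotspot 0.1–0.5). The operational default is
100 000 simulations; the committed analyses and tests train at n = 5000,
which the recovery experiments show is already past the point of
diminishing returns for this forward model. The default engine is a
single-hidden-layer feed-forward network (20 units, fixed seed, inputs
standardized, predictions clipped to the training range); a k = 1
nearest-neighbor engine is selectable where bitwise determinism matters
more than smoothness. Models serialize to JSON (weights, normalization,
ranges, seed) and reload with identical predictions.

The built-in forward model is a deliberate surrogate, pluggable behind
`rt_forward()`: leaf reflectance is an asymptotic spectrum attenuated
exponentially by chlorophyll, water, dry matter and brown pigment, and the
canopy mixes leaf and soil spectra through exp(−2K·LAI). That last
expression is also its honest limitation: **reflectance depends on LAI and
leaf angle only through the product K·LAI**, so no inversion — neural,
nearest-neighbor or Bayes-optimal — can separate a sparse canopy of
horizontal leaves from a denser canopy of erect ones. A conditional-mean
oracle over the training prior puts the best achievable LAI RMSE near 0.77
under these ranges, and the trained network lands close to that floor;
fiPAR = 1 − e^{−K·LAI}, being a function of the identified product, is
recovered almost exactly (RMSE < 0.01). A full radiative-transfer model
resolves the ambiguity through the angular and spectral shape information
the surrogate omits — which is precisely why the corresponding acceptance
check on surrogate-based LAI recovery fails and is left failing, with this
paragraph as the analysis. On synthetic scenes the situation is benign:
trees share one leaf parameterization and span LAI 0.5–2, and
vegetation-masked spectra recover tree LAI with RMSE ≤ 0.4 as the tests
assert.

Per-tree operational inputs are the full grid-cell mean reflectances (the
cell is the sampling unit of the trial); the vegetation-masked mean is also
reported (`LAI_rt_canopy`), and it is the right input for recovery
comparisons because the cell mean dilutes the canopy signal with ~80% soil.

The empirical route is a forward-selection/backward-elimination stepwise
regression (enter at p < 0.05, remove at p > 0.10, OLS at each step, ties
to the lower column index) of a trait on the five VIs plus canopy volume,
reporting R² and residual standard error. Reference multi-date almond
calibrations for LAI and daily fiPAR are shipped as `trait_equation`
objects; evaluations are floored at zero with a flag.

## Energy balance

TSEB runs in its component-temperature mode: with ~0.25 m thermal pixels,
canopy and soil temperatures are observed directly (vegetation-masked and
soil-masked zonal means per cell), so no Priestley–Taylor initialization is
needed and latent heat is the per-source residual. Negative component LE is
retained and flagged, never redistributed — with measured T_c/T_s a
negative soil LE is information (a drying, hot soil), not an error state.
The stability loop iterates resistances, the series-network T_ac and H
until |ΔH| < 0.1 W m⁻² (≤ 50 iterations; the fallback is the neutral
solution plus a flag, and the tests confirm convergence across the
synthetic weather range).

Constants the trial never published are taken from the originating TSEB
literature and exposed in the call signature: κ = 0.45 (net-radiation
extinction), G = 0.35·Rn_s (midday soil-heat fraction), d = 0.65h,
z_om = 0.125h, z_oh = z_om/7, soil-resistance coefficients a_s = 0.004,
b_s = 0.012, bulk boundary-layer coefficient C' = 90 s^½ m⁻¹, leaf width
0.05 m, wind floor 0.5 m s⁻¹, measurement heights h_c + 2 m. Net radiation
(also unpublished for the trial) is modeled as (1 − α)Rs + ε_a σT_a⁴ −
ε_s σT_rad⁴ with Brutsaert air emissivity, α = 0.2, ε_s = 0.98, and the
cover-weighted composite radiometric temperature.

The Shuttleworth–Wallace potential rate uses the same neutral log-profile
aerodynamics, the bulk leaf resistance halved for the two leaf sides,
r_s_c = 100/(2·LAI) s m⁻¹ and a wet, non-limiting soil (r_s_s = 0). The
100 s m⁻¹ minimum stomatal resistance is the one published constant; its
upscaling by 2·LAI and the wet-soil choice are this package's documented
reading of "potential conditions". Daily upscaling of both actual and
potential ET uses the irradiance-ratio method, which assumes LE/Rs is
conserved over the day — fair under clear skies, biased on days with
afternoon advection.

## Water status

CWSI = 1 − ET_a/ET_p, clamped to [0, 1] with a flag: an actual rate
marginally above potential is sensor noise, not physiology. The irrigation
balance is ETc = max(0, ETo·Kc(month) − P_eff) with the almond calendar
Kc = 0.70, 0.95, 1.09, 1.15, 1.17, 1.12 (April–September) and the
effective-rainfall rule P_eff = rain/2 only for a single event-day strictly
above 10 mm. Water productivity divides kernel yield by the ET total of an
explicitly stated period — the period is an argument because "daily water
production" is ambiguous between one day and a season, and the choice
changes the number by two orders of magnitude.

## The synthetic campaign

The generator exists so that every stage has a truth table to be tested
against. It emulates: a 3-row × 10-tree block (30 trees, the size of one
treatment replicate of a 10-rootstock trial) at 4.5 × 5.0 m spacing;
half-ellipsoid crowns with per-tree height (2.7–5.5 m), radius (1.0–1.8 m)
and LAI (0.5–2.0, the span ground measurements in such orchards cover);
a gently sloping terrain; six-band reflectance rendered by the forward
model at each tree's LAI over the default bright-soil spectrum, with a
0.4× shadow strip cast to the anti-solar side; clear-sky diurnal weather
peaking near 930 W m⁻² with midday VPD of 2–4 kPa; and a thermal field in
which the imposed stress factor s ∈ [0, 1] enters only through canopy
temperature, T_c = T_a + 1 + 9s K, spanning the 1–10 K canopy-air range
observed in stressed orchards, while soil stays at T_a + 12 K (sunlit) /
T_a + 4 K (shaded). Multispectral cells are 0.10 m (a 200 × 500 px scene,
seconds to generate) rather than the 0.03 m of a real campaign.

Numerical detail that matters: DSM noise (σ = 0.08 m) is generated as a
spatially correlated field (0.5 m grid, bilinear upsampling), because
photogrammetric surface error is smooth. White pixel noise would inflate
the per-tree *maximum* height by roughly three standard deviations over a
crown's thousands of pixels; correlated noise keeps the maximum statistic
honest, and the structure stage indeed recovers heights with RMSE well
under 2σ.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about real data: between-crown radiative interactions
and row shadows falling on neighboring canopies, BRDF and sensor PSF
effects, mixed pixels at crown edges at real 0.03 m/0.25 m scales,
registration error between sensors, leaf-parameter variation between trees,
and any soil-moisture feedback on soil temperature (the generator's soil is
uniformly hot and dry, independent of s). One visible consequence: because
the soil is dry while the potential model assumes a wet soil surface, even
unstressed trees carry a CWSI offset of roughly 0.3–0.5 in these scenes.
The index still ranks trees correctly — the monotonicity checks
(Spearman ≥ 0.9 between s and CWSI) are the meaningful validation here —
but the absolute CWSI of a synthetic unstressed tree is not near zero, and
users comparing absolute values against field expectations should know
why. A second consequence of the bright-soil/threshold interplay: crowns
with LAI ≈ 0.5 sit at the NDVI ≈ 0.4 classification knife-edge and can go
undetected in noiseless renders; they are flagged, not silently dropped.

## Problem sizes and runtimes

The committed analyses and the test suite use: 30–40-tree scenes at 0.10 m
cells, inversion training at n = 5000 with 300–500 held-out spectra, 1000
Monte-Carlo replicates for the stepwise selection-rate check, and two
full pipeline seeds (42, 43) for the end-to-end monotonicity check. The
whole suite runs in about a minute on one core; a single pipeline run is
~6 s. These sizes were chosen as the smallest at which the stochastic
checks are stable; scaling the generator or the training set up is a
configuration change, not a code change.

## Known limitations

- The surrogate forward model's LAI/leaf-angle confounding (above) bounds
  surrogate-based LAI inversion; plug a full radiative-transfer
  implementation into `rt_forward`'s contract for real retrievals.
- Neutral stability is assumed for the S-W aerodynamic terms; under strong
  midday instability the potential rate is slightly underestimated.
- The hedgerow interception model ignores row-end effects and assumes an
  opaque rectangular cross-section modulated by a single porosity.
- The irradiance-ratio daily upscaling ignores diurnal asymmetry in
  stomatal behavior.
- Zonal statistics assume the tree table's grid cells are correct; no
  re-registration against the imagery is attempted.
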