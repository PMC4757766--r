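# imeffect

Tools for quantifying the **Island Mass Effect (IME)** — the localized
enhancement of phytoplankton biomass in the waters around oceanic islands
and atolls — from gridded ocean-colour fields, and for modelling what
drives its strength.

The package is aimed at marine spatial ecologists and ocean-colour remote
sensing analysts. It implements the full analysis chain:

- **Sector geometry.** The 30-m isobath is traced from bathymetry
  (sub-pixel marching squares); every pixel gets its great-circle distance
  to it (km / 111.195 per degree, cos-latitude longitude scaling). Eight
  concentric bands of width `w = 0.0295°` (half the diagonal of a 0.0417°
  satellite pixel, ~3.27 km) span `[k·w, (k+1)·w)` for `k = 1..8`; pixels
  within `w` of the isobath are excluded as optically shallow. Pixels
  shared between neighbouring locations are removed, and locations sharing
  more than half their pixels merge into island complexes with combined
  bathymetry.
- **Gradient analysis.** Sector-mean chlorophyll follows a power law in
  distance, `chl = a·d^b`, fit as OLS on log–log axes. The slope `b` is
  the IME index: a location is *enhanced* when `b < 0` with `p < 0.05`.
  An ANCOVA interaction F tests slope heterogeneity among locations.
- **Standing stock.** Depth-integrated chlorophyll `ΣChl = chl / k490`
  (mg m⁻²); band 8 is the offshore reference, and
  `Σ_k (ΣChl_k − ΣChl_8) · area_k` over bands 1–7 is the phytoplankton
  mass (kg, and % of the offshore baseline) each island adds.
- **Driver model.** IME strength `|b|` versus biogeophysical predictors
  (geomorphic type, reef/land area, bathymetric slope, population status,
  climate summaries): VIF-based collinearity pruning, gamma GLM with log
  link, all-subsets AICc selection with two-way interactions under strong
  hierarchy, nested-model analysis of deviance, and hierarchical
  partitioning of explained deviance `D² = 1 − deviance/null deviance`.
- **In-situ profiles.** Trapezoidal 5–300 m integration of fluorometer
  casts and a nonlinear `c0 + A·exp(−x/λ)` fit of the cross-shore trend,
  centred to zero at 30 km.
- **Synthetic scenes.** A generator with known ground truth (power-law
  chlorophyll decay, parametric island/atoll bathymetry, lognormal noise,
  missing pixels, gamma-distributed driver responses, Gaussian
  deep-chlorophyll-maximum profiles) makes the whole pipeline testable
  without any satellite downloads.

## A worked example

Generate a synthetic island scene, build its sectors, fit the chlorophyll
gradient and total the standing-stock enhancement:

```r
library(imeffect)

sc      <- generate_scene(scene_config(ime_exponent = -0.4, seed = 42))
sectors <- scene_sectors(sc, "ATOLL-A")
series  <- sector_means(sc$chl, sectors)
fit     <- fit_gradient(series)
fit
#> <ime_gradient_fit> ATOLL-A : b = -0.383 (p = 2.31e-07 , r2 = 0.991 , n = 8 bands)
classify_ime(fit)
#> [1] "enhanced"

stock <- depth_integrated_chl(sc)
sigma <- sector_means(stock$sigma_chl, sectors)
enhancement(sigma, sector_area(sectors), fit_gradient(sigma),
            sigma_grid = stock$sigma_chl, sector_set = sectors)
#> <ime_enhancement> ATOLL-A - total 22150 kg (+ 25.28 % over offshore baseline)
```

The fitted slope (−0.38 for a true exponent of −0.4; the small gap is the
additive offshore baseline plus discretization) says chlorophyll rises
steadily toward shore; the island holds ~22 tonnes (+25%) more
phytoplankton in its nearshore bands than the same area would at offshore
concentrations. Every fitted object has broom-style methods
(`tidy()`, `glance()`) and a ggplot `autoplot()`.

The full pipeline — 28 synthetic locations drawn from a known driver
model, gradients, enhancement totals, and the driver GLM with selection
and partitioning:

```r
report <- run_pipeline(pipeline_config(seed = 1))
report
#> <ime_run_report>
#>   locations enhanced: 25 / 28 (89.3%)
#>   slope heterogeneity: F(27,168) = 408.41, p = 9.18e-139
#>   standing-stock enhancement: 2.95e+06 kg combined (+144.2%) over 22 locations
#>   best driver model: ~geomorphic_type + reef_area + bathy_slope + population_status + reef_area:population_status + bathy_slope:population_status (D2 = 0.96, AICc = -84.9)
#>   partition: geomorphic_type 9%, reef_area 59%, bathy_slope 7%, population_status 25%
```

See `vignette("island-mass-effect")` for the model, its assumptions, and
every numerical convention.

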