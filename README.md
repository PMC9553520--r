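# octspeckle

Speckle-statistics texture analysis for optical coherence tomography (OCT).

Transparent and semi-transparent structures — lymphatic vessels, peripheral
nerves, clear fluids — are nearly invisible to conventional OCT contrast,
which looks for backscattered signal. What they do carry is *texture*: the
granular speckle pattern of a region encodes its scatterer content even when
the mean intensity is low. `octspeckle` turns that texture into a
quantitative contrast mechanism and a six-way material classifier, and
ships a synthetic phantom simulator so the entire pipeline can be exercised
and validated without instrument data.

## The statistic

For a region of interest (ROI) of 6 × 6 × 10 voxels (depth × fast × slow),
pooled over 24 repeated B-scans into an 8640-pixel sample, the intensity
histogram is fitted with the three-parameter Rayleigh density

```
P(x; a, b, c) = a (x − c) / b² · exp(−(x − c)² / (2 b²)),   x ≥ c
```

where `a` is the amplitude normalisation, `b` the scale and `c` the shift.
Fully developed speckle follows this law almost perfectly; deviations are
informative. Three features are extracted per ROI or per sliding window:

- **R²** — goodness of fit on the histogram heights. Near 1 for air, noise
  and clear fluids; visibly degraded (< 0.93) in dense scatterers such as
  Intralipid.
- **a** — deviates from 1 when the histogram shape departs from a single
  Rayleigh (noise-floor convolution pushes it up, scatterer contamination
  pulls it around).
- **c** — the fitted shift; dragged far negative when a dim secondary
  intensity component is present.

An RBF-kernel SVM on `(R², a, c)` with stratified five-fold cross-validation
classifies six material classes (air, noise, dyed water, transparent solid,
semi-transparent solid, Intralipid). Two classical baselines — the
depth-resolved attenuation coefficient `μ[i] = I[i] / (2Δz Σ_{j>i} I[j])`
and four grey-level co-occurrence (GLCM) Haralick features — are trained
identically for comparison.

## Worked example

```r
library(octspeckle)

# a tissue-mimicking phantom: semi-transparent tube (dyed-water lumen) and
# transparent rod in Intralipid-gelatin, with ground-truth labels
ph <- generate_phantom(phantom_config(seed = 1))

# fit one ROI in the air gap and one in the scattering background
for (reg in c("air", "intralipid")) {
  roi <- place_rois(ph$labels, reg, n = 1, seed = 1)
  print(fit_rayleigh(pool_roi(ph$volume, c(roi$depth, roi$fast, roi$slow))))
}
#> Three-parameter Rayleigh fit
#>   a = 0.9969, b = 0.9923, c = -0.193
#>   R^2 = 0.9915  (SSE 0.0267, 8640 pixels, 64 bins)
#> Three-parameter Rayleigh fit
#>   a = 2.698, b = 2.309, c = -3.505
#>   R^2 = 0.8231  (SSE 0.456, 8640 pixels, 64 bins)

# the air histogram is near-perfect Rayleigh (R^2 0.99, a ~ 1, c at the
# generative offset); the dense scatterer fits poorly, with c dragged
# far negative -- exactly the signatures the classifier feeds on

glance(fit)          # one-row summary
autoplot(fit)        # histogram with the fitted curve

# region-wise study: 2 phantoms x 10 ROIs per region
study <- run_roi_study(phantom_config(), rois_per_region = 10, seed = 1)
summarise_roi_study(study)[, 1:4]
#> # A tibble: 6 × 4
#>   region                     n r_squared_mean r_squared_sd
#>   <fct>                  <int>          <dbl>        <dbl>
#> 1 air                       20          0.993      0.00212
#> 2 noise                     20          0.992      0.00232
#> 3 dyed_water                20          0.982      0.00572
#> 4 transparent_solid         20          0.979      0.00645
#> 5 semi_transparent_solid    20          0.953      0.00972
#> 6 intralipid                20          0.814      0.0259
```

The R² ordering — air and noise highest, then the clear fluid and
transparent solid, then the semi-transparent wall, with the scattering
Intralipid background far below — is the contrast that separates
"transparent structure" from "tissue". Classification quantifies it:

```r
reports <- classifier_study(ph$volume, ph$labels, per_class = 30,
                            folds = 5, n_randomizations = 10, seed = 1)
attr(reports, "comparison")
#> # A tibble: 3 × 3
#>   feature_set accuracy_mean accuracy_sd
#>   <chr>               <dbl>       <dbl>
#> 1 rayleigh             76.2        3.00
#> 2 attenuation          67.5        3.08
#> 3 glcm                 40.7        6.46

autoplot(reports$rayleigh)                # confusion-matrix heatmap
autoplot(reports$rayleigh, type = "roc")  # per-class ROC with optimal points
```

The Rayleigh features beat both baselines; air and noise remain mutually
confusable (their scale-normalised histograms are identical by
construction), which is also where real instruments struggle.

A thin command-line front end over these functions is installed at
`system.file("scripts", "octspeckle.R", package = "octspeckle")` with
subcommands `simulate`, `fit-roi`, `feature-map`, `attenuation`, `glcm`,
`classify`, `roi-study` and `flow-study`.

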