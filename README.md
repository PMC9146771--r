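# thermofoot

Prior-shape active contours (snakes) for segmenting the plantar foot in
infrared thermograms, with a hyperthermia-detection pipeline for
diabetic-foot screening.

## The problem

Freehand plantar thermography — both feet imaged at once with a
smartphone thermal camera, no isolating enclosure — leaves legs, ankles
and other warm body parts in the frame. These produce *false* thermal
boundaries stronger than parts of the true foot outline (the cool toes
sit barely above a ~20 °C background), and classical edge- or
region-driven segmentation fails. Robust segmentation is the prerequisite
for the clinically meaningful quantity: the point-to-point temperature
asymmetry |ΔT| between the two feet, where a difference above 2.2 °C
(hyperthermia) is a recognized pre-sign of ulceration.

## What the package implements

All methods share preprocessing (two-feet split and left-foot flip, Otsu
thresholding, line/box morphological cleanup, gravity centers), an
average prior foot shape, and the same initialization: the prior
downsized by a factor 2, placed vertically at the gravity center, inside
the plantar surface.

* **Curvature-prior snake** (`segment_snake()`) — the reference method: a
  parametric snake with internal tension/rigidity, an image force on
  |∇(G<sub>σ</sub> ∗ I)|², a constant outward balloon pressure, and a new
  prior energy γ·|C<sub>ss</sub> − ζ·C\*<sub>ss</sub>|² with
  ζ = |C<sub>ss</sub>|/|C\*<sub>ss</sub>|, the normalized curvature
  difference to the prior shape. With both curves parameterized from the
  heel, the term is invariant to translation, rotation and scale, so no
  pose parameters are estimated during evolution (semi-implicit
  Euler–Lagrange update). Reference weights: α = 0.1, β = 4,
  W<sub>edge</sub> = 20, δ = 0.2, γ = 35.
* **Greedy Fourier-prior snake** (`segment_greedy()`) — comparator:
  similarity-normalized Fourier descriptors of the contour matched to the
  prior's, minimized by classic greedy neighborhood search
  (α = 1.2, β = 0.1, W<sub>edge</sub> = 5, δ = 0.1, γ₀ = 0.5).
* **Geodesic prior-shape snake** (`segment_geodesic()`) — comparator:
  geodesic edge energy plus the squared fast-marching distance to the
  placed prior, with joint descent of the curve and a similarity
  transform (b = 0.1, σ = 0.3, λ = 8, μ₀ = 1, θ₀ = 0, T₀ = 0).
* **Seeded thermal-foot phantom generator** (`render_phantom()`,
  `phantom_suite()`, `render_phantom_pair()`) — 385 × 257 px per-foot
  frames with a butterfly interior pattern (warm arch, cool toes), warm
  clutter outside the foot, optics blur, optional white noise at a
  prescribed SNR, and exact ground truth.
* **Evaluation** (`contour_rmse()`, `dice_coefficient()`,
  `two_sample_ttest()`, `run_benchmark()`) — directed contour RMSE,
  Dice overlap, one-sided t statistics, and a benchmark harness over
  initialization offsets and SNR grids.
* **Hyperthermia pipeline** (`hyperthermia_pipeline()`) — rigid ICP
  registration of the segmented feet, point-to-point |ΔT| on the common
  region, 8-connected regions above 2.2 °C filtered at the area of a
  1 cm disk.

Results are tibbles or lightweight S3 objects with `tidy()`, `glance()`
and `autoplot()` methods. A thin command-line wrapper lives at
`inst/cli/thermofoot.R`.

## Worked example

```r
library(thermofoot)

prior  <- default_prior(200)                      # average foot shape
sample <- render_phantom(phantom_spec(), seed = 42)
loc    <- locate_foot(sample$image)               # Otsu + morphology
fit    <- segment_snake(
  sample$image, make_initial_contour(prior, loc$center, 2), prior
)

glance(fit)
#> # A tibble: 1 x 6
#>   method   iterations converged e_total area_px perimeter_px
#>   <chr>         <int> <lgl>       <dbl>   <int>        <dbl>
#> 1 proposed        760 TRUE        -9.34   23626         659.

dice_coefficient(fit$mask, sample$mask)
#> [1] 0.9995342
contour_rmse(sample$contour, fit$contour)
#> [1] 0.2038375

autoplot(fit, image = sample$image)   # contour over the thermogram
```

The snake converged in 760 iterations; its mask overlaps the ground
truth with Dice 0.9995 and the ground-truth contour lies on average a
fifth of a pixel from the fitted one.

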