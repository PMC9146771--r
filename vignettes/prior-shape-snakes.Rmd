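---
title: "Prior-shape snakes for plantar thermography: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior-shape snakes for plantar thermography: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5)
library(thermofoot)
```

## The segmentation problem

Infrared thermography of the plantar foot is a promising screening tool
for the diabetic foot: a point-to-point temperature difference above
2.2 °C between one foot and the contralateral region (hyperthermia) is a
recognized pre-sign of ulceration. A contactless, freehand acquisition
protocol — both feet imaged at once, no isolating enclosure — makes the
exam practical, but it leaves legs, ankles and other warm body parts in
the frame. Those create strong *false* thermal boundaries, while parts of
the true foot outline can be weak (the cool toes sit barely above the
background). Classical edge- or region-driven segmentation fails on such
images; shape knowledge must be brought in.

`thermofoot` implements a family of prior-shape active contours (snakes)
around five pieces of prior knowledge: the plantar outline is a single
closed curve; its average shape is known; it has only soft curvatures
(roughly an oval); no strong edges exist inside the plantar region; and
the feet are vertical or nearly so. Three methods share the same
preprocessing, prior shape and initialization:

* the **curvature-prior snake** (the package's reference method): a
  parametric snake with a balloon force plus a new prior energy on the
  *normalized curvature difference* to the average foot shape;
* a **greedy snake with Fourier-descriptor shape matching**: the prior
  enters as a distance between similarity-normalized Fourier descriptors,
  minimized by exhaustive per-point neighborhood search;
* a **geodesic snake with a distance-map prior**: the curve and a
  similarity transform (scale, rotation, translation) are descended
  jointly on a geodesic edge energy plus the squared fast-marching
  distance to the placed prior curve.

## The curvature-prior model

A closed contour $C(s)$, $s \in [0,1)$, sampled at $n$ points, evolves to
minimize

$$E = \int_0^1 \big(\alpha|C_s|^2 + \beta|C_{ss}|^2
      \;-\; W_{edge}\,|\nabla I(C)|^2 \;+\; \delta\,\eta(C)
      \;+\; \gamma\,|C_{ss} - \zeta\, C^*_{ss}|^2\big)\, ds ,$$

where $C^*$ is the prior contour,
$\zeta(s) = |C_{ss}(s)| / |C^*_{ss}(s)|$ a per-point curvature
normalization, $\eta$ the outward unit normal, and the stationarity
condition couples the fourth derivatives:
$-\alpha C_{ss} + (\beta+\gamma)C_{ssss} - \gamma\zeta C^*_{ssss} +
\partial(E_{image}+E_{balloon})/\partial C = 0$.

Both curves are examined from the same start point — the lowest point of
the heel (maximal $y$ in image coordinates, ties to the smallest $x$) —
which fixes the parameterization correspondence for the quasi-vertical
feet the protocol produces. The curvature difference is evaluated in each
curve's local tangent/normal frame: translation never enters a second
derivative, rotation cancels in the local frame, and scaling cancels
through $\zeta$, so the prior energy is invariant under similarity
transforms of the evolving contour and no pose parameters need to be
estimated (this is also what the package's invariance tests check,
exactly, to $10^{-6}$). Because of the normalization the prior constrains
the *shape* of the curvature profile, never the size: growth from a small
initialization is left entirely to the balloon and image forces.

The initialization is the prior downsized by a factor 2 and placed at the
foot's gravity center (Otsu threshold, line-erosion/box-dilation cleanup,
largest 4-connected component, centroid). Starting inside the plantar
surface and growing outward is what lets every method ignore the false
boundaries outside the foot.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.1 | tension (first-derivative) weight |
| `beta` | 4 | rigidity (second-derivative) weight |
| `w_edge` | 20 | image energy weight on $|\nabla(G_\sigma * I)|^2$ |
| `delta` | 0.2 | balloon pressure (outward, px per unit time) |
| `gamma` | 35 | prior-curvature weight |
| `tau` | 0.4 | time step |
| `sigma_img` | 2 px | Gaussian smoothing before the gradient |
| `n` (prior) | 200 | number of contour points |

The energy weights are the reference set for plantar thermograms. They
presume the usual snake intensity convention: the image is rescaled to
$[0,1]$ and the squared-gradient edge map to unit maximum before
differentiation (`external_force_field(..., normalize = TRUE)`, applied
automatically by `segment_snake()`). On that scale the maximal image
force (~`w_edge` × the edge-map slope) exceeds the balloon pressure
`delta` several-fold at every true boundary segment, including the weak
toe boundary, which is exactly the balance the method needs: the balloon
wins over flat regions and noise, the edges win at the boundary.

`sigma_img = 2` px was chosen of the order of the optics blur so that the
white-noise floor at the lowest studied SNR (5 dB) stays well below the
weakest (toe) boundary response; smaller values sharpen the clean-image
result slightly but surrender the toe boundary to noise at low SNR, and
larger values dilute the toe edge below the balloon pressure. The number
of snake points is not prescribed by the protocol; 200 points give a
sub-pixel sampling of a ~700 px perimeter and are exposed as
configuration.

### Numerics

The evolution uses the classical index-step (unit-spacing) discretization
of the contour derivatives. On the normalized arclength parameterization
($h = 1/n$) the fourth-derivative operator scales like $(2\pi k)^4$ and
the reference rigidity $\beta + \gamma = 39$ would contract any contour
to its centroid within one step; the reference weights are only
meaningful on the index-step scale, which is therefore what
`segment_snake()` uses. (`curvature_profile()` deliberately keeps the
resolution-independent $h = 1/n$ scaling for analysis purposes — a circle
of radius $r$ reports $|C_{ss}| = (2\pi)^2 r$ at any $n$.)

The update is semi-implicit: the pentadiagonal periodic operator
$A = -\alpha D_2 + (\beta+\gamma) D_4$ is inverted once per run
($(I + \tau A)^{-1}$, dense $n \times n$), and the image, balloon and
prior-pull forces enter explicitly with $\zeta$ frozen at the current
iterate. Further numerical safeguards, each stated with its rationale:

* $\zeta$ is clamped at 10: near-straight prior segments make the
  curvature ratio ill-conditioned, and transient curvature spikes of the
  evolving contour must not be amplified through the prior pull;
* the explicit image + balloon force is capped at 2 px per step (the
  prior pull is *not* capped — it is balanced by the implicit
  $(\beta+\gamma) D_4$ term, and clipping only one side of that balance
  destabilizes large $\gamma$);
* the force-field magnitude is additionally capped at its 99th
  percentile over the *active* (non-flat) pixels, guarding against
  isolated gradient spikes;
* the contour is re-resampled to uniform arclength and re-aligned at the
  heel every 10 iterations;
* `tau = 0.4` keeps the explicit part inside its stability bound at the
  strongest edges while the balloon (0.08 px/iteration) crosses the
  ~75 px from the downsized initialization to the boundary within the
  default iteration budget (1600);
* convergence is declared when no point drifts faster than `tol`
  (0.05 px/iteration) *net over a full resampling window*. A windowed
  maximum separates genuine balloon creep of a still-growing arc (which a
  mean over mostly-pinned points hides) from bounded sub-pixel dither at
  a pinned edge (which an instantaneous maximum never forgives).

## The comparator snakes

**Greedy Fourier-prior snake.** Contour points are the complex signal
$x + iy$; its DFT coefficients, normalized by zeroing the DC term,
dividing amplitudes by $R_1$ and subtracting $\theta_1$ from all phases,
are invariant to translation, scale and rotation. The prior energy is
$\gamma_0 \sum_k |\hat Z_k - \hat Z^*_k|^2$. Each pass moves every point
to the minimizing position of its 3×3 neighborhood, with the continuity,
curvature, image, balloon and prior terms min-max normalized within the
neighborhood (the classical greedy normalization); descriptors are
maintained across moves by exact rank-one DFT updates, with the full
recomputation kept as the test oracle. Known limitation (shared with the
tradition it reimplements): the min-max normalization amplifies whatever
variation exists in a window, so on noisy images the greedy walk is
image-term-driven and tends to freeze in local minima far from the
boundary; its noise robustness is well below the other two methods'.

**Geodesic prior-shape snake.** The energy density is
$g(|\nabla I|) + \tfrac{\lambda}{2} d^2(\mu R C + T)$ integrated along
the curve, with $g = 1/(1 + b|\nabla(G_\sigma * I)|^2)$ evaluated
literally in °C and $d$ the unsigned fast-marching distance to the prior
placed at the gravity center. Its curve-shortening flow contributes
$(\lambda/2) d^2 \kappa$ — the variationally consistent factor for a
$\tfrac{\lambda}{2}d^2$ density — plus the attraction
$\lambda \mu\, d\, \nabla d \cdot (R\eta)$; scale, rotation and
translation are descended simultaneously. Numerical choices: the descent
step is rescaled globally so no point moves more than 2 px per iteration
(the quadratic distance term is enormous far from the prior; per-point
clamping would destroy the velocity field's shape, global rescaling
preserves it); curvature is clamped to $|\kappa| \le 0.5$; the scale and
rotation gradients are normalized by the curve's mean squared radius so
one `rate_transform` serves all three pose channels; pose acts about the
curve's own centroid (centring it on an external point leaks translation
offsets into the scale/rotation channels); and the transform-channel
motion is included in the convergence measure so pose-only descents do
not stop prematurely.

## The phantom: what it emulates and what it does not

The generator renders, per foot, a 385 × 257 px frame at ~1 mm/px: a
~20 °C background with a mild (<1 °C) gradient; a vertical foot-like
outline (ellipse of length ≈ 3 × width, deformed by ≤ 8 % low-order
radial harmonics — broadened forefoot, rounded heel — with seeded pose
and size jitter); a smooth butterfly interior (base 30 °C, warm arch
32 °C, cool toes 27.5 °C, slightly cool heel rim, transition scales
≥ 15 px so the interior carries no strong edges); warm elliptical clutter
(28–34 °C) strictly outside the plantar surface, emulating the legs above
the toes and lateral sources, whose edges are at least as strong as the
true boundary; a global 1.5 px optics blur; and optional white Gaussian
noise at a prescribed SNR. Two-feet frames (480 × 640) hold near-mirror
feet ~10 cm apart with small within-subject pose jitter, matching the
premise that healthy subjects are thermally near-symmetric. Everything is
bitwise reproducible from a seed, and every sample carries its
ground-truth contour, mask and clutter map.

What passing tests on phantoms do *not* show: real thermograms have
radiometric calibration error, emissivity variation, motion blur,
partial-foot and amputated-foot anatomy, and Flir overlay graphics — none
of which are modeled. Phantom results are a controlled surrogate for the
private clinical database this family of methods was designed for, not a
clinical validation. Accuracy numbers on the phantom suite are
systematically higher than published clinical values (the phantom's
boundary, however cluttered, is cleaner than reality), so suite results
should be read against the published values as *bounds from above*,
compared with `>=`/`<=` rather than equality.

## Evaluation harness

`contour_rmse()` is the directed nearest-vertex RMSE from ground-truth
points to predicted points, both resampled to ≥ 512 points to remove
discretization bias. `dice_coefficient()` is the usual overlap score.
`two_sample_ttest()` reports the one-sided pooled statistic (decision at
the 1.65 large-sample 5 % critical value) *and* the Welch variant,
because published comparison tables of this kind are often not exactly
reproducible from summary statistics alone — for the headline DSC
summaries (0.940 ± 0.02 vs 0.855 ± 0.07, n = 50 each) the pooled formula
gives 8.26, and the package asserts only its own formula's value.
`run_benchmark()` runs any subset of the three methods over a phantom
suite under initialization offsets (gravity center, ±15 px diagonals)
and an SNR grid ({25, 15, 10, 5} dB), sharing preprocessing and force
fields per image, and returns a tidy per-run tibble.

Problem sizes used by the shipped study (chosen to keep a laptop-scale
run): 50 phantoms per suite, 3 initialization placements, 4 noise levels,
20 two-feet pairs (with and without a 3 °C, 1 cm lesion) for the
hyperthermia study.

## Hyperthermia pipeline

Both feet are segmented with the curvature-prior snake; the flipped left
contour is registered onto the right by rigid ICP (nearest-neighbor
correspondence refined to the adjacent-segment projection, closed-form
SVD fit, no scaling — the feet of one subject are near-congruent and a
scale channel would absorb genuine size asymmetry); the left image is
warped through the transform and $|\Delta T|$ is evaluated on the
intersection of the registered masks (only there is the difference
defined point-to-point). Regions where $|\Delta T| > 2.2$ °C are
extracted as 8-connected components and filtered by the pixel area of a
1 cm diameter disk at the recorded pixel size — the smallest clinically
considered hot spot — to suppress isolated exceedances. The injected
phantom lesion correspondingly models a hot spot as a full-amplitude
plateau of the nominal radius with a cosine skirt, so that a "3 °C, 1 cm"
lesion exceeds the 2.2 °C criterion over (at least) its nominal extent.

## Worked example

```{r example, eval = FALSE}
prior <- default_prior(200)
sample <- render_phantom(phantom_spec(), seed = 42)
loc <- locate_foot(sample$image)
fit <- segment_snake(
  sample$image, make_initial_contour(prior, loc$center, 2), prior
)
glance(fit)
dice_coefficient(fit$mask, sample$mask)
autoplot(fit, image = sample$image)
```

## Known limitations

* The greedy baseline's noise fragility (above) means SNR robustness
  comparisons are meaningful only for the curvature-prior and geodesic
  methods.
* The heel start-point convention assumes quasi-vertical feet; rotations
  large enough to move the global lowest point to another part of the
  outline break the parameterization correspondence (as they would for
  the clinical protocol this is designed for).
* The prior is a plain average of training outlines; no statistical
  shape model (modes of variation) is built, and strongly atypical
  anatomy (e.g. amputations) is outside the prior's validity.
* Timing is reported by the benchmark but never asserted: it is
  hardware-dependent.
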