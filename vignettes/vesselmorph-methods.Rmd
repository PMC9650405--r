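---
title: "Centerline morphometry of the great vessels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centerline morphometry of the great vessels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselmorph)
```

## The problem

An enlarged main pulmonary artery (PA) relative to the aorta (Ao) is a
well-established CT surrogate for pulmonary hypertension, and pulmonary
hypertension in turn predicts complications after anatomic lung resection.
The conventional measurement is manual: a radiologist places calipers on a
single axial slice at the level of the PA bifurcation. That protocol is
sensitive to slice selection and to the oblique course of both vessels
through the axial plane.

`vesselmorph` implements the 3D alternative: given binary segmentation
masks of the two vessels (with their anisotropic voxel spacing), it
extracts a centerline, measures cross-sectional diameters *perpendicular to
the vessel axis* over fixed anatomical windows, averages them, and forms
the PA/Ao diameter ratio. A ratio of at least 1 (inclusive) classifies the
PA as enlarged. The package also implements the downstream cohort stage
used to relate that classification to postoperative complications:
normality- and expected-count-gated group comparisons, Spearman correlation
between the 3D and 2D estimates, multivariable logistic regression with
Wald inference, and greedy 1:4 propensity-score matching with a 0.1-SD
logit caliper plus standardized-mean-difference balance diagnostics.

Because no imaging data ship with the package, every stage is exercised on
*phantoms* — tubular masks with analytically known geometry — and on a
*synthetic cohort* whose generative parameters are recovered by the
statistical stage. Both generators are first-class, tested package code.

## Measurement model

**Windows.** The aortic mean diameter is the arithmetic mean of
cross-sectional diameters sampled every 0.09 cm from 0.5 cm to 2.5 cm of
arc length from the heart-exit anchor (23 sections). The PA mean diameter
is sampled every 0.04 cm from 0.5 cm to 1.5 cm proximal to the branching
point, measured along the main trunk toward the pulmonic-valve side (26
sections). Window endpoints are inclusive at the start; the last sample
never exceeds the window end. The sampling intervals are configurable
(`measurement_config()`); the defaults follow the protocol's methods text.
(The source protocol's figure captions swap the two intervals relative to
its methods text; we follow the methods text and expose both as
parameters.)

**Diameter definition.** The protocol never defines "diameter" for a
non-circular section. We use the equivalent-area diameter
\(D = 2\sqrt{A/\pi}\) of the cross-section perpendicular to the local
centerline tangent. It is rotation-stable, reduces to the caliper value for
circular sections, and for an oblique cut of a cylinder gives
\(2r/\sqrt{\cos\theta}\), which the test suite verifies against a
numerically integrated ellipse. The plane is sampled on a 0.2 mm grid
(configurable) with trilinear interpolation of the mask and a 0.5
threshold, keeping only the in-plane connected component that contains the
centerline point — neighbouring structures cut by the same plane are
thereby excluded.

**Classification.** `enlarged = ratio >= 1` with an inclusive threshold,
matching the convention "PA/Ao ≥ 1" used in the clinical tables the
pipeline emulates; the threshold is a config field.

## Centerline extraction

The protocol only states that a centerline "was marked"; the algorithm is
the package's own design, chosen for determinism and a single tuning
parameter:

1. **Distance transform.** Exact anisotropic squared Euclidean distance to
   the background (Felzenszwalb–Huttenlocher separable scans), with the
   volume border treated as background.
2. **Anchored homotopic thinning.** Simple points — voxels whose deletion
   provably preserves digital topology in the (26, 6) adjacency pair — are
   deleted in increasing distance order, so survivors lie on the medial
   ridge. One voxel per *geodesic extremity* (limb tip) is protected: tip
   candidates are plateau clusters of local maxima of the weighted geodesic
   distance from each of the two mutually farthest foreground voxels, each
   ascended along the distance transform to the end of the local medial
   axis. Because deletion preserves connectivity, a one-voxel-wide medial
   path joining all anchors must survive. We do *not* use the common
   "protect voxels with one neighbour" endpoint rule: it freezes arbitrary
   tips mid-process (on cap-rim corners of oblique tubes, for instance) and
   fails to retain medial rods that digitize two voxels wide.
3. **Graph, pruning.** Skeleton voxels become an igraph with physical edge
   lengths; leaf branches shorter than `prune_factor` (default 2) times the
   local inscribed radius at their attachment node are removed. A leaf's
   length is credited with its endpoint's own radius, because the medial
   axis of a blunt tube genuinely terminates one radius short of the cap —
   without the credit, a legitimately retracted trunk looks like a spur.
4. **Main path.** The longest endpoint-to-endpoint geodesic; when the
   caller supplies an anchor hint (the heart-exit or trunk-origin end — the
   single place anatomical knowledge enters the pipeline), the path is the
   longest geodesic *starting at the endpoint nearest the hint*. On a
   branched PA skeleton the globally longest path runs daughter-to-daughter
   and would omit the anchored trunk, which contradicts the measurement's
   direction convention; tying the path to the anchored end resolves this.
5. **Smoothing, extension, resampling.** Five-point moving-average
   smoothing of the voxel-scale path suppresses staircase bias; ends are
   extended to the lumen surface along the osculating circle fitted to the
   terminal 20 mm (thinning retracts about one local radius inside blunt
   ends; a straight continuation drifts off-axis on curved vessels such as
   the aortic arch). A fitted curvature radius below 1.5 local radii is
   rejected as voxel wobble — a vessel cannot bend that sharply — and a
   modest curvature is only trusted when the circle fits the terminal
   stretch markedly better than a line. The path is resampled at 0.2 mm and
   tangents are central differences over ±3 mm, wide enough to suppress
   residual staircase tilt of the measurement planes.

The reconstructed end segments (within roughly one radius of a blunt cap)
are accurate along the axis but can deviate laterally by a few millimetres
at unlucky orientations; the measurement windows start 5 mm inboard of the
anchor, and rotation changes measured means by under 1.5 % in the test
suite.

**Bifurcation.** Adjacent branch voxels within two voxel diagonals are
merged into one junction cluster (fine grids split a single anatomical
junction). Clusters are scored by the length of the third-longest incident
subtree — a true trunk split carries three substantial limbs, whereas a
spur-created node scores only its spur. (The naive "sum of incident subtree
lengths" is constant across branch nodes of a tree and cannot
discriminate.) The winning junction is refined to sub-voxel precision as
the least-squares intersection point of the three limb axes, each fitted on
the outer half of its limb: near the junction the skeleton follows the
medial ridge of the merged daughter lobes (a "pitchfork"), not the daughter
axes, so the inner half is deliberately excluded.

## The 2D manual emulation

The manual protocol measures both vessels on the axial slice at the PA
bifurcation level. The exact caliper convention is unknowable, so
`measure_2d_axial()` uses the largest inscribed circle (twice the maximum
of the in-plane Euclidean distance transform) of the component nearest the
vessel's slice centroid — robust to the PA's elongated oblique footprint.
The slice is resampled at 0.25 mm in-plane before the distance transform;
whole-voxel quantization of the inscribed radius otherwise reorders
near-tied ratios. On straight vertical phantom pairs the 2D and 3D ratios
agree in rank exactly (Spearman 1.0 over 50 pairs in the test suite), since
both reduce to radius ratios there.

## Phantoms

`make_phantom()` voxelizes four analytic solids — straight cylinder,
circular-arc tube, trunk-plus-two-daughters bifurcation, and linearly
tapered cylinder — at arbitrary orientation and anisotropic spacing, with
the rule *foreground iff the voxel centre lies within the tube radius of
the analytic centerline*. Truth objects carry the exact centerline,
diameters, anchor, and (for bifurcations) branch point. A resolvability
floor `radius >= 3 * max(spacing)` keeps every tube several voxels wide.
Optional segmentation noise flips surface-adjacent voxels independently
with a given probability (no error model is published for the upstream
segmentation; independent surface flips are the minimal assumption).
Daughter tubes default to three trunk radii in length so that spur pruning,
which operates at the two-radius scale, cannot mistake them for artifacts.
`make_vessel_pair()` builds a matched aorta (vertical 90° arc, 40 mm arc
radius) and PA (30 mm trunk, 60° between daughters) sized so both
measurement windows fit, with truth ratio `pa_radius / ao_radius`.

What the phantoms do *not* emulate: real lumen shape variation, wall
irregularity, contact between vessels, motion or partial-volume artifacts,
and the error structure of any particular segmentation model. Passing
phantom tests therefore demonstrates geometric correctness of the
measurement chain, not clinical performance on real CT.

## The synthetic cohort

`simulate_cohort()` draws, per patient: enlargement with prevalence 0.0757,
tumor > 3 cm with prevalence 0.144, uniportal access with prevalence 0.292,
female sex with prevalence 0.632; age normal with mean 61.0 y (SD 9.7)
shifted by −6.6 y for enlarged patients; Charlson comorbidity index a
rounded, zero-clipped normal with mean 2.3 (SD 1.7) shifted by −0.6; and a
complication outcome
\(\mathrm{Bernoulli}\big(\mathrm{logit}^{-1}(\beta_0 + \ln(3.084)\,
\mathrm{enlarged} + \ln(3.173)\,\mathrm{tumor})\big)\)
with \(\beta_0 = 0\) by default. The shifts are derived from the reference
group means, so the propensity stage has genuine confounding to remove; the
outcome model carries exactly the two significant multivariable terms
(other covariates are generated but causally inert, which keeps parameter
recovery well-posed). Odds-ratio recovery is intercept-invariant, so the
zero intercept is a neutral default rather than a calibration to the
observed complication prevalence. A continuous `ratio3d` consistent with
the enlargement label (≥ 1 iff enlarged; sub-threshold values normal with
mean 0.8, SD 0.1, truncated below 1) and a noisy monotone `ratio2d` are
attached for correlation analyses. All draws are reproducible from a single
seed.

## Statistical stage

* **Categorical comparisons** use Pearson's chi-square without continuity
  correction unless any expected cell count is below 5, then Fisher's exact
  test. The uncorrected default matches the most common reporting
  convention for such tables; Yates correction is a flag. (One published
  worked example of the gate has a minimum expected count of exactly 5,
  which the stated "< 5" rule sends to chi-square.)
* **Continuous comparisons** are gated by Shapiro–Wilk at α = 0.05 on both
  samples: both normal → pooled-variance t test, otherwise Mann–Whitney U
  (exact for two small tie-free samples). Zero-variance samples are
  reported as untestable rather than forced through either branch.
* **Spearman correlation** is the Pearson correlation of mid-ranks.
* **Logistic regression** is a binomial GLM (IRLS, convergence tolerance
  1e-12) with Wald 95 % intervals \(\exp(\hat\beta \pm 1.96\,SE)\);
  non-convergence and quasi-separation are flagged. For a single binary
  covariate the fitted odds ratio equals the 2×2 cross-product ratio to
  1e-8, which the tests assert.
* **Propensity matching**: scores are the logit of the fitted probability
  of enlargement given age, comorbidity index and uniportal access. Cases
  are processed in descending score order; each takes up to 4 unused
  controls within the caliper (0.1 × SD of the pooled logit scores),
  nearest first, ties broken by smallest id, without replacement; cases
  with at least one control are retained (variable 1..4 matching — the
  order, replacement and retention rules are unstated in the source
  protocol and were fixed for determinism, consistent with its incomplete
  1:4 match). Balance is reported as
  \(\mathrm{SMD} = (\bar x_1 - \bar x_0)/\sqrt{(s_1^2 + s_0^2)/2}\)
  before and after matching.
* **Summary tables** render `n (%)` with half-up rounding (so 20/29 →
  69.0 %) and `mean ± SD`, with p values from the gates above.

## Numerical choices and degenerate inputs

* All geometry is computed in physical millimetres; voxel (i,j,k)
  (0-based) sits at `origin + (i·sx, j·sy, k·sz)`. Masks are used in stored
  axis order; no anatomical reorientation is attempted (the anchor hint
  carries the anatomical information instead).
* Float masks are re-binarized at 0.5 everywhere (file input, trilinear
  plane sampling, extension stopping).
* A sphere thins to a degenerate skeleton; paths shorter than 1 mm are
  rejected as "no admissible path". Masks with several components must be
  reduced with `largest_component()` first (a warning reports dropped
  components). A caliper of zero produces an (legal) empty match.
* Problem sizes in the test suite — phantom radii 7–18 mm, lengths
  35–60 mm, spacings spanning 0.38–0.89 mm in-plane and 0.6–1.25 mm between
  slices, cohorts of 4·10³–2·10⁵ — were chosen to cover the stated scanner
  ranges while keeping the full suite around a minute and a half of
  compute.

## Known limitations

* Vessels with more than one branching generation are not labelled; only
  the first split of the supplied mask is detected.
* The centerline end reconstruction assumes locally circular-arc geometry;
  strongly kinked or high-curvature vessels (curvature radius below ~1.5
  tube radii) fall back to straight continuation.
* Steep tapers (radius gradient ≳ 0.2 mm/mm) shift the anchored end
  inward by up to a few mm before the extension compensates; mean-diameter
  error stays within ±1 mm in the tests but grows with taper slope.
* The cohort generator reproduces marginals, two confounder shifts and a
  two-term outcome model — not the full joint distribution of a real
  surgical cohort; printed p values of the source tables are therefore not
  reproduction targets.

## A worked example

```{r example, eval = FALSE}
pair <- make_vessel_pair(ao_radius_mm = 17.4, pa_trunk_radius_mm = 13.9)
res <- measure_vessel_pair(pair$aorta$mask, pair$pa$mask,
                           pair$aorta$truth$anchor_mm,
                           pair$pa$truth$anchor_mm,
                           measurement_config(plane_halfwidth_mm = 30))
res$ratio
#> <ratio_result> PA/Ao = 0.798 (not enlarged at threshold 1)

co <- simulate_cohort(default_cohort_params(n = 200000))
tidy(fit_logistic(co))
```
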