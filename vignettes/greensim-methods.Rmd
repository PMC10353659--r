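---
title: "Methods: simulating canopy imagery and evaluating green-fraction segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating canopy imagery and evaluating green-fraction segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greensim)
```

## The problem

The green fraction (GF) of a crop canopy image — green-vegetation
pixels over total pixels — tracks the canopy's light interception and
is a routine phenotyping trait for rice and wheat. Estimating it well
reduces to a two-class semantic segmentation problem whose evaluation
requires pixel-accurate reference masks, which are expensive and
error-prone to annotate by hand, especially along leaf edges.
`greensim` provides the alternative: a procedural canopy simulator
whose masks are exact by construction, plus the complete measurement
stack (pixel metrics, domain-gap distance, GF regression, error-class
density analysis) needed to study segmenters on such data.

The simulator is a deliberately parametric stand-in for
functional–structural plant models: it reproduces the *controls* that
matter for segmentation imagery — arrangement (density, row spacing),
architecture (tillers, leaves, length, width, inclination, curvature,
height), colour, background and illumination — without claiming
physiological fidelity. That trade is intentional: segmentation ground
truth needs geometric and radiometric diversity, not carbon budgets.

## Canopy model

### Parameter space and sampling

Each crop has a documented ~12-dimensional parameter space
(`parameter_space()`), with bounds chosen once to emulate ground-based
canopy photography of transplanted paddy rice (sparse hills, long
drooping blades, flat water background) and drilled wheat (dense rows,
shorter more erect blades, soil background):

| dimension | units | rice | wheat |
|---|---|---|---|
| plant_density | plants·m⁻² | 14–33 | 120–320 |
| row_spacing | m | 0.20–0.33 | 0.12–0.20 |
| plant_jitter | m | 0–0.04 | 0–0.02 |
| tillers_per_plant | – | 3–12 | 1–4 |
| leaves_per_tiller | – | 3–6 | 2–5 |
| leaf_length | m | 0.25–0.60 | 0.10–0.30 |
| leaf_max_width | m | 0.007–0.016 | 0.004–0.012 |
| leaf_inclination | ° above horizontal | 35–80 | 30–75 |
| leaf_curvature | rad (total droop) | 0.3–2.8 | 0.2–2.0 |
| plant_height | m | 0.35–1.00 | 0.12–0.60 |
| green_hue, green_sat | – | 0–1 | 0–1 |

Spaces are user-extensible through a YAML/JSON config
(`read_parameter_space()`): the defaults are a starting point, not a
claim of completeness.

Points are drawn by Latin-hypercube sampling (`lhs::randomLHS`), which
guarantees exactly one point per equal-probability stratum per
dimension — with a few hundred draws this covers a ~12-D box far more
evenly than i.i.d. sampling. Growth stages are deliberately *not* a
hypercube dimension: each structural draw is replicated across all
`n_stages` stages (`with_growth_stages()`), emulating a design in which
one canopy is observed repeatedly through time. Stage `g` of `G` scales
organ counts (`round(count · g/G)`, floored at 1) and organ sizes
(linearly from 45% to 100%), so scene leaf area is non-decreasing in
stage by construction. Whether the stages should be parameter presets
or model time points was genuinely open; replication of a single draw
across stages was chosen because it preserves the within-genotype
correlation a time series would have.

### Geometry

Plants sit on a regular row grid: rows `row_spacing` apart, within-row
positions spaced so the realized count equals
`round(plant_density × plot area)`, plus seeded uniform jitter. A leaf
blade (`leaf_surface()`) is a triangulated strip whose midrib is a
planar arc: the tangent leaves the base at `leaf_inclination` above
horizontal and decreases linearly with arc length, sweeping
`leaf_curvature` radians in total — zero curvature is a straight blade,
large curvature droops the tip below its base. The arc has a closed
form (integrals of `cos/sin(θ₀ − c·u)`), which gives exact straight
limits and lets tests check the droop against an independent numerical
integration of the tangent-angle law. The width profile rises linearly
to `leaf_max_width` at 30% of blade length and tapers to zero at the
tip, so the one-sided blade area is analytically `0.5·width·length`;
the mesh (≥ 8 segments, more under strong curvature) stays within 5% of
it. Tillers fan around the plant centre and leaves take golden-angle
headings with seeded jitter — enough angular decorrelation that no row
direction is privileged in the mask statistics.

Everything is deterministic given the scene seed, and scene building
never touches the caller's RNG stream.

## Rendering

A pinhole camera (default: 1.5 m above the background plane, 85°
horizontal field of view, 45° from nadir, 1,024 × 1,024 pixels — the
capture regime the default spaces were tuned for) projects the scene;
rasterization is a deterministic z-buffer, not a ray tracer. The
85° field of view is fixed as *horizontal*; the source regime did not
state which axis it referred to.

Two passes consume the same projected geometry:

* **Label pass.** Since every primitive is green vegetation, a pixel's
  label needs only coverage: the pixel is green when the majority of a
  4 × 4 subpixel grid (≥ 9 of 16; ties to background) is covered by any
  primitive. No depth test is needed, occlusion cannot change the
  class, and the mask is exactly invariant to illumination — a property
  the tests assert bit-for-bit.
* **Shading pass.** Per pixel-centre z-buffer with two-sided Lambertian
  shading `E = d + (1 − d)·|n·s|·lit`, where `d` is the diffuse
  fraction (< 0.5 sunny, ≥ 0.8 cloudy), `s` the sun direction, and
  `lit` a hard-shadow term from an orthographic 1,024² sun-view depth
  map (sunny only). Wheat sits on mottled brown soil (two octaves of
  seeded value noise); rice sits on flat light-gray water with a
  specular sun glint. Output is 8-bit with clamp tone mapping.

The renderer trades realism for exact labels and desk-scale speed:
no global illumination, no lens distortion or sensor noise, no leaf
texture, no senescent organs. Those gaps are the *point* of the
domain-gap tooling — simulated imagery is expected to sit at a
measurable distance from field imagery, and `domain_gap()` quantifies
it rather than hiding it.

## Dataset conventions

Tiling centre-crops to the largest multiple of the tile size then cuts
a non-overlapping grid, so a 1,024² render yields four 512² tiles that
reassemble the source exactly, and the mean tile GF equals the source
GF identically (powers-of-two pixel counts make this exact in floating
point). Manifests assign whole *source images* to train/val/test — a
tile of one image never appears in two splits, preventing spatial
leakage the split fractions would otherwise hide. Mask files are PNG
0/255; any nonzero value is read as green, with a warning. The
unpaired `trainA/`/`trainB/` export exists so external style-transfer
tools can consume the data; running such tools is out of scope.

## Segmentation baseline

The bundled segmenter is the classical excess-green + Otsu pipeline:
`ExG = 2G − R − B` on raw digital numbers (range −510…510), thresholded
at the maximizer of between-class variance over the 255 interior bin
edges of the data range, with ties broken toward the smallest
threshold. Class statistics use the raw values rather than bin
midpoints, so the result coincides exactly with an exhaustive search
over the same candidates (a test does exactly that). On a bimodal
distribution with an empty gap every threshold inside the gap ties, and
the smallest-tie rule lands on the gap's lower edge — the same behavior
as reference implementations. A constant-colour image has no contrast
and falls back to an all-background mask with a warning. ExG scales
linearly under clip-free brightness scaling, so the baseline is
invariant to it up to threshold re-quantization.

External models enter through an executable adapter contract
(`adapter <rgb.png> <out.png>`); malformed outputs are rejected per
image and the run continues.

## Evaluation

Confusion proportions use green vegetation as the positive class and
sum to 1 over pixels, making them poolable across images by
pixel-weighted averaging — pooling equals evaluating the concatenated
images, which a property test asserts. `Accuracy = TP + TN` and
`F1 = 2·TP/(2·TP + FP + FN)` (defined 0 when the denominator
vanishes). GF agreement uses
`R² = 1 − Σ(fᵢ−yᵢ)²/Σ(yᵢ−ȳ)²` — the standard coefficient of
determination (benchmark reports sometimes typeset this formula
ambiguously; the standard form is adopted deliberately) — and RMSE;
R² is reported `NA` for a constant reference.

The Euclidean image distance is normalized per digital number and per
pixel count, `sqrt(mean(((x−y)/255)²))`, so it is bounded in [0, 1]
(black vs white = 1) and comparable across resolutions; the raw
sum-of-squares form grows with image size. Cross-set aggregation is a
seeded random pairing; the pairing is oriented canonically by set size
(and evaluated in both directions when sizes are equal), which makes
`domain_gap(A, B)` and `domain_gap(B, A)` identical under the same
seed. The standard error over sampled pairs is reported alongside the
mean.

## Uncertainty analysis

Segmentation errors on canopy imagery cluster by brightness (shadowed
vegetation) and greenness (senescent material). The module therefore
computes two per-pixel features — CIELAB L\* via the standard
sRGB/D65 piecewise transfer curve (a hand-rolled conversion because the
conversion standard matters: L\*(sRGB red) must be 53.24, and tests
check it against an independent colour library), and ExG on raw DN —
and estimates their distribution within each error class of a
prediction/truth pair. Densities are Gaussian-kernel KDEs with
Scott's-rule bandwidth on a 256-point grid spanning
`[min − 3bw, max + 3bw]`; pixels are pooled across images (per-image
pooling first was the open alternative; global pooling was chosen and
provenance tagged so per-image analysis remains possible). An absent
class yields an explicit absent result rather than an error. Error
overlays use a bijective four-colour palette, so decoding an overlay
recovers the class map exactly. On sunny shadowed fixtures the mean
L\* of true-positive pixels exceeds that of true-negative pixels —
lit vegetation is brighter than shadowed background — which the test
suite asserts on seeded scenes.

## Numerical and design notes

* Seeds: one global seed fans out to per-stage seeds through a fixed
  affine-modular map (`stage_seed()`, kept below 2³¹), so stages rerun
  independently and package functions restore the caller's RNG state.
* Mask edges: the 4 × 4 majority rule with ties to background is a
  convention; reference label rules at anti-aliased edges are
  generally unstated, and any fixed convention is consistent across
  image and mask here.
* Degenerate inputs: zero plant density is a legal empty scene;
  empty masks error in `green_fraction()`; constant references make
  R² `NA`; constant-colour images warn and segment to background.
* Fidelity: `detail` (leaf segments) and the `low` fidelity preset
  (8 segments, no shadow pass) trade geometric smoothness for batch
  throughput without touching the study conditions (sample counts,
  camera, resolution).

## Problem sizes used by the tests and acceptance script

The package's own evaluation uses: the full 500-point × 4-stage,
1,024² simulate-and-tile run (counts and GF accumulated streaming);
50 clean diffuse-light samples at 1,024² for the baseline's pooled F1;
20 seeded 256² scenes for the conservation invariants; 10³ random
16 × 16 mask pairs for the confusion oracle; and 10⁴-sample KDE checks
against the analytic normal density. These sizes were chosen so the
entire suite runs on one desktop CPU in minutes while still exercising
the full-scale dataset geometry end to end.

## Limitations

Simulated canopies lack senescent organs, leaf texture, specular leaf
reflection, wind blur and sensor noise; the background models are
caricatures (two-octave soil mottling, uniform water with one glint).
Passing the included tests therefore demonstrates correctness of the
geometry, labels and metrics — not that a segmenter trained or tuned on
`greensim` output transfers to field imagery. The domain-gap distance
is the honest bridge: treat simulated data as a controlled testbed
whose distance to your field data you measure, not assume away.
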