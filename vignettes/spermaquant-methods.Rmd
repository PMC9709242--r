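---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the measurement procedures
it implements, the tunable parameters that matter, what the synthetic
generator does and does not emulate, and the design decisions taken where
the underlying assay descriptions leave choices open.

## Conventions

All rasters are `(row, col)` matrices with the origin at the top-left,
1-based as usual in R. Intensities are never rescaled on read: an 8-bit
TIFF yields values in 0–255 and all thresholds operate on native values.
Channel identity (red/green/brightfield) is always supplied by the caller
or a configuration file, never guessed from file metadata. Every assay
driver accepts a `run_config()` whose effective values — including all
defaults — are written to a YAML run log, so any run is reproducible from
its log plus its seed.

## Shape morphometry

Per-object metrics follow particle-analysis conventions:

* **Perimeter** uses the 4-direction Crofton estimator: each 2×2 pixel
  configuration is coded and weighted by the integral-geometry look-up
  table. This estimator converges to the continuous perimeter on smooth
  shapes; circularity (4·π·area/perimeter², capped at 1.0 for
  rasterization artifacts) is calibrated against it, and a rasterized
  disc of radius 20 px scores ≈ 0.97. The choice is documented because
  circularity is sensitive to the perimeter estimator: a chain-code
  estimator would systematically depress circularity by ~5%.
* **Solidity** is pixel area divided by the pixel count of the rasterized
  convex hull (pixel centers inside the hull polygon of the centers).
  Under this convention a rasterized disc or rectangle is exactly convex
  (solidity 1), so deviations measure true concavities such as a
  pseudopod notch.
* **Aspect ratio** comes from the central second moments with a 1/12
  per-pixel variance term (the variance of a unit pixel), which keeps
  one-pixel-wide shapes finite and makes an n×m rectangle score exactly
  n/m.
* **Feret's diameter** is the maximum caliper distance, computed by
  rotating calipers over the convex hull of the pixel corners; tests
  compare it against an all-pairs brute force.
* Two auxiliary quantities drive classification: the **inscribed body
  radius** (distance-transform maximum) and the **protrusion extension**,
  `(feret − 2·r_body) / (2·r_body)` — how far the longest axis exceeds the
  inscribed-body diameter, in units of that diameter. The extension is
  nearly size-invariant and separates round cells from protrusion-bearing
  ones far more reliably than circularity alone.

## Activation classification

The four-class call (spermatid / small protrusion / spermatozoon /
abnormal) is automated as a deterministic decision tree; the original
assays classified manually, so the tree and its calibration against
synthetic truth are this package's explicit stand-in, and every threshold
is user-overridable via `activation_rules()`:

* extension < 0.20 → round cell: *spermatid*, unless its area exceeds
  1.22× the reference round-cell area (→ *abnormal*, swollen morph) or its
  internal intensity coefficient of variation exceeds 0.25 (→ *abnormal*,
  vacuolated morph);
* 0.20 ≤ extension < 0.50 → *small protrusion*;
* extension ≥ 0.50 → *spermatozoon*, unless the protrusion is thinner
  than 4 px (→ *abnormal*, spiked morph). Protrusion width is twice the
  inscribed radius of the largest appendage left after morphologically
  opening away the cell body.

The reference area defaults to the median area of the round cells in the
same field, so the swollen flag adapts to each strain's typical spermatid
size. Thresholds were calibrated once so that noiseless synthetic fields
are recovered with ≤ 5% per-class confusion; on the default noisy
presets, residual confusion is dominated by watershed-split touching
cells.

## Segmentation

Two masking procedures are provided. The JC-1 ("generous") pipeline runs,
in fixed order: Otsu threshold scaled by `generous_factor` (default 0.6 —
"generous" is interpreted as a deliberate under-threshold so whole dim
spermatids are captured), size filter (default 50 px), fill holes,
`closing_rounds` (default 2) of dilate/erode with a 3×3 square element,
then a distance-transform watershed. The watershed merges basins
shallower than `watershed_tolerance` (default 3 distance units), which
splits touching ~9 px-radius spermatids while leaving pseudopods attached
to their cell body. Per-step foreground pixel counts are logged on the
result.

The redox pipeline runs: Triangle threshold (256-bin histogram; maximal
perpendicular distance to the peak-to-tail chord, searched strictly
between the endpoints; a constant image raises "no threshold found"),
fill holes, watershed, size filter, replacement of each object by its
moment-fitted, area-preserving ellipse, and a second watershed to
re-separate merged ellipses.

## Mitochondrial pipelines

Preprocessing is rolling-ball-style background subtraction — a separable
min-then-max (grayscale opening) filter with window half-size 25 px,
subtracted and clipped at zero — followed by CLAHE (4×4 tiles, clip
limit 2). CLAHE block size and clip, and the background window, are
documented guesses exposed in `run_config()`; CLAHE is nonlinear, so no
idempotence is claimed.

Detection applies a Gaussian-smoothed (σ = 1 px) 3×3 Laplacian. Bright
blobs make the Laplacian negative, so the response is the *negated*
filter output *clipped at zero*: the clip pins the background mode of the
response histogram at exactly zero, which keeps the IsoData (iterative
intermeans, 256-bin) fixed point between background and blob response
instead of inside the noise — without it, the intermeans threshold on a
signed response lands near zero and the mask percolates. Two further
robustness rules are documented: a threshold that would mark more than
20% of the field as foreground indicates a signal-free (noise-only)
response and yields zero detections; and components below 7 px are
removed — the debris cutoff is exactly 7 px by default, matching the
published rule.

Counting collapses each detected blob to representative points via
find-maxima with a prominence tolerance (default 10% of the object's
dynamic range): a maximum merges into a higher one when the connected
region above `value − tolerance` containing it also contains that higher
peak, so plateaus and shallow secondary bumps give one point while
genuinely separate peaks (e.g. two mitochondria merged into one component)
give two. Counts are integer point counts per cell; points landing on a
cell boundary are assigned by majority overlap of their source blob, and
unassignable points are reported as orphans, preserving the conservation
law (Σ per-cell counts + orphans = total points).

Per-spermatid membrane potential is the ratio of total red to total green
fluorescence under the cell mask; a zero green total flags the ratio as
undefined (`NA`), never infinity. By default totals are raw (no per-cell
background correction), with an optional flag, since the original
measurement does not state a correction.

## Reporters and motility

Whole-animal reporter quantification is `adjusted = animal mean − mean of
all background readings`, then `relative = adjusted / control-group mean`
(so the control group's mean relative intensity is 1 by construction;
normalisation is idempotent and invariant to a common intensity scale).
Whether normalisation should pool replicates or be per-replicate is not
specified in the source assays; the package normalises against whatever
control IDs the caller passes, which makes either choice explicit.

The uterus axis is the straight vulva→spermatheca segment (no curved
path is defined by the assay), divided into thirds with half-open
boundaries [0, 1/3), [1/3, 2/3), [2/3, 1] — an axis fraction of exactly
1/3 falls in zone 2. Sperm projecting outside [0, 1] are clamped with a
warning. Track speed is total path length over elapsed time (the tracking
convention); net-displacement "progressive speed" is returned alongside.
Per-arm velocity averages zone-2 tracks and reports arms without
qualifying tracks as missing, never zero. Tracking itself (spot detection
and linking) is out of scope; the package ingests track tables (CSV with
`track`, `frame`/`t`, `x`, `y`; default frame interval 30 s).

## The synthetic generator

The generator renders ground-truthed scenes for every assay. Design
principles:

* **Stratified class counts.** Class counts are exact largest-remainder
  rounds of `mixture × n`, not binomial draws, so fraction-recovery tests
  see classifier error only. Per-object geometry remains random.
* **Determinism.** All draws flow from one seeded stream; the caller's
  RNG state is saved and restored; identical config + seed gives
  identical output.
* **Truth/render consistency.** With noise and gradient off, measuring a
  truth mask on the render recovers the configured amplitude exactly, and
  the JC-1 truth red/green totals are the rendered signal under each cell
  mask, so the ratio estimator is exactly unbiased on noiseless renders.

Morphology presets: spermatids are discs (radius 9 ± 0.35 px — an
arbitrary but plausible pixel scale, since no physical calibration is
published for these images; the radius spread is kept tight, consistent
with the reported absence of a size phenotype, so that the 1.5×-area
swollen morph is a genuine outlier). Pseudopods are tapered protrusions
0.6–0.9 cell diameters long; small protrusions 0.2–0.3 diameters;
abnormal cells render one of three sub-morphs — a 2 px-wide spike, a
1.5×-area swollen disc, or an internal dark vacuole. 5% of cells are
placed in touching pairs to exercise the watershed. Noise is Gaussian
read noise (σ = 2) with optional Poisson shot noise, over a background
with an optional linear gradient.

JC-1 fields render spermatids with a smooth dome of diffuse green
monomer signal (a hard-edged disc would put a spurious Laplacian edge
ring into the blob detector; real out-of-focus body fluorescence falls
off smoothly) plus anisotropic Gaussian mitochondria. The wild-type
preset draws aspect ratios around 1.2; the mutant preset draws them
around 3 with fewer, larger mitochondria (hyperfusion), a 30%
depolarised (green-dominant, red-invisible) fraction assigned as an exact
stratified count, and a wider mean-preserving log-normal per-cell
membrane-potential factor. The mutant red amplitude (98 vs 120) is set so
the *expected measured* red:green ratio matches the wild-type preset:
the published contrast is greater dispersion at an unchanged mean, and
the compensation makes that contrast hold by construction rather than by
accident of geometry.

Reporter scenes are worm-shaped tubes of known amplitude over a known
background; uterus scenes draw initial positions from a Beta distribution
over the axis (wild-type skewed to the spermatheca, mutant preset to the
vulva) and move each sperm with a constant per-frame step length and
random heading, so each track's true path speed equals its drawn speed
exactly.

What the generator does **not** emulate: optics (no PSF, no diffraction),
3-D structure (single plane only), autofluorescence, debris, drift, or
photobleaching. Passing tests therefore demonstrate that the pipelines
recover known quantities under controlled geometry and noise — they do
not certify performance on real micrographs, where segmentation and
detection parameters may need retuning.

## Numerical choices and degenerate inputs

* Histogram thresholds use 256 bins over the data range; degenerate
  (constant) histograms raise an error (Triangle, Otsu) or return `NA`
  treated as "no objects" (IsoData in detection).
* Connected components default to 8-connectivity (4 available);
  8-connectivity is derived from the 4-connected labeling by union-find
  merging of diagonally adjacent components.
* An empty segmentation result is a valid 0-object label map, never an
  error; empty cells in counting yield 0; arms without qualifying tracks
  yield `NA`.
* Single-pixel objects measure with finite perimeter (4·√area
  convention), so circularity never divides by zero.
* SEM uses the sample (n−1) standard deviation; single-observation groups
  get `NA` SEM with a degeneracy flag.
* Float TIFFs are written only on [0, 1] (the storage convention of the
  underlying library); out-of-range float data raises an error rather
  than being silently rescaled. Integer depths round-trip losslessly.

## Problem sizes

The bundled presets use 200 cells on a 900×900 px field for activation
assays (matching the >180-sperm populations the assays score) and 24
cells on a 512×512 px field for JC-1 assays (~100–190 mitochondria per
field). Statistical tests over synthetic fields pool two replicate
fields per condition, emulating the multi-male pooling of the real
assays; these sizes give stable population statistics while keeping a
full test run to a few minutes.

## Known limitations

* The activation classifier is calibrated on the generator's geometry;
  the published assays classified manually, and no claim is made that the
  default thresholds match any individual scorer.
* The "generous" threshold factor, cell-size cutoff, CLAHE parameters and
  Laplacian scale are documented defaults for quantities the original
  macros do not state.
* The uterine axis is straight; strongly curved uteri would need the
  polyline option.
* Detection requires blobs a few pixels across; the documented SNR floor
  is roughly amplitude ≥ 10× the read-noise σ after preprocessing, below
  which the IsoData threshold degrades.
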