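---
title: "frostmap: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{frostmap: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frostmap)
```

`frostmap` classifies nadir colour photographs of cereal canopies into frost
damage classes without any training data, and quantifies how trustworthy the
resulting thematic map is. This vignette explains the model behind each
stage, the tunable parameters and their defaults, what the synthetic scene
generator does and does not emulate, and the design decisions taken where
the method left genuine choices open.

## 1. Colour model

Outdoor crop photographs suffer strong illumination variability; the
classifier therefore works in CIE L\*a\*b\*, which separates perceived
lightness (L\*, 0–100) from two opponent colour axes (a\*: green–red; b\*:
blue–yellow, roughly ±110 for 8-bit input). The conversion chain is fixed:
RGB (normalized by the coding maximum, 255 for 8-bit) is mapped through the
classic CIE primaries matrix to tristimulus X, Y, Z, and then compressed by
the cube-root function f(t) = t^(1/3) for t > 0.008856 and
f(t) = 7.787·t + 16/116 below, the linear segment matching the cube root in
value and slope at the breakpoint.

Two conventions needed fixing:

* **Lightness low branch.** One circulating variant of the formula applies
  903.3·(Y/Yn)^(1/3) below the breakpoint, which is discontinuous with the
  upper branch (it jumps to ≈ 187 at the breakpoint) and inconsistent with
  f(t). The default is the standard matched linear segment 903.3·(Y/Yn)
  (note 116·(7.787·t + 16/116) − 16 = 903.3·t); the variant is available as
  `lowBranch = "as_printed"` for comparison, since published results based
  on it cannot be disambiguated after the fact.
* **White point.** No reference white is mandated by the method; the
  default is the equal-energy white (1.000, 1.001, 1.000) — the image of
  RGB = (1, 1, 1) under the matrix — so that pure white maps exactly to
  L\* = 100, a\* = b\* = 0. It is configurable for calibrated cameras.

## 2. Histogram quantization

The thresholders operate on discrete histograms. L\* is binned to integer
levels 0–100 and a\*, b\* to 0–220 (one level per unit over [−110, 110]).
Bin counts are configurable (`nLevels`); the defaults keep one bin per
Lab unit, which is comfortably finer than the class structure of vegetation
imagery while keeping the exhaustive threshold scans trivial.

## 3. Fused automatic thresholding

Three classical bi-level thresholders run on every channel histogram:

* **Isodata**: iterate t ← ⌊(μ₁(t) + μ₂(t))/2⌋ from the integer part of the
  histogram mean until the threshold stops moving. The update is monotone
  on a finite level set, so it always converges; the result is a fixpoint.
* **Otsu**: maximize the between-class variance
  σ²_B(t) = [μ_T·w(t) − μ(t)]² / (w(t)(1 − w(t))) over all t with
  0 < w(t) < 1.
* **Fuzzy entropy**: memberships μ_F(i) = 1/(1 + |i − μ_side(t)|) feed the
  Shannon function S(μ) = −μ ln μ − (1−μ) ln(1−μ); the fuzziness
  E(t) = Σ S(μ_F(i)) h(i) / (N ln 2) ∈ [0, 1] is minimized. The membership
  is used exactly in this unnormalized distance form (some formulations
  divide the distance by a dynamic-range constant; results differ only by a
  monotone reparameterization of the membership scale).

The operating threshold is the floored average ⌊(t_I + t_O + t_F)/3⌋, which
smooths the extremes of the three. Ties in the argmax/argmin scans break to
the smallest level, and a pixel with value v belongs to the lower region
iff v ≤ t; both conventions are arbitrary but fixed for determinism.
Degenerate histograms (mass at fewer than two levels) are rejected with a
typed error.

**Successive thresholding.** When M thresholds per channel are needed, the
first comes from the full histogram and each further one from
re-thresholding the sub-histogram of the partition with the largest
population-weighted within-partition variance. The method itself only says
that further partitions are produced; this selection rule mirrors the
variance logic of the merging stage, and is deterministic. Partitions too
small or degenerate to split are skipped; when no partition can be split, a
typed `frostmap_split_error` is raised.

## 4. Coding, labelling, merging

Pixel codes per channel count the thresholds strictly below the value;
codes combine into labels p = n²·c_L + n·c_a + c_b with n = M + 1, a
bijection onto 0..n³−1 (8 classes for M = 1). Per class the spectral mean
μ_k and within-class spread σ_k are computed, and per pair the separation
σ_kh = ‖μ_k − μ_h‖²/3. Any pair with σ_k ≥ σ_kh or σ_h ≥ σ_kh is
overlapping; the pair with the largest violation max(σ_k, σ_h) − σ_kh is
merged first, the fused class keeping the smaller-variance member's label,
and statistics are recomputed after every merge until all pairs are
separated. If no merge fired at all, the partition is considered too coarse
and the whole clustering restarts with M + 1 thresholds on all three
channels simultaneously (per-channel asymmetric growth was rejected for
determinism).

Two design points deserve emphasis:

* **Variance units.** σ_k is defined as a *mean Euclidean distance* scaled
  by 1/d, while σ_kh is a *mean squared distance*. The two are compared
  directly, so the merge criterion is not scale-invariant: multiplying all
  spectral values by c multiplies σ_k by c but σ_kh by c². The default
  (`varianceForm = "as_printed"`) keeps this behaviour for fidelity; the
  dimensionally consistent alternative (`"squared"`, σ_k as mean squared
  deviation) is one switch away. In practice, on spectrally well-separated
  scenes *neither* form triggers spontaneous merges, so the restart rule
  ("increase M until a fusion occurs") would not terminate; `classifyImage`
  therefore caps the escalation at `maxThresholds` (default 4) and
  proceeds.
* **Forced fusion.** A damage survey wants exactly K = 4 classes
  (GO/DO/HD/SG). When more remain, the criterion is relaxed: the pair with
  the largest max(σ_k, σ_h) − σ_kh (the highest degree of overlap) is
  merged repeatedly until K remain. Asking for more classes than remain is
  an error — the method only merges. A configurable population floor
  (`minPopulation`, default 1 = keep everything) can first absorb tiny
  classes into their nearest neighbour by σ_kh, since the method says
  nothing about near-empty classes.

**Semantic roles.** Mapping the four surviving clusters onto GO/DO/HD/SG is
expert judgement in the field; the package ships a deterministic
convenience heuristic — SG has the lowest mean L\*, GO the most negative
mean a\* of the rest, DO the most positive mean b\* of the remaining two,
HD is the remainder — and emits it alongside the statistics so a user can
override it. Ties resolve by label order with a warning.

**Damage report.** Per-role fractions and areas, plus the usable area
area(GO) + w·area(HD). Field experts put the usable share of half-dried
plants at 40–60%, hence the default w = 0.5.

## 5. Accuracy assessment

Sample units are homogeneous polygons rather than single pixels, so that
positional error does not masquerade as thematic error. The number of units
follows the multinomial design n_s = ⌈B·Π(1−Π)/b²⌉, with b the desired
accuracy (default 0.05), B the chi-square quantile χ²(1, 1 − b/k), and Π
the image fraction of the class of interest (worst case over the supplied
fractions unless a class is named). B may be supplied explicitly to
reproduce published tables; note that with the worked coefficient
B = 6.36640, Π = 0.16, b = 0.05 the formula gives ⌈342.27⌉ = 343 — the
package reports what the formula yields. Units are apportioned to classes
by largest remainder, which always sums exactly to n_s.

Scoring a polygon against the classified map uses its overlap f with the
reference class: f = 1 is absolutely correct (diagonal); 0.5 ≤ f < 1 is
acceptable, attributed to the row of the majority *non-reference*
classified role (the worked example in the source material is consistent
with this attribution, though no formal rule is stated); f < 0.5 is an
error, attributed to the majority classified role (or the leading wrong
class when the reference is still the plurality). Counts are pixel-weighted
by default — survey-scale matrices with totals in the tens of thousands
imply area weighting — and unit weighting is available
(`weighting = "unit"`).

From the fuzzy matrix: overall accuracy (diagonal over grand total;
fuzzy mode adds the acceptable counts), classifier's/user's accuracy per
class (row basis; complement = commission error) and expert's/producer's
accuracy (column basis; complement = omission error). Accuracies are
reported as exact ratios plus nearest-integer percents (half rounds up),
matching survey reporting practice. Collapsing each off-diagonal pair by
addition reproduces the deterministic matrix exactly, and fuzzy accuracy
can never be below deterministic accuracy — both identities are enforced by
tests.

`exampleSurveyMatrix()` ships a synthetic 4-class matrix reconstructed to
be consistent with a published survey's marginal totals and worked cells;
the two off-diagonal cells those totals do not pin down were fixed by
setting the DO-row confusion with GO to zero. Every accuracy measure
derived from it reproduces the published-style values (92% / 96% overall,
etc.).

## 6. Synthetic scenes

The generator emulates the *class-mixture statistics* of four-texture field
photographs, nothing more: each class receives a smooth random field
(two-scale bilinear upsampling of coarse Gaussian noise, characteristic
blob size `patchScale`, default 32 px); every pixel takes the class with
the largest shifted field, the shifts calibrated so realized area fractions
hit their targets within 2% (256×256 and up); colours are the class's mean
RGB under a linear illumination ramp across columns (default ±5%) plus
additive Gaussian noise, clipped to [0, 255]. The default palette mirrors
the four damage textures — green (50, 110, 40), yellow (180, 170, 80),
olive (120, 130, 60), dark (25, 30, 25) at fractions 0.35/0.25/0.2/0.2 —
and the default noise of 5 digital numbers reflects a realistic consumer
sensor at field exposure. Reference polygons are axis-aligned squares
placed fully inside single-role regions with a 2-px purity margin.

What the generator does **not** emulate: leaf morphology and specular
structure, mixed boundary pixels, spatially correlated noise, and the
heavy-tailed radiometry of real sensors. Passing recovery tests on these
scenes therefore demonstrates that the pipeline's spectral logic is
correct, not that real-field accuracy will match.

## 7. Noise regimes and a known limitation

The recovery tests construct scenes whose class-mean separation is at least
10× the class noise spread *in the classifier's working space* (Lab). This
distinction matters: the cube-root compression has unbounded slope near
black, so the dark (SG) class's b\* noise is amplified ≈ 5.6× relative to
its RGB noise. At an RGB noise sd of 5 DN the default palette is 15×
separated in RGB but only ≈ 2× in Lab for the worst class — and in that
regime the merge machinery has a failure mode: thresholds that cut through
the dark class's wide Lab mode create fragments whose mutual separation
(σ_kh ≈ 62) exceeds the genuine DO–HD class separation (≈ 46), so the
forced fusion re-merges DO with HD before reuniting the fragments, capping
pixel agreement near 80%. Neither the `"squared"` variance form nor a
population floor changes that ordering — it is a property of comparing
spread to separation without population weighting. At Lab-space ratios ≥
10 (RGB noise sd ≈ 0.8 for the default palette; the recovery tests verify
the measured ratio before asserting) recovery is complete: 100% pixel
agreement across seeds and 100% deterministic polygon validation.

Practical consequence for real photographs: very dark regions are the
least reliable part of the map, and denoising or exposure care pays off
disproportionately there.

## 8. Problem sizes used by tests and the acceptance script

Unit tests use histograms with L ≤ 64 (100 random cases against exhaustive
oracles), small constructed label maps, and scenes from 48×48 to 512×512.
The recovery checks run ten 512×512 scenes (≈ 2.6 M pixels total) through
the full classify-and-validate pipeline with 20 reference polygons each;
the whole suite completes in about a minute on one core. These sizes were
chosen as the smallest at which area-fraction calibration, blob geometry
and the ±2% fraction contract are all comfortably exercised.
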