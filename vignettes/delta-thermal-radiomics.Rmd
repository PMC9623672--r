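---
title: "Delta thermal radiomics of dairy cow teats: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta thermal radiomics of dairy cow teats: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teatherm)
```

## The problem

Infrared thermography images skin temperature, and changes in teat skin
temperature before versus after machine milking carry information about
short-term physiological responses (blood flow, congestion) that a single
bulk temperature reading misses. Handheld thermal cameras, however, export
*colorized* images: a 3-channel palette rendering of the temperature field,
with the displayed range printed beside a colorbar. Quantitative analysis
therefore needs (i) a faithful inversion from color back to temperature,
(ii) a segmentation of each teat, (iii) a large, *named* panel of
quantitative descriptors ("image biomarkers") of the segmented region, and
(iv) a statistical screen that says which descriptors actually change after
milking. `teatherm` implements that workflow end to end, plus a synthetic
phantom generator so every stage can be validated without animal data.

## Color-to-temperature conversion

A `colorbar_spec` records the displayed range $[T_{\min}, T_{\max}]$ and the
ordered palette. `build_lut()` anchors the first and last colors at
$T_{\min}$ and $T_{\max}$ and assigns interior colors linearly by list
position, quantized half-up to 0.1 °C — the precision of the camera class
this workflow targets. Conversion assigns each pixel the temperature of its
nearest palette color (unweighted Euclidean distance over the three 8-bit
channels; ties resolve to the lower index, i.e. the lower temperature), and
stores temperatures as unsigned integers at 10 units per °C, the format
medical-image viewers expect; files go to single-frame 16-bit DICOM with
rescale slope 0.1 so a viewer displays °C directly. 8-bit storage cannot
hold the value 400 (= 40.0 °C), hence 16 bits.

Two capacity facts shape this design. A 3×8-bit image distinguishes at most
$256^3 = 16{,}777{,}216$ colors, and a 5–40 °C range at 0.1 °C precision
needs only $(40-5)/0.1 = 350$ steps, so a palette with one color per step
loses nothing. The built-in `"iron"` ramp is generated programmatically with
every channel monotone from cold to hot and all entries distinct, which
makes nearest-color inversion unambiguous. Its default size is one entry per
0.1 °C step of the colorbar range (351 for 5–40 °C) rather than a fixed 256:
with 256 entries over a 35 °C span the color spacing is 0.137 °C and the
worst-case inversion error 0.069 °C, which breaks both the exactness of the
zero-noise phantom round trip and the half-quantization-step (0.05 °C)
recovery guarantee. A channel-monotone 8-bit ramp supports at most
$3 \times 255 + 1 = 766$ distinct colors; requests beyond that are refused.

## Segmentation representation and agreement

Teat outlines arrive as ordered (row, col) vertex lists in 0-based pixel
coordinates with pixel centers at integers. The tracing convention — follow
the teat perimeter, then close the segment with a straight chord where the
teat meets the udder — is implemented by `close_with_chord()`.
Rasterization uses the even-odd rule on pixel centers with on-boundary
centers counted inside. Agreement between two segmentations is the Dice
score $2|A\cap B| / (|A|+|B|)$; `dice_summary()` adds a percentile
bootstrap confidence interval (default 2000 resamples). The percentile
bootstrap was chosen because observer-agreement Dice distributions are
skewed toward 1, so a symmetric normal-theory interval would be
inappropriate; the interval method used in the motivating study is not
stated.

## The 851-biomarker inventory

Extraction settings default to: no image interpolation, fixed bin width
0.1 °C (so, on stored integers, the gray level is simply
`stored - min(stored) + 1`), range re-segmentation off, symmetric GLCM,
no Laplacian-of-Gaussian smoothing, all wavelet sub-bands on. Under these
settings `extract_all()` emits exactly

$$14\ \text{shape} + 93\ \text{intensity/texture} +
  8 \times 93\ \text{wavelet} = 851$$

named features, with the 93 composed of 18 first-order, 24 GLCM, 16 GLRLM,
16 GLSZM, 14 GLDM and 5 NGTDM features following the standardized
definitions in the radiomics literature. Names follow
`<image>_<class>_<feature>` with image `original` or `wavelet-XXX`.

The wavelet bank treats the single 2D image as a one-slice volume: a
one-level undecimated Haar transform runs along the singleton depth axis,
then rows, then columns, with symmetric boundary extension, yielding eight
same-size sub-bands `LLL … HHH` named over (depth, row, col). This is the
only convention consistent with the 851 total ($107 + 8 \times 93$).
Symmetric extension of a singleton axis is constant, so the four
depth-high-pass bands are identically zero and contribute degenerate
(constant-image) feature values; the depth low-pass contributes a factor
$\sqrt 2$. The Haar kernel is the package's documented default: it is exact
in integer-friendly arithmetic, testable against a two-line separable
convolution, and its high-pass annihilates constants, which the validation
suite exploits.

Conventions the source literature leaves open, fixed here:

* **Direction handling (GLCM, GLRLM).** Matrices are built per direction
  (horizontal, vertical, two diagonals, distance 1), features computed per
  direction and then averaged.
* **Degenerate co-occurrence.** A direction with no valid neighbor pairs
  falls back to the diagonal gray-level histogram, so a single-pixel ROI
  produces the single-entry matrix $p(1,1)=1$.
* **GLDM.** Dependence counts use the 8-neighborhood at distance 1 with
  gray-level tolerance $\alpha = 0$; a pixel's matrix column is
  $j = \text{count} + 1$ (the center counts as part of its own dependence
  group), keeping the small-dependence emphases defined for isolated
  pixels.
* **NGTDM Strength** uses a $10^{-16}$ guard in the denominator so constant
  ROIs return 0 instead of 0/0.
* **Binning** is minimum-anchored (bin 1 at the ROI minimum), making all
  discretized-texture features invariant to a constant temperature offset.
* **First-order moments** are population moments (denominator $N$);
  Kurtosis is not excess kurtosis; percentiles use linear interpolation
  (R type 7). Total Energy equals Energy times the pixel area, which is 1
  for uncalibrated thermogram pixels.
* **Shape.** Mesh surface and perimeter come from a marching-squares
  contour of the mask (pixel centers as nodes, saddle cells resolved
  foreground-connected). The raw marching-squares length overestimates a
  smooth boundary by $8(\sqrt 2 - 1)/\pi \approx 1.055$ on average over
  orientations, so the perimeter applies that isotropic correction — exact
  in the mean for smooth closed contours, slightly short for axis-aligned
  polygons. Axis lengths are $4\sqrt\lambda$ from the eigenvalues of the
  pixel-coordinate covariance. Because thermogram pixels are not spatially
  calibrated, only the ratio features (Sphericity, Elongation,
  Eccentricity, Extent, Solidity, Aspect Ratio) are meaningful across
  images — the absolute lengths are reported but should be interpreted
  only within an image.

## The expression screen

For each feature the screen computes a two-sided paired Student's t-test
across teats (the same teats are measured pre and post, so the paired form
is the default; an unpaired variant sits behind a flag), Cohen's d in the
pooled-SD form

$$d = \frac{\bar x_{\text{post}} - \bar x_{\text{pre}}}
           {\sqrt{\big((n_1-1)s_1^2 + (n_2-1)s_2^2\big) / (n_1+n_2-2)}},$$

and the absolute percent difference of means
$|\bar x_{\text{post}} - \bar x_{\text{pre}}| / |\bar x_{\text{pre}}| \times 100$.
A feature is **expressed** when $p < 0.01$ and $|d| > 1.2$ jointly (both
thresholds adjustable). The absolute value of $d$ is compared against the
threshold, matching the direction-free phrasing of the criterion. No
multiple-testing correction is applied by default — the screen is a
descriptive filter, not a confirmatory test — but Benjamini–Hochberg
adjustment is available via `adjust = "BH"`. Features whose paired
differences are constant to within floating-point round-off are flagged
`zero_variance` and excluded from expression rather than given a fake
p-value.

## Local feature maps

`local_map()` slides a square window (stride 1, default 10 px — even
windows span `floor((w-1)/2)` before and `floor(w/2)` after the center)
over the ROI and reports the window statistic at every in-ROI center whose
window covers at least `min_pixels` (default 4) ROI pixels: mean, skewness,
histogram entropy (0.1 °C bins within the window), or gradient magnitude
($\sqrt{g_x^2+g_y^2}$ of central differences, window-averaged by default
with the raw per-pixel variant behind a flag, since the display convention
is not fixed by the source material). Sliding rather than tiled windows
were chosen because they produce the smooth maps the application calls for.
Window skewness on zero-variance windows is defined as 0 (`NaN` available
behind a flag); internally the sliding moments are computed on
ROI-mean-centered values, which is mathematically identity-preserving for
skewness and avoids catastrophic cancellation in the cubed sums.
`delta_map()` subtracts two same-feature maps on the intersection of their
defined regions — the ROIs may differ, because teats elongate after
milking — and returns all-`NA` (not an error) when the regions are
disjoint.

## The phantom generator

`phantom_spec()` describes a synthetic thermogram: a cool background
(default 18 °C base with a mild vertical gradient and a smooth sinusoidal
ripple) and teat-shaped warm regions. Each teat is a superellipse
$|x'/a|^p + |y'/b|^p \le 1$ (default exponent 2.5, giving the rounded
apex of a real teat) with temperature

$$T = T_\text{base} + \Delta_\text{apex}\, \ell^{k} + \Delta_\text{edge}\, \rho^2,$$

where $\ell \in [0,1]$ runs from the udder attachment to the apex and
$\rho$ is the normalized superellipse radius. Defaults
($T_\text{base} = 34$ °C, $\Delta_\text{apex} = -1.5$ °C,
$\Delta_\text{edge} = -1$ °C, $k = 3$) put teat skin in the physiological
range for healthy dairy cows and concentrate the temperature gradient at
the teat end, the qualitative pattern seen in pre-milking thermograms. The
full-frame default is 640×480 with two non-overlapping hind teats; the
colorbar default is 5–40 °C through the iron ramp. Optional Gaussian pixel
noise (°C, before quantization) and impulse ("salt and pepper") noise
(fraction of rendered pixels replaced by the coldest/hottest palette color)
emulate the two noise sources thermograms actually show.

`effect_spec()` turns a pre-milking spec into a post-milking one: a mean
shift `d_mean`, a major-axis `elongation` (the motivating observation is a
+31 % major-axis increase after milking), an `area_factor`, an apex-gradient
scaling, and a skew factor acting on the ramp exponent. `generate_cohort()`
draws `n_teats` independent single-teat frames with per-teat jitter — axes
× U(0.9, 1.1), orientation jitter, baseline temperature + N(0, 0.5 °C)
across teats — so that Cohen's d in the screen faces realistic between-teat
variability; 0.5 °C is a realistic across-animal spread for healthy teat
skin. All randomness flows from one master seed through per-teat sub-seeds.

What the phantom does *not* emulate: true udder anatomy and occlusion,
motion blur, emissivity/reflection physics (the acquisition metadata are
carried but never used to correct temperatures), JPEG chroma artifacts, and
the spatial autocorrelation structure of biological skin temperature.
Passing tests on phantoms therefore validate the *computational* pipeline —
inversion exactness, feature definitions, statistical behavior — not the
biology of real cow images.

## Validation strategy and problem sizes

Every texture matrix is checked against an independent brute-force
enumeration oracle on 100 random masked images (≤10×10, 2–5 gray levels);
first-order features and window maps against naive per-formula/per-window
recomputation at 1e-9; the wavelet low-pass against a separable-convolution
oracle; rasterization against a scalar point-in-polygon loop; DICOM output
against an independent reader. The screening behavior is validated by
simulation: 100 cohorts of 36 teats (the scale of an 18-cow study) with a
+2 °C injected mean shift at noise σ = 0.3 °C must flag the mean-sensitive
first-order features expressed in ≥99 % of cohorts, and 100 null cohorts
must keep every feature's false-expression rate within binomial tolerance
of the 1 % significance level (the d-threshold only lowers it). The
simulation cohorts use 120×96 single-teat frames, the generator's fast
path (ground-truth temperature maps, bypassing the render/invert step that
is exact at σ = 0 anyway), and the first-order panel — the panel the power
claim is about; the full 851-feature path and full-size 640×480 frames are
exercised separately in the inventory, round-trip and pipeline tests.

## Known limitations

* Only single-frame monochrome Explicit-VR-Little-Endian DICOM is read;
  vendor radiometric payloads are out of scope and palettes must be
  supplied, not OCR'd from the image margin.
* The perimeter's isotropic correction trades axis-aligned accuracy for
  rotation-invariant accuracy; Sphericity of a digital square reads ~5 %
  high as a result.
* Texture features are 2D only (the one-slice-volume wavelet convention
  notwithstanding); no 3D meshes, no LoG-filtered features.
* Absolute shape features carry pixel units with no physical calibration.
* The JPEG robustness of nearest-color inversion is only as good as the
  palette's separation in color space; heavily compressed images can
  alias to neighboring temperatures.
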