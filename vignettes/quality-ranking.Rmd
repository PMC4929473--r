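---
title: "Ranking microscopy images by relative quality: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking microscopy images by relative quality: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iqrank)
```

## The ranking model

`iqrank` does not attempt to assign an absolute quality number to an
image. It ranks the images of one dataset against each other, on the
premise that a good microscopy image has (a) contrast — bright detail
over dark background, occupying much of the dynamic range — and (b)
proper focus, i.e. fine detail that survives into the high-frequency part
of the power spectrum. Both properties can be captured by global
statistics that are cheap, deterministic, and easy to reason about.

### Contrast: masked histogram entropy

The histogram of a fluorescence image is dominated by background pixels,
and the background fraction varies strongly between fields of view. The
package therefore restricts the histogram to a *detail mask*: the image
is smoothed with a uniform (box) mean filter of radius `mask_radius`
(default 100 px, window side $2r+1$), and the mask selects pixels whose
smoothed value strictly exceeds the `mask_percentile`-th percentile
(default 80) of the smoothed image. Smoothing first means isolated bright
pixels (hot pixels, dust) cannot enter the mask on their own; the
percentile construction caps mask coverage at roughly 20% of the image.
The contrast score is the Shannon entropy
$E = -\sum_i P_i \log_2 P_i$ (in bits) of the original pixel values at
the masked positions, binned into `bins` (default 256) equal-width bins
spanning the min–max range of the masked values.

Choices a user should be aware of:

* **Bin range.** Bins span the observed min–max of masked values, not the
  sensor range, so the entropy measures occupancy of the values actually
  present; a fixed-range variant can be had by passing pre-scaled images.
  256 bins is natural for 8-bit data and works well for 16-bit microscopy
  data too, since it is the occupancy *pattern* that matters.
* **Entropy base.** Base-2 (bits). The base rescales all entropies by a
  constant, so dataset rank order is unaffected.
* **Boundary handling.** The mean filter pads by symmetric reflection
  (edge row/column included), avoiding dark-border artifacts in the mask.
* **Strictness and ties.** Thresholding is strict (`>`), which guarantees
  coverage ≤ 20% except on heavily tied smoothed images (flat plateaus),
  where the comparison relaxes to `>=`; a constant image then yields the
  all-true mask rather than an empty one.
* **Small images.** If the image is smaller than the filter window the
  radius is clamped to `floor(min(dim)/2) - 1` with a warning; a radius
  exceeding both image dimensions is an error.

### Detail, blur and noise: power-spectrum tail statistics

The 2D power spectrum is the squared magnitude of the centered discrete
Fourier transform, divided by the image mean gray level times the pixel
count. The division makes spectra comparable across images of different
brightness: scaling an image by $k$ scales the normalized spectrum by
exactly $k$, which cancels in the dataset normalization. The 2D spectrum
is reduced to a 1D profile in one of two ways:

* **summed** (default): all rows are added, all columns are added, each
  signed-frequency profile is folded (negative frequencies added onto the
  matching positive ones), and the two folded profiles are summed,
  interpolating the shorter one for non-square images. This costs only
  additions and is much faster than the radial average.
* **radial**: the mean power over all pixels whose rounded Euclidean
  distance from the spectrum center equals $r$, for integer $r$ up to the
  maximum inscribed radius. A brute-force binning loop serves as its
  oracle in the test suite, which the implementation matches exactly.

The frequency axis is expressed as the fraction of the maximum
representable frequency, so the tail `threshold` has the same meaning for
any image size. Statistics are computed on the profile values strictly
above the threshold: `fMean`, `fSTD`, `cv`, moment skewness, excess
kurtosis, the Shannon entropy of the renormalized tail, `high90` (summed
power above 90% of the maximum frequency) and `MeanBin` (mean of the five
samples just above the threshold). An all-equal tail is assigned zero
skewness and kurtosis by convention. The tail must contain at least five
samples; a higher threshold raises an error suggesting a lower one.

**Choosing the threshold.** At the default 40% the statistics ignore the
large spatial structures that differ between fields of view, which is
what makes cross-image ranking meaningful; they are then extremely
sensitive to small amounts of blur but saturate once blur has pushed the
tail to the numerical floor (in our synthetic series around blur radius
5–6). At 2% the response stays monotone over the whole radius 0–29 range,
at the price of sensitivity to scene-dependent low-frequency content —
the right trade-off for autofocus-style series of a single field.

### Normalization, composites, triage

Each measure column is divided by its dataset maximum (absolute values
first for the signed skewness and kurtosis), giving scores in [0, 1];
all-zero columns map to zeros with a warning. Inverted columns
(`invSTD`, `invSkew`, `invMeanBin` = 1 − normalized value) are
materialized in the same pass, so blur-oriented and noise-oriented
rankings do not require two runs. Composites are plain means of selected
normalized columns; `entropy` + `invSTD` is the recipe for high-contrast,
non-noisy structure. Ranking is a sorted *view* — the results CSV always
keeps the dataset enumeration order, with ties broken by filename so
output is deterministic. `two_level_blur_flags()` turns a normalized
score into `in_focus` / `blurred` / `out_of_focus` labels given two cut
points, mirroring the two blur levels one typically wants to distinguish
in screening time courses.

### Baseline autofocus metrics

For benchmarking, the package implements the Brenner gradient
$\sum_{i,j} (G_{i,j+2} - G_{i,j})^2$ (differences along the row
direction; zero for images constant along x) and the Spectral Moments
score $\sum_i i \log_2(1 + P_i)$ over the entire sum-normalized 1D power
spectrum. The moment formula is isolated in a single pure helper so the
expression can be adjusted without touching any behavioral test. Both
metrics decrease monotonically under blur on every synthetic series in
the test suite; the Spectral Moments score generally spans a smaller
dynamic range than the 40%-threshold tail measures — except on the
noiseless bead-like base, where the tail measure itself saturates early
(see *Limitations*).

## The synthetic data generator

Real focus-series benchmarks are built from microscope images that cannot
ship with a package, so `iqrank` generates its own study conditions.
`make_base_image()` produces 256×256 images (the size used throughout the
validation suite; any size ≥ 64 works) on a 0–255 intensity scale:

* `filaments` — 14 random line segments of Gaussian cross-section
  (σ = 1.2 px, amplitude 150 over background 8), emulating intermediate
  filaments;
* `beads` — 40 Gaussian spots (σ = 2 px, amplitude 180 over background
  10), emulating fluorescent nanoparticles;
* `ramp` — a pure linear gradient (10 → 245), a pathological
  low-frequency image;
* `white_noise` — i.i.d. uniform pixels, a pathological high-frequency
  image;
* `scene` — a photograph-like composite (large smooth blobs, filaments,
  spots, mild Gaussian sensor noise of σ = 2.5). Twelve scenes drawn with
  consecutive seeds form the `mixed` dataset, emulating a set of
  grayscale photographs: one statistical family with comparable broadband
  spectra. A one-of-each-kind mixture would be meaningless for
  cross-image ranking, because e.g. a ramp and a white-noise image differ
  by orders of magnitude in tail power before any blur is applied.

`gaussian_blur()` applies a separable Gaussian with symmetric-reflect
boundary (total intensity conserved; kernel truncated at 4σ). The blur
**radius follows the kernel-support convention radius = 3σ**. This is a
deliberate design decision: mapping the radius directly to σ makes a
radius-5 blur attenuate the 40% tail by $e^{-4\pi^2\sigma^2 f^2} \approx
10^{-17}$, below any representable signal, so no measure could respond
out to radius 5 at the 40% threshold — whereas with radius = 3σ the
40%-threshold measures track blur reliably to radius ≈ 5 and the
2%-threshold measures stay monotone over radii 0–29, the qualitative
behavior the method is designed around.

Blur series are written as **16-bit TIFF** (the native precision of
microscope acquisitions); the photograph-like `mixed` dataset is written
as 8-bit, matching photographs. 8-bit output for the single-kind series
would make consecutive ramp images bit-identical (sub-quantization
differences) and so introduce artificial rank ties. Every series carries
a ground-truth sidecar CSV (`image_id`, `kind`, `radius`, and for the
screening series a `label`), which is the oracle for all separation
tests. `make_hcs_like_series()` emulates a screening well over 48 time
points: content density ramps from nearly empty to detail-packed, and a
seeded ~1/6 of frames is blurred at radius 2 ("blurred") or radius 8
("out_of_focus").

**What the generator does not emulate:** optical point-spread functions
(defocus is a Gaussian screen, not a Born–Wolf model), photon-counting
noise statistics, detector artifacts, or the content diversity of real
photographs. Passing tests therefore demonstrate the mechanics and the
qualitative blur/noise response of the measures, not field performance on
any particular instrument.

## Numerical choices

* FFTs use `stats::fft`; the spectrum is centered so the zero-frequency
  sample sits at index `floor(n/2) + 1` on each axis (for odd axes this
  is the true middle sample, and folding pairs every frequency exactly).
* Radial binning uses rounded Euclidean distance — the simplest rule that
  an independent loop oracle can reproduce exactly.
* Skewness and kurtosis use the plain moment estimators (`e1071`,
  type 1), kurtosis as excess kurtosis; the convention shifts values, not
  ranks.
* Percentiles use the default interpolating quantile (type 7); with the
  strict mask inequality this puts the below-threshold fraction within
  one pixel of the nominal percentile on untied data.
* The results CSV prints floats with nine significant digits, enough for
  normalized scores to round-trip within 1e-9 and for byte-identical
  re-runs.
* Degenerate inputs are handled explicitly: all-zero images are rejected
  by the spectrum normalization, constant images fall back to the
  all-true mask and a single-bin histogram (entropy 0), all-zero measure
  columns normalize to zeros with a warning, and fewer than two records
  is an error because relative ranking is undefined.

## Known limitations

The test suite asserts the intended behavior everywhere and currently
documents three genuine boundary cases, kept visible rather than patched
around:

1. **`fSTD` on a white-noise base is not monotone at the first blur
   step.** An i.i.d. noise image has a *flat* spectral tail, whose spread
   is only sampling noise; any blur imposes a decaying envelope that
   *increases* the tail spread before further blur collapses it. This is
   the same fact as "noise moves the spectral measures opposite to blur":
   for noise-dominated data the inverted measures are the right tool.
   `fMean` and `MeanBin` are monotone on all four base kinds.
2. **Mixed-dataset separation at radii {0, 1, 2} is imperfect.** Under
   the radius = 3σ convention a radius-2 blur attenuates the 40% tail by
   only a factor of ~2, which is smaller than the natural tail-power
   spread across heterogeneous photograph-like scenes; some sharp scenes
   score below some blurred ones (pairwise ordering is ~80–92% correct,
   not 100%). Stronger per-image blur, or per-scene (rather than global)
   comparisons, separate perfectly.
3. **On the noiseless bead-like base the 40%-threshold `fSTD` saturates
   early**, capping its measured dynamic range over radii 0–29 below the
   Spectral Moments baseline's on that one series. This is a floor
   effect of a synthetic image with no noise floor, not a property of
   real microscope data.

Absolute cross-dataset scores, opinion-score modelling, structure-aware
measures (e.g. gradient directionality to tell filamentous from dotty
content), windowing before the FFT, and proprietary microscope formats
are out of scope.
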