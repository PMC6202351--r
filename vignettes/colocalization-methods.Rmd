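---
title: "Measuring colocalization per cell: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring colocalization per cell: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coloctools)
```

## The problem

Colocalization asks whether two or three labeled molecules occupy the same
locations within a cell. Whole-image correlation of channel intensities is
dominated by the background (most pixels are extracellular) and by
cell-to-cell heterogeneity. `coloctools` therefore (i) identifies individual
cells from a dedicated cell-identification channel, mask, or ROI set, so
intracellular pixels can be separated from background, and (ii) computes
every metric *per cell*, so heterogeneous populations can be summarized,
histogrammed, or gated rather than averaged away.

## Pipeline model and assumptions

**Inputs.** Each channel is a stack of monochrome rasters of identical
dimensions and order; pixel values are arbitrary units and are never
rescaled on load. One channel identifies cells (phase contrast,
bright-field, a membrane or cytoplasmic label); two or three reporter
channels carry the signals under study.

**Alignment.** Channels acquired separately can be offset by a few pixels.
Each channel image is thresholded, and the reporter mask is translated over
`[-max_shift, max_shift]^2` (default 20 px, configurable) to maximize
foreground overlap with the cell-identification mask. The search is
exhaustive over integer shifts, so it is deterministic and exactly inverts a
synthetic translation; ties prefer the smallest `|dy| + |dx|`, then smallest
`dy`, then `dx`. Pixels shifted out of the frame are discarded and vacated
pixels become exactly 0, so all channels keep one common aligned region.
Alignment is per-slice because fields of view drift independently; it
assumes thresholding selects cell areas in both channels — with signal-free
or saturated images the estimated shift is meaningless, which is why the
pipeline logs every shift for inspection. Rotation, scaling, and subpixel
registration are out of scope (subpixel interpolation would alter the pixel
values the metrics depend on).

**Background polarity.** Assuming background pixels outnumber cell pixels,
positive skewness of the intensity distribution (sample third standardized
moment, `n` normalization) indicates a dark background, negative a light
one. Exactly zero skew falls back to dark with a warning. A manual override
is available wherever polarity enters.

**Thresholding.** All auto-threshold methods operate on a 256-bin histogram
of min–max scaled intensities and map the chosen bin back to raw units;
foreground is strictly above the cutoff (dark background) or strictly below
it (light background, implemented by mirroring the histogram). `Default` is
the iterative intermeans (IsoData-family) algorithm; Otsu, Mean,
Kittler–Illingworth MinError, and Triangle are also registered, and the
registry is extensible. Constant images are rejected rather than guessed at.

**Segmentation.** Foreground components are 8-connected and labeled in
raster-scan order of their topmost-leftmost pixel, making labels fully
deterministic. Optional watershed splitting computes the exact Euclidean
distance transform (frame edges count as background), takes plateau-merged
local maxima of the EDT as markers, and floods synchronously from the
markers in order of decreasing distance; pixels reached by two labels in the
same step become watershed lines and revert to background, so splitting can
only increase the object count. The pre-watershed area filter removes
objects larger than a user bound *before* watershed, because large debris or
aggregates would otherwise be shattered into cell-sized fragments that
contaminate the analysis. Objects touching the frame border are always
removed — a partially imaged cell yields misleading values.

**Cell filters.** Each filter is an inclusive interval test on one feature;
a cell is retained iff it passes every filter, so filters are
order-independent. Physical features are measured on the cell-identification
channel (Area, Perimeter, Circularity `4πA/P²` clamped to `[0,1]`,
AspectRatio/Roundness from a second-moment ellipse fit with the 1/12
pixel-extent correction, Solidity against the convex hull of pixel corners,
Feret diameter). Intensity features are per reporter channel: mean/median
intensity and the background ratios (object mean or median divided by the
extracellular mean or median of the same image) — the practical test for
"does this cell express signal above background". `NaN` feature values fail
the filter.

Perimeter is the crack length: the count of exposed pixel edges along the
object boundary. It is exactly 12 for a 3×3 square, but overestimates smooth
shapes (a large disc's crack perimeter is `8r`, not `2πr`), so circularity
of a pixelated disc plateaus near 0.61 rather than 1. Interval bounds on
these features should be chosen empirically from the feature table rather
than from continuum formulas.

## Thresholds and metrics

A threshold is the *top percentile* `F_T` of in-cell pixels by intensity:
exactly `max(1, round(F_T · N))` pixels, ranked by descending intensity with
ties broken by ascending pixel index (R's `round` half-to-even applies at
the boundary). Rank-based selection makes the selected *count* exact, which
in turn makes the threshold-overlap arithmetic exact on the grid, ties or
not.

With per-channel selected fractions `f_i = n_i / N`:

- observed overlap `A_O` = fraction of pixels selected in **all** channels,
- expected overlap under independence `A_E = ∏ f_i`,
- maximum `A_max = min f_i`, minimum `A_min = max(0, Σ f_i − (k−1))`
  (inclusion–exclusion bound; `k` = number of channels).

**TOS.** Linear scaling maps `A_O` to `(A_O − A_E)/(A_max − A_E)` above
expectation and `(A_O − A_E)/(A_E − A_min)` below, so +1/0/−1 mean
maximal/independent/minimal overlap. Log scaling uses
`ln(A_O/A_E)/ln(A_max/A_E)` and `−ln(A_O/A_E)/ln(A_min/A_E)`; when
`A_min = 0` the log form diverges on the anticolocalization branch and the
linear value is used instead (a documented design choice — the log variant
is only defined up to its source's supplement). Whenever any channel's
selection is the whole cell (`f_i = 1`), overlap is forced and the score is
`NaN`: this is the blacked-out last row/column of a TOS metric matrix. The
package computes the terms from *actual* selected counts, not nominal
fractions, so the invariant `A_min ≤ A_O ≤ A_max` holds exactly and the
formula agrees bit-for-bit with brute-force set counting (an acceptance
property).

**PCC / SRCC / ICQ.** These do not require a threshold. When one is given,
the computation restricts to pixels selected in **all** channels
("intersection"; configurable to union), as if only those pixels existed —
including the means inside ICQ. The intersection rule is what makes a
three-channel ICQ fail (NaN) when no pixel clears all three thresholds,
matching the blacked-out entries seen in three-channel matrices. ICQ
excludes pixels whose demeaned product is zero from both numerator and
denominator, avoiding bias from flat regions; its range is `[-0.5, 0.5]`
for two channels and `[-0.25, 0.75]` for three.

**Manders.** `M1` is the fraction of channel 1's total intensity in pixels
selected by channel 2 (both other channels, for `k = 3`); cyclic for
`M2`/`M3`. It always needs a threshold and is scale-invariant only under
positive scalar multiplication (not shifts), unlike the correlation metrics.

**Costes' thresholds.** An OLS line `B = a + bA` is fitted to all in-cell
pixels (orthogonal regression would also be defensible; OLS is the
documented, configurable-in-code choice). Candidate `T_A` values descend
through the sorted unique intensities of A (or 512 evenly spaced quantiles
when there are more); the first pair `(T_A, a + b·T_A)` whose
below-both-thresholds pixels have Pearson correlation ≤ 0 is selected. On
perfectly correlated channels the below-threshold correlation never reaches
zero and the scan descends to the minimum with a warning. On independent
noise the correlation of "everything but the top pixels" is the full-sample
correlation: when the realized sample correlation of the seeded noise is
non-positive the scan stops within the top decile; seeds that happen to
realize a slightly positive sample correlation legitimately descend further
before stopping. This is a property of the method, not of the
implementation, and is why the acceptance check pins a seeded instance.

## Metric matrices, heat maps, reports

The grid for metric matrices reuses `F_T` as the step: thresholds
`{F_T, 2F_T, …}` capped at 1, with the remainder as the last step when
`F_T` does not divide 1 (step 0.3 → 0.3, 0.6, 0.9, 1.0). Axis 1 is reporter
1's `F_T`, axis 2 reporter 2's, axis 3 reporter 3's. Aggregation across
cells is element-wise mean, median, or mode with `NaN` excluded per element
(`NaN` only when every cell is `NaN` there); the mode bins values at width
0.01 over `[-1, 1]` and reports the midpoint of the fullest bin, ties to
the lower bin — the bin width is a documented choice, as the original tool
does not state one.

Heat maps rescale in-cell intensities so the scope's minimum maps to 0 and
maximum to 255: per cell (where does the signal peak within each cell?),
per image (are cells unevenly bright within a field?), or per stack
(bleaching/labeling drift across fields or time). Background is 0, constant
scopes map to 0, outputs are integers, and rescaling an already cell-scaled
raster is the identity.

The per-cell data table holds the label (`image:cellnumber`), physical
features, per-channel mean intensities, and metric values, with `NaN`
written literally wherever a value could not be computed. Summaries report
count/mean/median/sample standard deviation (n−1; `NaN` for a single value)
over finite values. Histograms use equal-width bins spanning the finite
range, right-closed with the first bin closed at the minimum (so `[0, 0.5,
1]` with two bins counts `2, 1`), and report the midpoint of the fullest
bin as the mode. Masks (8-bit, 255 = in-cell) and ImageJ-compatible
`RoiSet.zip` outlines are exported per image; outlines are crack-boundary
polygons in ImageJ corner coordinates, so re-importing them reproduces the
identical pixel sets for hole-free objects (interior holes are filled on
re-import — the one known asymmetry of the round trip).

## The synthetic generator: what it emulates, what it does not

`synth_config()` + `generate_cells()` + `paint_reporters()` build a stated
world: non-overlapping random ellipses (default semi-axes 7–9 px ≈ 200 px
cells, a typical bacterium-to-small-eukaryote scale at ordinary
magnification) on a noisy background (level 100, Gaussian sd 10, a low but
non-zero camera floor), with a bright cell-identification channel and
reporters painted per pattern:

- `correlated(ρ)` — per-cell bivariate (equicorrelated, for 3 channels)
  normal pixel pairs, mean 3000, sd 500, clipped at 0 and rounded to 16-bit
  integers; per-cell PCC recovers ρ up to sampling error (±0.05 at 100
  cells × 200 px). Note SRCC of a bivariate normal is attenuated to
  `(6/π)·asin(ρ/2)` ≈ 0.78 at ρ = 0.8 — the wider SRCC tolerance in the
  acceptance property is that attenuation, not noise.
- `colocalized_foci` / `anticolocalized_foci` — bright foci sized exactly to
  the top-`F_T` selection, identical or disjoint across channels, so TOS at
  that `F_T` is exactly +1 / −1 by construction.
- `nested_organelles` — channel 1 bright at the cell center, channel 2 in a
  ring around it, all channels dimmest in a shared outer zone: tight
  thresholds select disjoint structures (TOS < 0), loose thresholds exclude
  the same peripheral pixels (TOS > 0) — the sign-flip signature of
  organelles that touch at their edges but not their centers.
- `independent` — no structure; the null.

Determinism: every draw derives from the config seed through R's default
Mersenne-Twister generator, and rasters are integer-valued, so datasets are
bit-reproducible across platforms.

What the generator does *not* emulate: point-spread blur, shot noise,
vignetting, uneven illumination, autofluorescence gradients, or z-structure.
A green test on synthetic data therefore establishes the *arithmetic* of
segmentation and metrics — not robustness to optical artifacts, which real
acquisitions must still be checked for (misalignment and threshold quality
in particular).

## Numerical choices and degenerate inputs

- Selection count `max(1, round(F_T·N))`: at least one pixel is always
  selected; R's half-to-even rounding is the tie rule at bin boundaries.
- Grid construction uses a 1e-9 tolerance so steps like 0.1 do not produce
  a spurious extra point from floating-point drift; the last grid point is
  exactly 1.
- Metrics return `NaN` (never an error) for degenerate cells: constant
  channels (PCC/SRCC), empty threshold intersections (ICQ, restricted
  correlations), zero channel totals (Manders), forced overlap (TOS).
  Errors are reserved for precondition violations: Costes with fewer than 8
  pixels or a constant channel, thresholds of constant images, empty masks
  in alignment.
- Watershed flooding is synchronous per distance level, so the result does
  not depend on queue order; markers closer than 2 px (plateau-connected)
  merge into one.
- TIFF I/O is deliberately minimal: uncompressed grayscale 8/16-bit
  unsigned or 32-bit float, single or multiple strips, both byte orders on
  read. Compressed (LZW/ZIP) TIFFs are rejected with the compression named;
  decompress them upstream. RGB/CMYK input is refused — channel images must
  be monochromatic so intensities are unambiguous.
- Overlapping hand-drawn ROIs: the later ROI wins the contested pixels (the
  original tool leaves this unspecified); ROIs fully outside the frame are
  dropped with a warning.

## Known limitations

- No physical units: all lengths are pixels, all intensities arbitrary
  units.
- Alignment is translation-only and mask-based; strong illumination
  differences between channels can bias the mask overlap objective.
- ImageJ feature parity is approximate for ellipse- and hull-derived
  features (AspectRatio, Roundness, Solidity, Feret); Area, centroids,
  intensities, and background ratios are exact by construction.
- Three-channel scatterplot data is returned as a table; rendering (2-D
  projections, point color) is left to the caller.
- The histogram of a constant metric degenerates to one zero-width bin —
  its `bin_width` of 0 is reported as such rather than faked.
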