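---
title: "Mapping the membrane dipole potential of plasma and organelle membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the membrane dipole potential of plasma and organelle membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dipoleratio)
```

## The measurement

The dipole potential is the large positive intramembrane potential created
by the ordered dipoles of lipids and interfacial water. It cannot be
measured electrically in an intact cell, but the 3-hydroxyflavone dye F66
reports on it optically: its excited state undergoes an intramolecular
proton transfer (ESIPT), producing a normal (N\*) and a tautomer (T\*)
emissive species whose relative population depends on the local electric
field. The ratio of the T\*-band (543--589 nm) to the N\*-band
(463--527 nm) emission therefore rises monotonically with the magnitude of
the dipole potential. Because F66 accumulates in *all* membranes after a
long incubation while a short second staining step brightens the plasma
membrane, a single dual-band confocal image pair, combined with a
fluorescent organelle marker, contains enough information to compare the
dipole potential of the plasma membrane with that of lysosomes, the Golgi
apparatus, the endoplasmic reticulum, or mitochondria — cell by cell,
inside living cells.

`dipoleratio` implements the complete quantification chain for such image
pairs:

1. **Background estimation** over a user-annotated cell-free rectangle
   (`estimate_background()`), per channel.
2. **Cell segmentation** by a manually seeded watershed on the F66
   intensity relief (`segment_cells()`): one interior seed per cell plus
   one outside seed; the bright membrane ridge becomes the basin divide.
3. **Compartment masks** (`build_compartment_masks()`): intracellular
   membranes are interior pixels whose F66 intensity exceeds a fixed
   multiple (default 4) of the background mean; organelle membranes are
   interior pixels whose marker intensity exceeds a maximum-entropy
   (Kapur) histogram threshold.
4. **Ratio mapping** (`ratio_map()`): per pixel,
   $(T - \bar{b}_T) / (N - \bar{b}_N)$ after per-channel background
   subtraction.
5. **Per-cell statistics** (`measure_cells()`): median and quartiles of
   the valid ratio pixels per compartment, and the organelle median
   normalized to the plasma-membrane median of the *same* cell.
6. **Group statistics** (`welch_t()`, `anova_tukey()`,
   `compare_compartments()`): plasma membrane vs organelle by Welch's
   t-test on per-cell medians; organelle vs organelle by one-way ANOVA
   followed by Tukey's HSD on the normalized medians.

## Segmentation model and its numerical choices

The watershed floods the relief from the seeds in non-descending intensity
order with 4-connected growth, so basins grow from the dim cytosol and dim
extracellular space and meet on the bright membrane ridge. The relief is
the *sum* of the N\* and T\* images by default (`relief_channel = "sum"`);
either single channel can be selected instead. Flooding on the raw
intensity (rather than a gradient image) is the default because the
surface stain makes the plasma membrane itself the ridge; a gradient
relief can be emulated by passing a precomputed stack.

Determinism matters for reproducible masks, so the tie-break is part of
the contract: among pixels of equal relief value the one queued first
wins, and pixels are queued in lexicographic (row, col) order. A pixel
whose already-labeled 4-neighbours carry two or more distinct labels
becomes a watershed-line pixel (thickness 1) and never propagates. The
plasma-membrane mask of a cell is the set of line pixels adjacent to its
basin, dilated by `pm_line_dilation_px` (default 1, a 3×3 element) and
restricted to pixels outside every cell basin; with a line pixel adjacent
to two cells, the lower cell id wins. Consequently interiors, membrane
masks and the outside mask always partition the image — an invariant the
test suite asserts on every fixture. The default dilation of one pixel
reflects that the optical width of the stained membrane at ~52 nm pixels
is set by the point-spread function (a few pixels), not by the bilayer.

Cells whose basin touches the image border are measured but flagged, and
excluded from group statistics by default (`include_border_cells`),
since a clipped cell has a clipped membrane ring.

## Thresholds

* **Intracellular membranes**: threshold = `f66_threshold_multiplier`
  (default 4) × the background mean of the relief channel. With the
  summed relief this is four times the summed N\* and T\* background
  means.
* **Organelle marker**: 256 equal-width histogram bins spanning `[0, max]`
  of the marker intensity within the union of all cell interiors of the
  image; the Kapur criterion maximizes the sum of the Shannon entropies of
  the below- and above-threshold class distributions. The histogram is
  per image, not per cell, because organelle markers are thresholded per
  field in practice; exact or floating-point-level ties resolve to the
  lowest bin. `marker_threshold_override` substitutes a visually
  confirmed threshold and is flagged as such in the run report.
* The organelle mask is defined by the marker alone (not intersected with
  the F66 membrane mask) — the marker is the compartment's identity; the
  F66 intensity is its readout. `intersect_f66 = TRUE` enables the
  intersection variant.

## Ratio statistics

Only the denominator gates pixel validity: a pixel enters statistics when
its background-subtracted N\* count exceeds `ratio_denominator_epsilon`
(default 1 count, below which ratios are shot-noise dominated). Negative
numerators are allowed so that the estimator stays unbiased near zero.
Note that epsilon is denominated in counts: rescaling the intensities by a
constant requires rescaling epsilon to preserve the valid set exactly.
Medians and quartiles use type-7 quantiles everywhere (even-count median =
mean of the two central order statistics). A compartment with fewer than
`min_pixels` (default 10) valid pixels in a cell is dropped with a warning
— a median over fewer pixels is too unstable to compare.

The paper's comparison of plasma membrane vs organelle uses an unpaired
Welch test although the two values come from the same cells; `welch_t()`
implements the unpaired test as the default and offers `paired = TRUE`
for sensitivity analyses, without taking a position on which is more
appropriate. ANOVA/Tukey operate on per-cell normalized medians pooled
across experiments; no experiment-level blocking factor is modeled because
none is described for the data the packaged parameter sets transcribe.

## The synthetic generator

`generate_experiment()` renders single-cell 256×256 images (52 nm pixels)
whose per-cell true ratios are drawn from normal distributions with the
packaged per-cell-line moments (`f66_parameter_set()`), truncated at 0.1.
Each cell is an elliptical membrane band — a one-pixel crest at the N\*
amplitude `amp_pm` flanked by one pixel at 80% on either side — around an
interior holding organelle structures (discs, a curved ribbon, a
reticular web, or filaments, for lysosomes, Golgi, ER and mitochondria
respectively), a generic endomembrane web with its own drawn ratio
(default mean 2.4, SD 0.3 — chosen between the packaged organelle and
plasma-membrane levels so the whole-intracellular analysis has realistic
content), and flat background. Expected intensities are
`background + amplitude` (N\*) and `background + ratio × amplitude` (T\*),
so with noise disabled the background-subtracted pixel ratio *equals* the
true ratio on every structure pixel, and the whole pipeline is exact on
such fixtures: the watershed basin of a clean cell equals the second
4-connected erosion of the filled ellipse by construction, the line lies
on the crest, and recovered medians equal the drawn truths to floating
point. This exactness is what the end-to-end identity tests assert.

Amplitudes default to 150 (membrane crest), 100 (organelle), 80
(endomembrane) and 120 (marker) counts over backgrounds of 20/20/10
counts, with Poisson shot noise plus Gaussian read noise (SD 2); negative
noisy counts are clamped at zero (a sub-0.1% truncation at these levels).
These settings put the marker SNR near 10 and the F66 structures well
above the 4× background threshold, which is what the acquisition the
parameter sets describe achieved. Three RNG streams are derived from one
seed — truth draws, geometry, noise — so truths are reproducible
independently of the noise realization. Per-cell plasma-membrane and
organelle true ratios are drawn independently by default; a
`ratio_correlation` argument exists because the dispersion (not the mean)
of normalized ratios depends on the within-cell correlation, which the
printed per-compartment moments do not constrain.

What the generator does *not* emulate: the optical point-spread function,
spectral bleed-through and FRET between F66 and the markers, 3D structure
and defocus, photobleaching, or biologically realistic organelle shapes.
Passing the recovery tests therefore demonstrates that the *quantification
chain* is unbiased on data satisfying its model, not that segmentation is
robust to every optical artifact of real microscopy.

## Worked example

```{r example, eval = FALSE}
ds <- generate_experiment("skbr3", "lysosome", 20, seed = 1)
res <- analyze_dataset(ds)
head(res$measurements)

go <- analyze_dataset(generate_experiment("skbr3", "golgi", 20, seed = 2))
cmp <- compare_compartments(list(lysosome = res$measurements,
                                 golgi = go$measurements))
format_comparison(cmp)
```

Problem sizes used by the packaged validation: the acceptance script
analyzes four experiments of 100 cells at 256×256; the test suite uses 50
cells at 160×160 for parameter recovery and twenty replicate runs of four
80-cell experiments at 128×128 for the compartment-ordering check — sizes
at which the standard error of a recovered mean is a few times smaller
than the effects being checked.

## Known limitations

* Seeds are manual by design; there is no automatic cell detection.
* One organelle marker per run; no colocalization or per-organelle
  instance statistics.
* Single 2D midplane slices only; no z-stacks or time series.
* The T\*/N\* ratio is reported as-is: converting it to millivolts
  requires a calibration that is not part of the package.
* TIFF support covers plain unsigned 8/16-bit and float pages;
  vendor-specific container metadata is ignored.
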