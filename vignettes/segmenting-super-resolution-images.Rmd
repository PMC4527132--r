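---
title: "Segmenting super-resolution images by controlled Gaussian fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting super-resolution images by controlled Gaussian fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srseg)
```

## The model

Super-resolution microscopy trades the diffraction-limited point spread
function (PSF) for one an order of magnitude narrower. A structure that a
confocal image renders as one blob — a nuclear pore, a synaptic active
zone — decomposes into its constituent molecule clusters. That is the
point of the technique, and the obstacle to segmenting its images: the
pixels no longer encode which clusters belong together.

`srseg` restores that grouping *computationally and controllably*.
Convolving the image with an isotropic normalized Gaussian of width
$\sigma$ walks the effective resolution back toward the diffraction limit:
two point sources at distance $d$ fuse into a single intensity maximum
exactly when $d \le 2\sigma$, and remain two maxima otherwise. The filter
is parameterized by an *artifact diameter* $D$ (the kernel FWHM,
$\sigma = D/2\sqrt{2\ln 2} \approx D/2.355$), chosen between the
within-structure cluster spacing and the between-structure separation.
Everything downstream is ordinary object segmentation:

* **Thresholding.** Maximum Correlation Thresholding: among all distinct
  observed intensity levels $t$ (excluding the global minimum), choose the
  one maximizing the Pearson correlation between the grayscale image and
  the binary mask $I \ge t$. Ties go to the smallest $t$ (the more
  inclusive foreground). A 1 px-sigma Gaussian pre-smoothing is applied
  before threshold selection by default, and the mask is taken on the
  smoothed image — but all object measurements use the raw intensities.
* **Declumping.** Touching objects are split by a seeded watershed. For
  *fused parents* the elevation is the (1 px-sigma smoothed, negated)
  Euclidean distance transform: a fused object's internal intensity varies
  cluster-to-cluster and would over-segment, but its outline necks at true
  boundaries. For *clusters in the raw image* the elevation is the negated
  intensity, seeded at local maxima. In both cases maxima within the
  *lower-maxima suppression distance* of a higher maximum are discarded.
* **Relation.** Clusters segmented from the raw image are children;
  Gaussian-fused domains are parents. Each child goes to the parent it
  shares the most pixels with. Counts per parent, their histogram and mean
  are the readout.

The assumptions are that structures of interest are mutually separated by
more than the fusion width while their internal clusters are closer than
it; that a global threshold is meaningful (roughly uniform background);
and that both label maps come from the same image or from pre-aligned
channels — no registration is performed.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| fusion artifact diameter (donuts) | ring diameter in px (10.67 at 15 nm px) | must exceed the subunit spacing (4.1 px) and stay below the pore separation (32 px); the geometric midpoint in log terms is the ring diameter itself |
| pan-FG smoothing | 5.0 px | the value used for the central-channel stage on the real two-color data |
| MCT pre-smoothing | 1 px sigma | standard MCT practice; suppresses single-pixel threshold candidates |
| suppression distance | `"auto"` = median equivalent radius of first-pass objects | the radius of the objects being separated is the natural minimum seed spacing |
| suppression, cluster stage | 2.0 px (manual) | at the cluster stage the first-pass components are whole fused rings, so `"auto"` would resolve to the ring radius (~6.5 px), larger than the 4.1 px subunit spacing, and merge the clusters being counted. 2 px is the median equivalent radius of single-PSF clusters at the default geometry |
| donut size window | 6–60 px eq. diameter, border discarded | ring + fused PSF spans ~12–25 px; partial border pores are not countable |
| cluster size window | 1.5–12 px, border kept | single-PSF clusters span ~2–5 px; children inherit the border decision through their parents |
| bandpass cutoffs | 3 / 40 px | the classical defaults: single-pixel artifacts below, illumination gradients above |

All stage parameters are exposed in `npc_pipeline_config()` /
`az_pipeline_config()` and in the YAML config (see
`inst/extdata/npc_example.yml`).

## The bandpass convention

The bandpass is a spatial-domain difference of Gaussians,
$G(\sigma_s) - G(\sigma_\ell)$, min-shifted to zero. The cutoff diameters
are converted with the frequency-domain convention of the classical FFT
bandpass tools — 50 % amplitude transmission for structure exactly at the
cutoff size, $\sigma = d\sqrt{\ln 2/2}/\pi \approx 0.187\,d$ — *not* as
kernel FWHMs. The distinction is not cosmetic: with FWHM sigmas a
"filter small structures up to 3 px" setting becomes $\sigma_s = 1.27$ px,
which blurs clusters whose own PSF FWHM is 2.7 px past the Rayleigh limit
of their 4.1 px spacing; the ring then retains only ~5–6 of its 8 maxima
no matter how the watershed is seeded. Under the 50 %-transmission
convention ($\sigma_s = 0.56$ px) single-pixel noise is suppressed while
the 8 subunits stay countable, which is the entire purpose the filter
serves in this procedure.

## The two-impulse fusion law

The quantitative form of the fusion claim is verified against a dense
convolution oracle: for impulses at distance $d$ and artifact diameter
$D$, the smoothed profile has a single maximum iff $d \le 2\sigma =
0.849\,D$, sharp to within one pixel of the boundary over the whole sweep
$d, D \in \{2,\dots,40\}$. Note the boundary is the Gaussian *width*
$2\sigma$, not the FWHM: for $d$ between $0.85\,D$ and $D$ two shallow but
genuine maxima persist. Fusion parameters should therefore be chosen with
$2\sigma$, not $D$, compared against the spacing to be merged.

## What the simulator emulates — and what it does not

`simulate_npc_field()` renders, with exact ground truth: ring-arranged
subunit clusters (default 8 on an 80 nm-radius ring, 4° angular jitter)
as Gaussian spots of PSF FWHM 40 nm on 15 nm pixels; independent uniform
per-cluster peak amplitudes (120–220 by default) — the premise that merged
objects vary in intensity internally, which is why parents declump by
shape; one central pan-FG spot per pore in a second channel; constant
background (10) with optional Poisson resampling and Gaussian read noise
(SD 2). Defaults put neighbouring subunits ~1.5 PSF widths apart:
just resolved, the regime that motivates fusion. These physical scales are
simulator-side choices representative of the technique, not measured
constants of any instrument.

Not emulated: localization-list output, blinking/drift kinetics, aberrated
or anisotropic PSFs, structured background (nucleoplasmic haze, labeling
inhomogeneity), chromatic misalignment between channels, and partial
labeling (every simulated pore carries its full complement). Passing
recovery tests therefore demonstrate the procedure's correctness under its
own assumptions, not its performance on any particular instrument's data;
on real images the fusion diameter, size windows and suppression distances
must be re-derived from the observed geometry.

`simulate_active_zones()` is the same machinery for flat groups of small
clusters at larger mutual separation.

## Numerical conventions

* All filters use half-sample symmetric ("reflect") boundaries; with a
  normalized symmetric kernel this preserves the spatial mean exactly and
  can only contract the intensity range.
* Kernels are truncated at $4\sigma$ and renormalized.
* Connectivity is 8-connected everywhere; components are labelled in
  raster-scan order of their first pixel.
* Maxima on plateaus contribute one seed at the plateau's raster-first
  pixel. Suppression is greedy in decreasing value (ties: increasing
  raster index) and is applied *within* each connected component, so every
  component keeps at least one seed and declumping can only split objects,
  never lose them.
* The seeded watershed floods by increasing elevation with FIFO tie-break,
  so identical inputs give identical label maps.
* Coordinates in tables are 0-based (row, col); CSV output is comma-
  separated, UTF-8, `.` decimal, LF line endings, ≥ 6 significant digits.
* Degenerate inputs: a constant image cannot be thresholded (error); an
  empty mask declumps to an empty label map; an empty parent set flags
  `zero_parents` instead of raising; a constant image rescales to the
  lower bound with a warning.
* One integer seed drives every stochastic draw of a simulation in
  documented order, and the simulator restores the caller's RNG state.

## Design choices where the design was open

* *Overlap, not centroid containment, for relation.* A ring-shaped
  parent's central hole is background; a central child's centroid would
  fall outside every parent. Maximal pixel overlap is robust to exactly
  this geometry. Ties go to the smaller parent label.
* *Fixed donut segmentation in preprocessing comparisons.*
  `compare_preprocessing()` re-runs only the cluster stage per variant.
  On real data donut segmentation was observed to be insensitive to
  preprocessing; fixing it removes that confound by construction, so
  histogram differences are attributable to the cluster stage alone.
* *Distance-transform smoothing (1 px sigma) before shape-declump seeding*
  avoids plateau artifacts of discretized discs.
* *Candidate thresholds = observed intensity levels*, not fixed bins:
  bit-depth agnostic and exactly verifiable by brute force.
* *Measurements on raw intensities* even though masks come from smoothed
  images: the quantities of interest belong to the original image.

## Known limitations

* A global MCT threshold always exists: on structure-free *dense* noise
  the pipeline reports spurious donut-scale objects (fused noise genuinely
  contains blobs in the size window). Only sparse speckle noise is cleanly
  emptied by the size filter. Inspect fields with implausible object
  counts rather than trusting them.
* Mild smoothing (3×3 mean) sits in an unhappy middle at the default
  simulated geometry: too weak to stop over-segmentation at high noise,
  strong enough to merge just-resolved subunits — its histogram modes run
  1–2 low. The comparison operation exists to make such effects visible.
* Heavily overlapping structures (pore separation below the fusion width)
  merge into one parent; the procedure counts clusters per *merged*
  domain without warning.
* 2D only; no propagation/secondary objects; no sub-pixel localization.

## Problem sizes

Recovery checks in the test suite run on 320 px fields of 20 pores; the
headline end-to-end checks and the acceptance script use the full study
condition of 512 px fields with 60 pores, which segment in about two
seconds each.
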