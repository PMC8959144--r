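---
title: "Quantifying corticopontine and corticospinal projections on atlas-registered sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying corticopontine and corticospinal projections on atlas-registered sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ponsquant)
```

## The analysis problem

Transgenic reporter mice (e.g. Thy1-eYFP-H) label layer V pyramidal
neurons and their descending axons. After serial sagittal sectioning,
fluorescence imaging, and registration of each section to a reference
atlas (CCFv3), three quantitative questions arise:

1. **Where are the labelled cell bodies?** Counting YFP+ somata per
   cortical area, per section, across animals and genotypes.
2. **What do the descending tracts look like?** Dorso-ventral width of
   the corticospinal tract at defined medio-lateral levels, the area
   under the lateral-to-medial width curve, and how tightly the fibres
   fasciculate caudal to the pontine nuclei.
3. **Where do corticopontine axons terminate in 3D?** Semi-quantitative
   point clouds recorded from serial sections, inspected through digital
   slab slices and compared between groups.

`ponsquant` implements these three pipelines, the histogram-matching
intensity normalization that makes signal comparable across animals, the
associated ANOVA statistics, and a synthetic-data generator that plants
known ground truth through all of them. Nonlinear section-to-atlas
registration is out of scope: inputs are assumed registered (external
tools such as QuickNII/VisuAlign produce the paired atlas plates).

## Atlas-masked soma counting

Each registered section is paired with a colour-coded atlas plate. The
pipeline in `count_section()` is:

1. **ROI extraction** (`extract_rois()`): exact RGB matching of each
   plate pixel against the colour lookup table. Plates are label images,
   not photographs, so matching uses zero tolerance; unmapped colours
   are collected into an `unassigned` mask and reported, never fatal.
   Masks are pairwise disjoint by construction.
2. **Background subtraction** (`subtract_background()`): grayscale white
   top-hat with a disk structuring element (default radius 15 px),
   the morphological equivalent of rolling-ball background subtraction.
   The disk radius must exceed the soma radius (a factor ≥ 3 is safe);
   flat background maps to ~0 and blobs smaller than the disk survive.
3. **Detection** (`detect_objects()`): global intensity threshold
   (explicit value, or Otsu), then 8-connected component labelling.
   Per object: area, boundary-following perimeter (Moore contour, axis
   steps 1, diagonal steps √2; isolated pixels get perimeter 4),
   circularity `4πA/P²` clamped to ≤ 1 (rasterization can push the raw
   ratio above 1), and mean intensity.
4. **Shape gate** (`filter_by_circularity()`): keep circularity in
   [0.5, 1], the conventional range that accepts compact somata and
   rejects elongated fibre fragments. An optional `min_area` (in the
   spirit of particle-analysis size ranges) rejects 1–2-pixel specks,
   which are otherwise near-circular by construction: with additive
   noise the top-hat output has an elevated mean (the opening follows
   the lower noise envelope), and isolated suprathreshold pixels can
   appear at blob rims.
5. **Assignment** (`count_per_region()`): each object goes to the region
   containing its centroid pixel; centroids on background count into the
   `unassigned` bucket, so bucket totals always conserve the object
   count.

Two normalizations (`normalize_counts()`) mirror common reporting:
counts per region divided by the number of sections analysed per animal,
and motor/somatosensory counts expressed as percentages of their sum
(`%M + %S = 100` exactly).

### Threshold choice

The threshold is deliberately a single global scalar. Otsu is offered as
an automatic default, but on sparse fluorescence images (signal pixels
≪ background pixels) Otsu can land inside the noise; for quantitative
counting we recommend an explicit threshold calibrated on a
representative section, placed well above the corrected-background tail
(about half the typical soma peak works well — on the synthetic
fixtures, 0.6 × blob peak with noise at 10% of the peak gives exact
recovery in all 140 region-cells tested).

## Tract morphometry

`width_at_column()` measures, in a binarized sagittal image at a given
column: the **total width** (first to last signal row, inclusive), the
**fibre width** (number of signal rows) and the **gap width**
(total − fibre). All arithmetic is integer pixel counting before the
micrometre conversion, so `fibre + gap = total` holds exactly.
`profile_series()` repeats this across a lateral-to-medial series at
labelled columns (e.g. rostral and caudal to the pontine nuclei);
`area_under_profile()` integrates a profile trapezoidally over the
medio-lateral positions. The **fasciculation index**
(`fasciculation_index()`) is fibre/total: 1 for a single compact bundle,
lower when gaps open between fascicles. The phrase "ratio of total and
fibre width" does not by itself fix the orientation; fibre/total was
chosen so that *lower index = less fasciculated*, and the reciprocal is
available via the `orientation` argument. Offsets of 250 and 500 µm
caudal to the pontine nuclei are converted to columns with
round-half-away-from-zero; an optional ±k-column median makes single
measurements robust to one-column noise.

## 3D point clouds

`record_points()` converts a per-section density map into points: each
pixel emits a Poisson number of points with rate proportional to local
density, placed uniformly within the pixel — the "semi-quantitative"
recording convention in which point density reflects observed labelling
density. Density classes are ordinal (1..3 by default).

`jitter_z()` displaces each point's z uniformly within the
inter-section gap (default centred, `(−gap/2, +gap/2)`; a `forward`
mode, uniform on `[0, gap)`, covers the alternative reading of
"within the gap"). x, y, ordering and labels are preserved bit-exactly,
and gap = 0 is the identity.

`slice_points()` cuts digital slabs (default thickness 100 µm) with
half-open membership `[centre − t/2, centre + t/2)`, so slabs tiling an
axis partition the cloud exactly. Axis convention throughout: x
increases rostral → caudal, y dorsal → ventral, z left → right; all I/O
column names carry explicit `_um` suffixes to prevent silent axis flips.

`centroid_shift()` quantifies group displacement as the difference of
centroids with a seeded percentile-bootstrap CI (default 1000
resamples); `density_overlap()` compares voxelized, unit-normalized
densities by histogram intersection within a region volume. Note the
intersection estimator is biased downward when voxel counts are small;
choose voxels coarse enough for tens of points per occupied voxel.

## Intensity normalization

`build_histogram_map()` implements discrete CDF matching: source level
`s` maps to the lowest reference level whose cumulative mass reaches the
source CDF at `s`. The lookup is monotone non-decreasing (pixel ranks
are preserved; ties may merge), and reapplying the same reference is
exactly idempotent. After matching, the maximum CDF discrepancy against
the reference is bounded by the quantization step plus the largest
occupied bin mass of the two histograms; for images whose mass is spread
over many levels this is ≈ 1/256 + max reference bin on 8-bit data.

## Group statistics

`two_way_anova()` fits `value ~ genotype * region` and reports Type II
sums of squares — appropriate for the unbalanced animal numbers typical
of mutant cohorts (e.g. 6 controls vs 4 mutants) — with classical
pooled-MSE pairwise genotype contrasts within each region,
Bonferroni-adjusted over the full family of contrasts in the analysis
(the family size is recorded in the result). `one_way_anova()` does the
same across groups; with two groups its F equals the squared pooled t.
Significance tiers follow the conventional `*P<0.05`, `***P<0.005`
markers. Degenerate inputs (all values identical) report F = 0, p = 1
rather than floating-point noise. The analysis unit is whatever rows
you pass: per-animal aggregates are the default recommendation (section
counts from one animal are not independent); per-section analyses are
possible but conflate within- and between-animal variance.

## The synthetic-data generator

The generator is first-class, tested code; every downstream stage is
validated against its planted truth.

* **Sections** (`make_section_set()`): seven vertical-strip regions
  emulate the rostro-caudal sequence of cortical areas on a lateral
  sagittal section (PFC, M, S, A, V, RSC, GC). Planted cells are
  isotropic Gaussian blobs truncated at the nominal radius (3σ), peak
  30 000 on a 16-bit scale over background 2000 — the simplest model
  that yields near-unity circularity after thresholding. Centres are
  dart-thrown with a global ≥ 2r + 1 px separation so detected
  components map one-to-one onto planted cells (exact count oracle);
  overfull regions raise an error rather than silently overlapping.
  Additive Gaussian noise is clipped to the bit range. Defaults follow a
  control-like graded count profile with motor/somatosensory dominance;
  a flat profile emulates a gradient-flattened mutant.
* **Tracts** (`make_tract_image()`): fascicles are per-column row
  intervals, validated disjoint; ground-truth total/fibre/gap widths are
  computed analytically from the interval lists, making every
  morphometric quantity exactly checkable.
* **Clouds** (`make_pointclouds()`): Gaussian clusters inside a
  voxelized ellipsoid standing in for the pontine nuclei (semi-axes
  600 × 400 × 500 µm), sampled by rejection so all points lie inside the
  volume; z is snapped to 100 µm section planes inside the rejection
  loop (so membership holds for the returned coordinates), emulating
  recording from serial 2D sections. The "mutant" group is the same
  generative process translated by a known shift, resampled under the
  same seed policy; shifts too large for the volume raise an error.

What the generator does **not** emulate: autofluorescence and vascular
artefacts, anisotropic or clumped somata, intensity falloff across
sections, registration error between image and plate, and non-Gaussian
noise. Passing tests therefore demonstrate correctness of the
computations under controlled conditions, not robustness to every
property of real micrographs; the threshold/size-gate discussion above
is where real-data judgement enters.

## Numerical choices and problem sizes

* Determinism: every stochastic function takes a seed and uses it
  locally (the caller's RNG state is untouched); identical spec + seed
  reproduce outputs bit-exactly.
* Validation scales (chosen to exercise the estimators meaningfully):
  20 seeded section sets (7 regions × 10–200 cells, noise 10% of peak)
  for count recovery; 10⁴-point clouds with 1000-resample bootstraps and
  100 coverage replicates for shift recovery; 10⁴ null simulations for
  ANOVA calibration; synthetic cohorts of 6 control + 4 mutant animals,
  4 sections each, for the end-to-end group comparison.
* Ties and edges: slab membership half-open; centroid assignment is a
  single pixel (no tie possible); circularity clamped at 1; empty
  columns yield zero widths; zero total width yields a missing
  fasciculation index; zero M+S denominators are explicit errors naming
  the animal.

## Known limitations

* Counting assumes somata are resolvable compact blobs; touching cells
  are counted as one (an optional maxima-splitting step is deliberately
  not enabled by default, keeping the detector deterministic and
  oracle-checkable).
* Straight-column width measurement, as in the original drawings; the
  tract is not re-parameterized along its curvature.
* `density_overlap()` is a descriptive score, not a test statistic.
* The ANOVA helpers do not model within-animal correlation of sections;
  aggregate per animal first.
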