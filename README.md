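# ponsquant

Quantitative neuroanatomy of corticopontine and corticospinal
projections on atlas-registered serial brain sections.

Transgenic reporters such as Thy1-eYFP-H label layer V pyramidal
neurons and their descending axons. Once serial sagittal sections are
registered to a reference atlas (CCFv3), `ponsquant` answers three
questions quantitatively:

* **Where are the labelled somata?** Automatic counting per
  colour-coded cortical area: grayscale white top-hat background
  subtraction, global intensity thresholding, 8-connected particle
  detection with a circularity gate (`4πA/P²` in `[0.5, 1]`), and
  centroid-based assignment to atlas ROIs, with per-section and
  motor/somatosensory-percentage normalizations.
* **How do the descending tracts behave?** Dorso-ventral width profiles
  of the corticospinal tract at labelled medio-lateral levels, the
  trapezoidal area under the width curve, and the **fasciculation
  index** `fibre width / total width` at 250 and 500 µm caudal to the
  pontine nuclei (1 = compact bundle, lower = defasciculated).
* **Where do corticopontine axons terminate in 3D?** Semi-quantitative
  point recording proportional to labelling density, uniform z-jitter
  within the inter-section gap, ~100 µm digital slab slices with exact
  half-open tiling, centroid-shift estimates with bootstrap CIs, and a
  voxelized density-overlap score.

Histogram-matching intensity normalization (discrete CDF matching
against a representative reference case) and the group statistics used
with such data (one-/two-way ANOVA, Type II sums of squares, Bonferroni
pairwise contrasts) are included. A synthetic-data module generates
sections, tract images and point clouds with *planted ground truth*, so
the entire pipeline is testable end to end without any imaging data.

Section-to-atlas registration itself is out of scope; inputs are assumed
registered (QuickNII/VisuAlign-style tools produce the paired plates).

## Worked example

Generate a synthetic two-section animal with a known graded count
profile, run the counting pipeline, and normalize motor (M) vs
somatosensory (S) counts:

```r
library(ponsquant)

spec <- cortical_section_spec(
  planted_counts = c(PFC = 12, M = 40, S = 28, A = 18, V = 14,
                     RSC = 8, GC = 10),
  n_sections = 2, noise_sd = 1500, seed = 7)
ss <- make_section_set(spec)

counts <- do.call(rbind, lapply(1:2, function(i)
  count_section(ss$images[[i]], ss$plates[[i]], ss$region_map,
                threshold = 18000, min_area = 2)))
counts$animal_id <- "demo"; counts$genotype <- "control"
counts[counts$section_index == 1, ]
#>   section_index  region_id raw_count animal_id genotype
#> 1             1        PFC        12      demo  control
#> 2             1          M        40      demo  control
#> 3             1          S        28      demo  control
#> 4             1          A        18      demo  control
#> 5             1          V        14      demo  control
#> 6             1        RSC         8      demo  control
#> 7             1         GC        10      demo  control
#> 8             1 unassigned         0      demo  control

normalize_counts(counts, "MS_percentage")
#>   animal_id genotype region_id count      pct
#> 1      demo  control         M    80 58.82353
#> 2      demo  control         S    56 41.17647
```

Every planted count is recovered exactly despite noise at 5% of the
blob peak; the M area holds 58.8% of the M+S total, the control-like
motor dominance the generator plants.

A defasciculated tract (four 8-px fascicles spread over 155 µm) scores
well below the compact-bundle index of 1 at both caudal offsets:

```r
tr <- tract_spec(c(200L, 400L),
                 fascicles = lapply(c(90, 108, 126, 144),
                                    function(t) list(top = t, bottom = t + 7)),
                 measurement_columns = c(c250 = 200, c500 = 300),
                 pixel_size = 2.5)
img <- make_tract_image(tr)$image
fasciculation_at_offsets(img, reference_column = 100)
#>   offset_um column total_width fibre_width gap_width fasciculation_index
#> 1       250    200         155          80        75            0.516129
#> 2       500    300         155          80        75            0.516129
```

See `vignettes/methods.Rmd` for the models, parameter choices and
limitations.

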