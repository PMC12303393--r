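---
title: "Quantification methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods and design notes}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wingquant)
```

wingquant quantifies confocal fluorescence readouts of epithelial tissue —
membrane/cytoplasm partitioning, colocalisation, nuclear puncta and
levels, apoptotic area — and the gene-set statistics used to compare
differential-expression experiments. This vignette documents the models
behind each stage, the parameters that matter, the numerical conventions,
what the synthetic-data generators do and do not emulate, and the design
choices that were genuinely open.

## Membrane/cytoplasm partitioning

A junction skeleton — a 1 px binary network tracing cell–cell boundaries,
produced by external junction segmentation — defines the cells: every
4-connected region of non-skeleton pixels is a candidate cell.
4-connectivity is essential, since a 1 px 8-connected skeleton line does
not 4-separate its two sides but does block 4-paths; with 8-connected
labelling, diagonal junction pixels would leak neighbouring cells into
one another. Regions smaller than `min_cell_area_px` (default 20 px,
segmentation specks) are dropped, and regions touching the image border
are dropped by default because a cropped field truncates them.

Each cell's perimeter (region pixels 4-adjacent to the outside, or on the
image border) is dilated by a city-block ball — the "diamond" structuring
element — of radius `dilation_radius_px` (default 3). The dilated band is
the membrane compartment; the region minus the band is the cytoplasm. The
band deliberately extends onto the skeleton and into neighbouring cells
so that it captures the full lateral spread of the junctional signal;
membrane masks of adjacent cells therefore overlap, and each cell is
measured independently. Cells whose cytoplasm is consumed entirely by the
dilation are flagged and excluded from summaries. Disc-level values are
unweighted means over cells, so large cells do not dominate, and the
headline readout is the ratio of the disc-level cytoplasm and membrane
means.

The radius parameterises the half-width of the band measured from the
perimeter. We read "a diamond-shaped structuring element of size 3" as a
radius-3 L1 ball (the common convention parameterises structuring
elements by radius); the alternative reading, a 3×3 footprint, is
available as `radius = 1`.

## Colocalisation: MCC_diff

Channels are binarised with the iterative-intermeans (isodata) threshold
and co-positivity is the logical AND of the two binary stacks. With
`A⁺`, `B⁺` the positive sets of the query and partner channel,

- `mcc_pct = 100 · |A⁺ ∩ B⁺| / |A⁺|` — the percentage of query-positive
  pixels that are also partner-positive;
- `baseline_pct` — the value expected under random colocalisation;
- `mcc_diff_pct = mcc_pct − baseline_pct`.

Two baselines are implemented. Under independent placement the expected
value of `mcc_pct` is exactly the partner channel's positive fraction, so
`partner_fraction` is the default (a correctly calibrated null: MCC_diff
has expectation 0 for independent channels). The `query_fraction`
baseline — the query channel's own positive fraction — reproduces the
study convention this statistic descends from and is retained as an
option; both interpretations give identical results when the two
channels have equal positive fractions.

The whole-stack variant thresholds each channel once, on a caller-chosen
section (conventionally the section in the middle of the border signal),
and applies the thresholds stack-wide. Because "middle of the border
signal" was a by-eye choice in the original procedure, the section index
is a parameter; `suggest_border_section()` offers an optional heuristic —
the slice maximising the skeleton-masked mean — clearly labelled as an
extension. The cytoplasm-only variant works section by section: each
section is thresholded independently, pixels within a city-block
dilation (default radius 3) of the junction skeleton are excluded, and
sections with no query-positive cytoplasmic pixel are skipped. Per-section
values are aggregated by unweighted mean by default (pixel-pooled
aggregation is available); the two variants coincide for a single-section
stack with an empty skeleton.

Inference against zero uses the classical one-sample t test on
per-sample MCC_diff values (df = n−1), refusing fewer than two values or
zero variance.

## Nuclear readouts

**Puncta.** The projection is smoothed with a Gaussian kernel
(`gaussian_sigma_px`, default 2), binarised against a local-mean adaptive
threshold, labelled with 8-connectivity (the usual choice for bright
blobs), and filtered: components below `min_punctum_area_px` (default
200 px, in pixels exactly as specified — the floor is therefore
calibration-dependent) or touching any image border are removed. Punctum
mean intensities are measured on the unsmoothed image.

The adaptive rule marks a pixel foreground when its smoothed value
exceeds `(2 − sensitivity)` times the local mean over a square window
(odd side, default the nearest odd number to one-eighth of the smaller
image dimension). The factor mapping was chosen so that at the default
`sensitivity = 0.5` the cutoff is 1.5× the local mean, which for a
punctum roughly twice as bright as its nucleus places the cut near the
half-maximum of the Gaussian-blurred edge — the point where the detected
footprint equals the true footprint. The default was then calibrated on
synthetic nuclear scenes so that detected areas track designed areas with
near-zero bias; this mirrors the empirically-determined settings such
procedures use on real data, where the exact window and sensitivity are
tuned per staining. Two regimes break the rule and are worth knowing
about: a blob filling the local window raises its own threshold and
disappears (the window must be comfortably larger than the largest
punctum), and a step edge brighter than `(2 − sensitivity)×` its
surroundings fires the detector (nucleus rims on a very dark background
do this; on real stainings the extranuclear background is rarely that
dark, and the synthetic scenes use a background at half the nuclear
level accordingly).

**Per-nucleus means** are computed over externally supplied label maps
(e.g. CellPose output); a nucleus segmentation of its own is out of
scope.

**Region levels and N/C ratios.** For average nuclear levels, each
image's foreground is the set of pixels strictly above
`background_fold ×` its measured background (default 2×), or an
explicitly supplied mask — the mask-based route mirrors the procedure of
defining the mask on the control region's signal and applying it to both
regions. The level is `(expr_in − expr_out) / (ctrl_in − ctrl_out)`:
subtracting the outside mean is the background correction, dividing by
the control region normalises staining strength. The N/C ratio readout
forms `inside/outside` per region and divides the expressing by the
control ratio. Degenerate cases — empty or full foreground, control
difference ≤ 0 — are errors, never silent zeros.

## Apoptosis scoring

The projection is smoothed with the 3×3 mean filter, thresholded strictly
above `2 × background` (the background is measured by the caller on the
raw projection, in a signal-free region — automating its placement is
deliberately not attempted), and 8-connected particles are counted within
a caller-traced ROI. Particles are clipped to the ROI before the size
test, so edge-straddling particles count only their inside pixels;
particles of at least `min_particle_area_um2` (default 4 µm², converted
through the pixel size) qualify, and the score is the percentage of ROI
pixels they cover.

## Gene-set statistics

DE calls follow the standard rule: `up` iff adjusted p < α (default
0.05) and log2FC > cutoff (default 1); `down` symmetrically; otherwise
`ns`. Missing adjusted p-values (independent-filtering artefacts) give
`ns` and are never dropped silently.

Overlap significance is the exact hypergeometric upper tail
`P(X ≥ k)` computed via R's log-space CDF. The universe defaults to the
genes present in both tables — the mapped, tested genes — because the
universe behind any externally computed overlap probability is rarely
recoverable; published overlap p-values are therefore not reproduction
targets, and any explicit universe can be supplied. Direction consistency
is the fraction of shared significant genes whose fold changes agree in
sign, and concordance is the squared Pearson correlation of the two log2
fold changes over shared significant genes (Spearman optional). An empty
overlap leaves consistency and r² undefined (`NA`), not zero. Three-way
Venn region counts are derived set-theoretically; no proportional-area
graphics.

## Numerical conventions

- **Isodata threshold**: 256 equal bins spanning [min, max]; initial
  threshold the global mean; iterate T ← (mean below + mean above)/2 on
  bin centres until successive values differ by less than half a bin
  width; ties at a bin boundary fall to the lower class. Constant images
  are an error (no threshold exists). The result is invariant under
  adding a constant to the image up to one bin width.
- **3×3 smoothing** averages over in-bounds neighbours only at edges and
  corners; no padding value is invented, so constants are fixed points
  and the output never leaves the input range.
- **Strict inequalities** at thresholds: a pixel exactly at
  `fold × background` is excluded (the boundary case is unspecified in
  the source procedures; strictness is the documented choice).
- **Exactness**: compartment totals on integer images are conserved
  exactly (sums of doubles of integers); closed-form checks are asserted
  to 1e-12; floating-point linearity properties to 1e-9.
- ROI membership uses pixel centres; polygon boundaries count as inside.

## The synthetic scenes

The generators exist to give every stage a parameter-recovery test with
known ground truth; they emulate the *structure* of the real data, not
its biology.

**Epithelium scenes** build a relaxed-Voronoi lattice (jittered grid
seeds, two Lloyd iterations), draw the shared boundaries as a 1 px
skeleton, and paint membrane and cytoplasm intensities. Two regimes:
the default paints the junctional signal on the 1 px skeleton itself
(the thin-junction regime of real membrane stainings); the band regime
(`membrane_halfwidth_px` equal to the measurement dilation radius) paints
the membrane with exactly the per-cell perimeter-dilation geometry the
measurement uses, which is what makes the noise-free cytoplasm:border
round trip exact. Vesicles are uniform in the cytoplasm; each query
vesicle receives a partner vesicle at the same site with probability
`coloc_rho`, otherwise the partner lands uniformly anywhere in the
cytoplasm — independent placement, so `coloc_rho = 0` is a genuine
independence null for MCC_diff (pairing partner vesicles within the
query's cell would correlate counts and bias the null upward). Stacks
apply a multiplicative axial envelope peaking at the middle slice (the
junctional plane in focus), then an isotropic Gaussian PSF and mixed
Poisson–Gaussian noise. Ground truth records the skeleton, label maps,
design intensities, vesicle table with the realised colocalised
fraction, and the noise-free post-PSF stacks.

Default geometry: 256 × 256 px at 0.06 µm/px with 9 cells — apical
domains of roughly 5 µm, many PSF widths across. The size matters: with
much smaller cells, PSF spill past the radius-3 membrane band
contaminates a large fraction of the cytoplasm and biases the recovered
ratio well beyond what the dilation is designed to absorb; the chosen
scale is the regime in which a radius-3 dilation genuinely encompasses
the lateral spread, matching the logic of the measurement itself.
Colocalisation tests use 128 px / 9-cell scenes, and the test suite
states its problem sizes (20–50 seeds per property) in the test files.

**Nuclear scenes** split the field into an expressing left half and a
control right half, with disk nuclei (radius 40 px ≈ 5 µm) on a jittered
grid. Expressing nuclei carry
`background + expr_factor · (nucleus_intensity − background)`, so the
background-subtracted, control-normalised level is `expr_factor` by
construction. Puncta are compact regions of exactly `punctum_area_px`
pixels (nearest-pixel blobs, ties broken in raster order) with a fixed
intensity added on top of the nuclear level. The extranuclear background
defaults to half the nuclear level so that nucleus rims stay below the
adaptive-threshold cutoff, as discussed above.

**DE-table pairs** are fixture generators, not simulations of count-based
inference: a designed fraction of the smaller DE set shares its signed
effect between the two tables, remaining DE genes get independent
effects in disjoint blocks, observed log2FC is effect plus Gaussian
noise, and adjusted p-values are assigned deterministically from effect
rank so that exactly the designed genes fall below α. Effect magnitudes
span 0.75–1.5 × `lfc_scale` (default 2), keeping designed effects above
the call cutoff with margin. The truth record includes the exact
per-gene expected sign-agreement probability under the noise model, so
recovered consistency can be checked against its binomial interval.
Defaults emulate the scale of the study's comparisons (12,956 genes, DE
fractions 0.145 and 0.318, shared fraction 0.47).

What the generators do **not** emulate: real junction geometry and its
segmentation errors, z-dependent PSFs and optical aberrations, bleaching
and flat-field structure, nuclear texture, or count-based DE inference
(dispersion, shrinkage, independent filtering). Passing tests therefore
demonstrate that the measurement code recovers known parameters under
controlled corruption — not that any particular biological claim holds
on real images.

## Known limitations

- The pipeline consumes finished junction skeletons, nucleus label maps
  and DE tables; segmentation and DE model fitting are out of scope.
- The puncta detector's window/sensitivity must be tuned per staining,
  as in the procedure it reproduces; its defaults are calibrated for the
  synthetic scenes' contrast regime.
- The 200 px punctum floor is a pixel count, not a physical area.
- Overlap p-values depend strongly on the chosen universe; compare them
  only within a fixed universe convention.
- `read_stack` trusts caller-supplied calibration, not TIFF tags; 32-bit
  TIFFs are exchanged on an explicit max-value scale.
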