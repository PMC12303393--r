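# wingquant

Quantification of confocal fluorescence readouts in epithelial tissue such
as the *Drosophila* wing imaginal disc, together with the gene-set
statistics used to compare RNA-seq experiments. The package turns the
bespoke per-study measurement scripts of this kind of work into a tested,
reusable pipeline, and ships a synthetic-scene generator with full ground
truth so every stage can be validated without microscopy data.

## What it measures

**Membrane vs cytoplasm partitioning.** Given a 1 px junction-skeleton
mask (from external junction segmentation), every 4-connected inter-
junction region is a cell; the cell's perimeter dilated by a city-block
("diamond") ball of radius *r* (default 3) is its membrane compartment and
the remainder its cytoplasm. Mean and total intensities per compartment
are averaged, unweighted, over cells to give per-disc values and the
cytoplasm:border ratio.

**Colocalisation (MCC_diff).** A Manders-style coefficient on channels
binarised with the isodata ("Default") threshold:

    MCC      = 100 · |A⁺ ∩ B⁺| / |A⁺|
    MCC_diff = MCC − baseline,

where the baseline is the co-positivity percentage expected under random
overlap (by default the partner channel's positive fraction, the exact
independence expectation). A whole-stack variant thresholds on the
mid-border section; a section-by-section variant excludes a dilated
border zone and measures intracellular signal only. Per-sample MCC_diff
values are tested against zero with a one-sample t test.

**Nuclear readouts.** Per-nucleus means over external label maps;
H3K9me3-style puncta by Gaussian smoothing (σ = 2 px), local-mean adaptive
thresholding, and filtering of components below 200 px or touching the
border; background-subtracted, control-normalised region levels
`(expr_in − expr_out)/(ctrl_in − ctrl_out)`; and normalised
nuclear/cytoplasm ratios.

**Apoptosis.** Cleaved-Dcp-1 staining smoothed 3×3, thresholded at 2×
background, and scored as the percentage of a traced ROI covered by
particles of at least 4 µm².

**Gene-set statistics.** DE calls at FDR < 0.05 and |log2FC| > 1, exact
hypergeometric upper-tail probabilities for overlap and enrichment,
direction-consistency fractions and r² of log fold changes between
experiments.

## Worked example

Generate a synthetic epithelium (membrane painted at 200, cytoplasm at 40,
so the true cytoplasm:border ratio is 0.2; 1 px PSF and Poisson-Gaussian
noise), then run the partition pipeline on it:

```r
library(wingquant)

params <- scene_params(n_cells = 16, membrane_halfwidth_px = 3,
                       vesicle_density = 0, seed = 7)
scene  <- make_epithelium_scene(params)

cells     <- label_cells(scene$truth$skeleton)       # border cells excluded
partition <- build_partition(cells, radius = 3)
partition
#> <wq_partition> 4 cells (0 flagged), radius 3, 256 x 256 px

tab <- measure_partition(average_projection(scene$query), partition)
tab
#> <wq_intensity_table> 4 cells; border mean 114.9, cyto mean 26.53, ratio 0.2309
head(tab$cells[, c("cell_id", "membrane_mean", "cytoplasm_mean")])
#>   cell_id membrane_mean cytoplasm_mean
#> 1       1        114.88          26.63
#> 2       2        114.94          26.42
#> 3       3        114.85          26.35
#> 4       4        115.03          26.72
```

The absolute means carry the axial intensity envelope of the stack
(everything is scaled by the mean slice weight), but the ratio is
envelope-free: the recovered 0.231 sits within 15% of the true 0.2, the
residual bias being PSF spill past the membrane band. With the PSF and
noise switched off the recovery is exact.

Colocalisation on a vesicle scene with a 50% co-placement probability:

```r
sc  <- make_epithelium_scene(scene_params(size = 128, n_cells = 9,
                                          vesicle_density = 3,
                                          coloc_rho = 0.5, seed = 7))
mcc_diff_cytoplasm(sc$query, sc$partner, sc$truth$skeleton, radius = 3)
#> <wq_mcc> cytoplasm_only: MCC 54.48%, baseline 5.56% (partner_fraction), MCC_diff 48.93%, n+ = 6080
#>   8 sections used, per-section MCC_diff mean 48.93%
```

About half of the query-positive cytoplasmic pixels carry partner signal,
against a 5.6% random-overlap baseline.

Batch runs are driven by a YAML config (`run_config()`, or
`Rscript inst/scripts/wingquant.R config.yaml`), with stages `partition`,
`coloc`, `apoptosis`, `puncta`, `nuclei`, `concord`, `enrich` and
`simulate`; every output CSV embeds the parameter set used.

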