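# mcquant

Computer-aided quantification of mast cells in immunohistochemically
stained skin sections.

Mast cells (MC) accumulate around cutaneous T-cell lymphoma (CTCL)
infiltrates, and both their density and their activation state
(degranulated vs. non-degranulated) are of pathophysiological interest.
Counting them by eye is slow and irreproducible, and their spatial
relation to the tumour — inside the infiltrate, in its immediate
vicinity, or in distant dermis — is lost in a manual count. `mcquant`
implements a full image-analysis pipeline for brightfield sections
stained with an anti-tryptase antibody (red AEC chromogen) on a
hematoxylin counterstain, for pathologists and image-analysis groups who
want per-region MC statistics from calibrated RGB scans.

## Method

Given an RGB image with calibration *s* (µm/pixel, default 0.275 at 20×):

1. **Stain separation.** Each pixel is mapped to optical density,
   OD_c = −log10((I_c + 1)/(I0_c + 1)), and unmixed by color
   deconvolution: with unit stain vectors **h** (hematoxylin) and **t**
   (AEC), the OD vector is decomposed in the basis (**h**, **t**,
   **h**×**t**), giving concentration maps H and T.
2. **Nuclear segmentation.** Cells are detected on H inside the dermis:
   Gaussian smoothing, Otsu threshold, hole filling, watershed splitting
   on the Euclidean distance map, and a 3–20 µm equivalent-diameter gate.
3. **Infiltrate extraction.** Local cell density λ(x) is estimated by the
   Parzen window method — a Gaussian kernel (σ = 25 µm) integrating to one
   cell placed on every centroid, expressed in cells/mm². The CTCL
   infiltrate is the regularised region with λ ≥ ρ_min (default
   4000 cells/mm²); a user-supplied mask can replace it.
4. **Proximity bands.** From the Euclidean distance transform of the
   infiltrate, P1 = (0, 30] µm and P2 = (30, 60] µm outside the
   infiltrate, restricted to dermis (epidermis is excluded throughout).
5. **Mast-cell detection.** Blobs on T (8-connected components above an
   Otsu/0.15-OD threshold) are grouped by single-linkage clustering
   (12 µm). A cluster is one mast cell: a single large compact blob
   (area ≥ 40 µm², solidity ≥ 0.8) is *non-degranulated*; any fragmented
   or ragged cluster is *degranulated*.
6. **Statistics.** Per region (CTCL, P1, P2): area, total cells, MC
   count, MC/mm², MC as % of total cells, and degranulated MC as % of all
   MC. Cohort contrasts use the Wilcoxon matched-pairs signed-rank test
   (paired, e.g. P1 vs P2 within samples) and the Mann–Whitney U test
   (unpaired, e.g. early vs advanced stage), exact by enumeration at
   small n, with p < 0.05 two-sided called significant.

A synthetic-image generator (`scene_spec()`, `generate_sample()`,
`synth_cohort()`) renders IHC-like scenes with exhaustive ground truth —
epidermal band, dense infiltrate, both MC morphologies — through the same
Beer–Lambert model the analysis inverts, so every stage is testable
without any slide data.

## Worked example

```r
library(mcquant)

spec <- scene_spec(seed = 42)          # synthetic biopsy, 0.704 x 0.704 mm
smp  <- generate_sample(spec)
res  <- run_sample(smp$image, run_config(um_per_px = 2))
res
#> <sample_run> synthetic: 1230 cells, 77 mast cells
#>   region area_mm2 total_cells mc_count mc_per_mm2 mc_pct_of_cells
#> 1   CTCL 0.121916         776       38  311.69002        4.896907
#> 2     P1 0.040320          86        9  223.21429       10.465116
#> 3     P2 0.046216          57        4   86.55011        7.017544
#>   pct_degranulated
#> 1         42.10526
#> 2         11.11111
#> 3          0.00000
```

The infiltrate covers 0.122 mm² and holds 38 mast cells (312 MC/mm²,
4.9 % of its 776 nucleated cells, 42 % of them degranulated); density is
similar in the inner band P1 and drops sharply in the outer band P2 —
the spatial pattern the generator planted. A paired cohort contrast:

```r
wilcoxon_signed_rank(c(231, 205, 188, 301, 177, 290),
                     c(160, 170, 140, 242, 181, 201))
#> Wilcoxon signed-rank: statistic = 1, p = 0.0625 (exact), n = 6
```

From the shell, the same pipeline is available as a CLI:

```sh
mcquant=$(Rscript -e 'cat(system.file("exec", "mcquant", package = "mcquant"))')
Rscript $mcquant synth demo --n 20 --seed 1
Rscript $mcquant run-cohort demo/manifest.csv --out demo_out \
    --contrast paired:P1:P2,group:stage=IA|IB:stage=IIA|IIB
```

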