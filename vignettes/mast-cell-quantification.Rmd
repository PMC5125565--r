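---
title: "Quantifying mast cells around lymphoma infiltrates: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mast cells around lymphoma infiltrates: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcquant)
```

# The analysis problem

Skin biopsies stained for mast-cell tryptase (red AEC chromogen) over a
hematoxylin counterstain contain three superimposed signals: nuclei of
all cells, the tryptase-positive cytoplasm and granules of mast cells,
and unstained stroma. The questions the pipeline answers are spatial:
how many mast cells sit *inside* a dense lymphoma infiltrate, how many
in its immediate vicinity, how many further away — as absolute density
(MC/mm²), as a fraction of all nucleated cells, and split by activation
state, where a degranulating mast cell scatters its granules into a
fragmented cloud instead of one compact body.

# Model and procedure

## Stain separation

Brightfield stains attenuate light multiplicatively, so they add in
optical density (Beer–Lambert). We use the offset transform

$$\mathrm{OD}_c = -\log_{10}\frac{I_c + 1}{I_{0,c} + 1},$$

which maps background ($I = I_0$) to zero and keeps fully absorbing
pixels finite. Unmixing follows the standard OD-space linear model: with
unit stain vectors $\mathbf h$ (hematoxylin) and $\mathbf t$ (AEC), each
pixel's OD vector is decomposed in the basis
$(\mathbf h, \mathbf t, \mathbf h \times \mathbf t)$. Because the basis
has full rank this equals the least-squares projection onto the stain
plane; the third coordinate is the residual, reported per image as an
unmixing-quality figure. Negative concentrations (noise outside the
stain cone) are clipped to zero and the clipped fraction logged.

The default vectors are the published hematoxylin/AEC directions used by
common two-stain deconvolution vector sets, normalised to unit length.
Scanners differ; `stain_model()` accepts overriding vectors, e.g. median
OD directions measured on single-stain control patches.

The synthetic renderer (`render_ihc()`) is the exact inverse of this
transform, $I_c = (I_{0,c}+1)\,10^{-(Hh_c + Tt_c)} - 1$, so that the
noiseless float path round-trips to machine precision and the only
distortion under quantisation is the 8-bit rounding itself. (A renderer
without the +1 offset would leave a systematic ~0.007 OD error and make
the round-trip tests insensitive to real regressions.)

## Nuclear segmentation

Nuclei are segmented on the H map inside the dermis: Gaussian smoothing,
a foreground threshold (Otsu on in-mask values, floored at 0.10 OD so a
nearly-empty mask cannot drive the threshold into stroma), hole filling,
then watershed on the Euclidean distance transform to split touching
nuclei, an equivalent-diameter gate of 3–20 µm (lymphocyte to
keratinocyte scale), and a 3 µm minimum centroid separation that removes
duplicate fragments, keeping the larger component.

Two numeric choices matter and were set by measuring split quality on
planted fields with known positions: smoothing σ = 0.7 µm and a
watershed merge tolerance of 0.15 µm. A heavier blur (≥ 1 µm) fattens
touching pairs enough that the distance map loses the saddle between
them; the shallow tolerance re-splits them while the minimum-separation
rule absorbs any resulting over-segmentation of single nuclei. "Total
cells" includes mast-cell nuclei — nothing in the counting rule
distinguishes them, and at the densities involved the difference is a
few percent of the total.

## Density mapping and infiltrate extraction

Local cell density is a Parzen (kernel density) estimate: an isotropic
Gaussian of bandwidth σ_d = 25 µm, normalised to integrate to exactly one
cell, centred on every centroid, and expressed in cells/mm². The
discrete kernel is truncated at 4σ and renormalised, so total mass
equals the cell count (verified to 1 % for kernels ≥ 3σ inside the
grid) and the single-cell peak matches the closed form
$10^6/(2\pi\sigma_d^2)$ cells/mm². σ_d ≈ three lymphocyte diameters is
the scale at which an infiltrate reads as a region rather than as
individual cells. The estimate may be evaluated on a decimated grid and
bilinearly upsampled (`parzen_decim`), a pure speed knob.

The infiltrate is the dermis region with density ≥ ρ_min, closed by
15 µm, hole-filled, with components under 0.005 mm² dropped. ρ_min
defaults to 4000 cells/mm²: dense lymphoid infiltrates run several-fold
above normal dermal cellularity (~1000–2000 cells/mm²), so the
threshold sits between the two regimes rather than at either. Published
sources for this kind of analysis name no number, so the value is a
package default, configurable, and replaceable outright by an edited
mask (`ctcl_override`) — the programmatic equivalent of the visual
correction step a pathologist would apply. Multiple disjoint infiltrate
components are allowed and pooled per sample.

## Epidermis

The epidermis is found as the band of elevated nuclear density adjacent
to the tissue/background boundary: within a 150 µm-deep surface collar,
the blurred H map (σ = 10 µm) is thresholded by Otsu; components
adjacent to the surface are kept, gaps between band and surface that do
not connect to deep tissue are filled, and two guards (a flat-signal
check and a band-vs-deep median contrast of at least 1.15×) return an
empty mask with a warning rather than a fabricated band. An override
mask replaces the heuristic verbatim. The epidermis is excluded from
the proximity bands and from all counting — the analysis is a dermal
one, and epidermotropic signal would otherwise contaminate P1.

## Proximity bands

P1 and P2 are half-open shells of the Euclidean distance transform of
the infiltrate mask: distance in (0, 30] µm and (30, 60] µm, intersected
with the dermis. Half-open intervals make the partition exact; on
conflicts the priority is EPIDERMIS > CTCL > P1 > P2. Band areas on a
disc phantom match the analytic annuli within pixelation error (2 % at
0.275 µm/pixel is verified in the tests).

## Mast-cell detection and degranulation

Tryptase blobs are 8-connected components of the thresholded T map
(Otsu on in-dermis values, floored at 0.15 OD) after a 0.5 µm median
filter; components under 2 µm² are discarded as chromogen specks. Blobs
within 12 µm (single linkage, so chains merge transitively) form one
cluster = one candidate mast cell; this keeps a body with its scattered
granules as a single cell rather than counting every granule. Clusters
under 15 µm² total are debris.

The degranulation rule operationalises the morphological definition
"single large compact blob vs. cluster of fragmented blobs":

* **non-degranulated** — exactly one blob, area ≥ 40 µm², solidity
  (area / convex-hull area) ≥ 0.8;
* **degranulated** — anything else above the debris gate.

All four parameters are package-defined operational choices, not
published constants; they are configurable, and their defaults bracket
mast-cell scale (a 10 µm body is ~80 µm²). The linkage radius doubles as
an implicit cap on cluster extent; two genuinely adjacent mast cells
closer than 12 µm would merge, which is the known failure mode of any
unsupervised grouping at this resolution.

## Statistics

Per region and sample: area (labelled pixels × pixel area), counts by
centroid membership, MC/mm², MC as % of total cells, and degranulated MC
as % of all MC, with zero denominators giving *undefined* (empty CSV
field), never zero. Cohort comparisons use the Wilcoxon matched-pairs
signed-rank test (W = min(W⁺, W⁻), zeros dropped by default, Pratt
optionally) and the Mann–Whitney U test (U = min(U_A, U_B), mid-ranks).
P-values are exact — equivalent to full enumeration, which the test
suite verifies against independent brute-force oracles — for up to 20
untied pairs / combined n ≤ 12 without ties, and tie-corrected,
continuity-corrected normal approximations beyond. The cutoffs are
package choices: enumeration is cheap there and the approximation is
accurate beyond. No multiple-testing correction is applied anywhere;
the CLI prints raw p-values and says so. Significance is strict
(p < α), so p = 0.05 at α = 0.05 is not significant.

# The synthetic-data generator

`generate_sample()` builds the scene the pipeline expects to see: a
background strip, an 80 µm epidermal band at 6000 nuclei/mm², dermis at
1500 nuclei/mm², a disc infiltrate (radius 200 µm) at 8000 nuclei/mm²,
and mast cells placed by a hard-core process (4 µm nucleus separation,
35 µm between mast cells so clusters never bridge). Non-degranulated
cells are ellipses with 8–14 µm axes; degranulated cells are a 3–5 µm
remnant plus 3–6 satellite granules (1.5–3 µm) within 10 µm. Default MC
densities are 250/250/125/100 per mm² in CTCL/P1/P2/remaining dermis —
the orderings infiltrate ≈ inner band > outer band. The standard
validation cohort (`run_synthetic_cohort()`) uses 20 samples, 10
early-stage at base density 300 MC/mm² and 10 advanced at 180, with
zone multipliers 1/1/0.5/0.4.

The planted P1→P2 drop is steeper than cohort medians reported for real
sections. That is deliberate: at desk scale the bands cover ~0.04 mm²
per sample, so per-sample counts are ~5–12 and Poisson noise dominates;
real biopsies offer band areas two orders of magnitude larger. A
count-level power analysis of the exact cohort structure (stage split
included) fixed the multipliers so the planted orderings are detectable
in 20 samples with high probability; the first version of that analysis
ignored the stage split and overstated power, which is why the P2
multiplier is 0.5 rather than the 0.64 a pooled analysis suggests.

What the generator does *not* emulate: chromogen texture within cells
(concentrations are flat with sharp edges), optical blur, uneven
illumination and stain gradients, overlapping nuclei in 3-D, folds,
pigment, and real degranulation morphology (partial degranulation,
granule trails). Passing tests therefore demonstrate correctness of the
geometry, calibration, unmixing, counting and statistics under the
stated noise model — not segmentation robustness on real slides, which
must be established per scanner and staining protocol, typically with
the override-mask route for QC.

# Numerical and interface choices

* Pixel convention: a pixel is a d×d µm square; centroids are region
  members through the pixel containing them. Areas are labelled-pixel
  counts × pixel area.
* Coordinates exchanged with files are physical (`x_um`, `y_um`);
  in-memory row/col indices follow R's 1-based convention.
* Masks are 16-bit single-channel TIFFs with a JSON legend sidecar
  (bit-exact round trip); images are 8-bit TIFF/PNG with calibration
  from an explicit argument, a sidecar, embedded resolution metadata, or
  the 0.275 µm default, in that order.
* Configuration is YAML (`run_config()` defaults, `read_run_config()`),
  CSV output always uses `.` as decimal separator.
* Degenerate inputs are contracts, not errors: empty dermis → empty cell
  set; empty infiltrate → empty bands with a warning and undefined
  densities; all-zero paired differences → p = 1.
* EBImage supplies the image primitives (blur, FFT convolution, distance
  transform, watershed, morphology); connected components are relabelled
  to 8-connectivity. The 3×3 median is a sorting network, and hard-core
  placement uses a bucket grid, both for speed at cohort scale.
* Problem sizes in the shipped tests: 0.36 mm² fields at 1–2 µm/pixel
  for detection checks, 200 planted mast cells per regime at
  0.5 µm/pixel, 2000-replicate null simulations at n = 15, and 50
  seeded cohort replicates of 20 samples each for the end-to-end
  contrasts. These are the scales at which the package's own validation
  was designed to be informative yet quick to re-run.

# Known limitations

Stain vectors are a literature default, not a fitted model; badly
calibrated scanners need the override. The infiltrate threshold is a
global density cut — infiltrates defined by cytology rather than
density will need the mask route. The degranulation rule is a
2-D morphological proxy; electron-microscopy-grade activation state is
out of reach of brightfield IHC. And the statistics are deliberately
plain (exact nonparametrics, no covariates): survival or regression
modelling belongs downstream.
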