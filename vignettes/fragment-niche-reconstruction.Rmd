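---
title: "Reconstructing spatial niches from fragment-based single-cell hashing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing spatial niches from fragment-based single-cell hashing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragseq)
```

## The measurement model

Fragment-based single-cell sequencing sorts partially dissociated tissue
into 200-450 µm cellular communities ("fragments"), one per well, sizes
estimated from the sorter's time-of-flight (TOF). Each well's cells are
labelled with a fragment-specific lipid-anchored DNA barcode before
pooling, so after sequencing every cell can be traced back to the
community it came from. No cell ever receives a physical coordinate: the
spatial information is the *composition and expression profile of each
fragment*, which this package converts into niche labels.

Three niche reconstructions are supported:

1. **Lobule layer (liver zonation).** For each fragment, a pseudobulk
   over its liver endothelial cells (LECs) is compared against reference
   profiles of central and portal landmark genes. After max-normalizing
   each landmark across fragments (so every gene contributes equally),
   the portal and central landmark sums pLM and cLM give the zonation
   coordinate
   $$ZC = \frac{pLM}{pLM + cLM},$$
   min-max rescaled over retained fragments so 0 is the most central and
   1 the most portal fragment. Coordinates are binned into decile layers
   L1-L10 (upper bin closed so the map is total on [0, 1]), optionally
   merged into L1-L3 / L8-L10 where sampling is sparse, and grouped into
   central (L1-L5) and portal (L6-L10) zones.
2. **Metastasis proximity.** Fragments containing at least one landmark
   cell (metastatic cell) are `proximal`, the rest `distal`; samples with
   fewer than 20 landmark cells overall and fragments with fewer than 5
   cells are excluded first.
3. **Data-driven niches.** Fragment pseudobulks over a small landmark
   gene panel are scaled, projected to principal components and
   partitioned with a shared-nearest-neighbor graph plus Louvain
   communities (resolution 0.4 by default).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_cells` (zonation pseudobulk) | 5 | cells | fragments with fewer cells cannot represent a niche |
| `min_cells` (two-group DE pseudobulk) | 2 | cells | the two-group contrast tolerates sparser fragments |
| landmark filter floor | 1e-5 | normalized expression | drops unexpressed reference genes |
| landmark pole fold change | 1.1 | ratio | requires a 10% L1-vs-L10 gradient |
| landmark SEM/mean | 0.2 | ratio | discards highly varying reference profiles |
| `min_landmark_cells_per_sample` | 20 | cells | samples with fewer metastatic cells cannot define proximity |
| neighbor radius | 10 | µm | edge threshold of the spatial graph (strictly `<`) |
| `k_cap` | 41 | neighbors | radius-search cap; saturation warns |
| permutations `m`, `n_perm` | 1000 | draws | permutation resolution; p floor is 1/(m+1) |
| `min_frac_expressing` | 0.1 | fraction | ligand/receptor gating before scoring |
| segment-area filter | median + 4·MAD | pixels | removes fused segments; MAD is unscaled |

## Statistical models

Niche-resolved statistics run on *sum-mode pseudobulks* (raw counts
summed within fragment and cell type), fitted with negative-binomial
generalized log-linear models and quasi-likelihood F-tests (edgeR), with
the sample always included as a fixed-effect blocking factor and BH
adjustment across genes. We deliberately call edgeR rather than
re-deriving the NB machinery: the package's contribution is the
pseudobulk/design construction around it, and the QL F-test is the
field-standard test for this design. For zonated-gene detection the
lobule layer enters as an ordered factor encoded as equally spaced
scores (L1-L3 < L4 < L5 < L6 < L7 < L8-L10); equal spacing after merging
the extremes is an assumption, made explicit here, since nothing in the
design fixes the spacing. Cell-type abundance shifts are modeled per cell
type on sample-by-group count units with the unit's total cell count as
library size, dispersion estimated without an abundance trend and a
robust QL fit.

Ligand-receptor scoring follows the mean-of-means convention: an
interaction's score is the average of the ligand's mean normalized
expression (log1p of counts scaled to 10^4 per cell) in the sender
cluster and the receptor's in the receiver cluster; multi-subunit
complexes are summarized by the minimum over subunits; an interaction is
only tested when every component is expressed in more than 10% of its
cluster. Significance is an upper-tail label permutation over the pooled
sender/receiver cells with the add-one estimate p = (b+1)/(n+1),
unadjusted. Whether permutation should respect sample boundaries is
genuinely open; pooled permutation is the default and a within-sample
option exists.

The colocalization test compares, per slide, the difference between ROI
groups of normalized neighbor-graph edge counts per cell-type pair
(E/(n₁+n₂); 2n for same-type pairs) against a null from permuting type
labels over the slide's vertices with the graph fixed, p = (b+1)/(m+1).
Per-ROI means are averaged before differencing (the pooled-count variant
is a documented alternative). The default counts the two-sided tail
|null| ≥ |observed| and carries the sign into the cross-slide score (the
signed fraction of significant slides); the literal one-tail count is
available via `tail = "upper"`.

## Cell-to-fragment classification

Hashing-count classification places a per-barcode threshold on the log1p
count scale along the interval between the background mode and the
signal mode of that barcode's count density, sweeping a single quantile
position q over 0.10-0.90 (step 0.05) and keeping the q that maximizes
the fraction of singlet cells. A raw count quantile cannot work here:
with B barcodes only ~1/B of cells are positive per barcode, so the
optimal raw-count quantile (1 - 1/B) leaves any fixed sweep grid; the
inter-mode interpolation keeps the sweep meaningful for any barcode
count. Cells above threshold for zero, one, or several barcodes are
NEGATIVE, POSITIVE, or DOUBLET respectively. Species-mixing scoring
flips the well species of any fragment whose cells are 100% mismatched
(attributed to a sorting error) before computing accuracy; the threshold
is exactly 1 by default and configurable.

Barcode design draws random candidates over {A,C,G,T}^L and greedily
rejects any candidate within the minimum Hamming distance of an accepted
one, with a try budget that converts infeasible requests into capacity
errors. Any generator satisfying the pairwise-distance invariant is
conformant; the invariant is always re-verified post hoc by the
exhaustive O(n²L) check. Homopolymer/GC content filters are off by
default.

## The synthetic-data generator

`simulate_lobule_experiment()` emulates the statistical structure the
pipeline consumes: a true zonation coordinate per fragment (uniform by
default; a truncated-normal option mimics sparsely sampled extreme
layers), negative-binomial UMI counts whose log-mean is linear in the
coordinate for landmark and planted zonated genes (restricted to carrier
cell types), proximity-shifted cell-type compositions (more metastatic
cells and macrophages, fewer KCs and LECs near metastases — directions
configurable, magnitudes free parameters), Poisson hashing counts with
doublet/negative contamination, and TOF linear in fragment size with
noise. Defaults — 200 fragments over 3 samples, ~30 cells per fragment,
20 landmark genes per pole with log-slope ±2, hashing signal mean 500
over background 5, 5% doublets and 5% negatives — were chosen once as
plausible values for this assay; the hashing noise levels in particular
are order-of-magnitude guesses, as no quantitative values are published
for the chemistry.

What the generator does *not* emulate: ambient RNA, empty droplets,
batch-specific gene programs beyond a per-sample depth factor,
transcriptome doublets (only hashing doublets), or irregular ROI
geometry (`simulate_point_pattern()` uses square ROIs with uniform
placement plus planted type-type attraction). Passing recovery tests on
this generator therefore demonstrates correctness of the algorithms
under the stated statistical model, not robustness to every artefact of
real data.

## Numerical choices and degenerate inputs

- Layer binning adds a 1e-9 guard before `floor()` so coordinates that
  are exact bin edges in decimal (0.7, 0.9) are not misplaced by
  floating-point representation; ZC = 0.9 belongs to L10, making the
  binning total.
- Fragments with no landmark expression (pLM + cLM = 0) are dropped and
  reported, never imputed; an all-identical coordinate set is a
  degenerate-rescale error.
- The landmark stability filter averages SEM/mean only over layers with
  positive mean (the ratio is undefined at zero), and a zero mean at one
  lobule pole counts as infinite fold change — such genes are kept and
  flagged, since silencing at one pole is the strongest zonation signal.
- Sizes predicted from TOF can be negative under a noisy calibration;
  they are flagged, never clamped. Gates are closed intervals, so the
  printed ranges 211-325 and 326-457 µm tile without overlap.
- Label expansion assigns exact Euclidean nearest segments; distance
  ties go to the smaller label id. Point-in-polygon uses the closed
  boundary convention (on-edge = inside).
- Permutation p-values use the add-one estimator everywhere, so p ≥
  1/(m+1) and never 0.

## Problem sizes used in the validation suite

The packaged tests run parameter-recovery and calibration studies at
desk scale, chosen to estimate each property with comfortable error
margins: zonation recovery at 200 fragments (Spearman ≥ 0.9 against
truth), type-I error of the DE paths pooled over 20 replicates × 2000
null genes (expected fraction of raw p < 0.05 within [0.03, 0.07]),
permutation-null uniformity over 200 replicates (KS), detection power
for planted effects over 10-20 replicates, and oracle equivalence of the
fast spatial routines against brute force at up to 500 points.

## Known limitations

- The ordered-factor scores treat merged extreme layers as single
  levels; if the merged bins cover very different coordinate spans the
  linear trend coefficient is only an approximation of the per-layer
  trend.
- Reference landmark panels may carry 9 or 10 layers; pole-based filters
  use the first and last available layer, so a 9-layer reference
  slightly shifts the pole definition.
- The classification sweep assumes a bimodal per-barcode count
  distribution; with signal ≈ background the modes merge and cells are
  conservatively called NEGATIVE.
- `landmark_cluster_fragments()` reproduces the *number and separation*
  of niche clusters, not any specific tool's label values.
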