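# fragseq

Spatial niche reconstruction and niche-resolved statistics for
fragment-based single-cell transcriptomics.

Fragment-based sequencing partially dissociates tissue into 200–450 µm
cellular communities (*fragments*), sorts one fragment per well on a
large-particle biosorter, tags each well's cells with a
fragment-specific lipid-anchored DNA barcode, and pools everything for
single-cell RNA sequencing. No cell carries a physical coordinate;
instead, each fragment's composition and expression reveal the niche it
came from. This package implements the computational side of that assay
for analysts working with hashed single-cell data:

- **Barcode design and demultiplexing** — DNA hashing-barcode sets under
  a minimum Hamming-distance constraint (e.g. 288 barcodes of 8 nt at
  distance ≥ 3), and classification of cells to fragments from barcode
  UMI counts (POSITIVE / NEGATIVE / DOUBLET), with species-mixing
  accuracy scoring.
- **Sorter calibration** — least-squares standard curve of time-of-flight
  (TOF) on bead diameter, TOF → size inversion, and size gating.
- **Niche reconstruction** — the per-fragment liver zonation coordinate
  ZC = pLM/(pLM + cLM) from central/portal landmark-gene sums in liver
  endothelial cells, min–max rescaled, binned into lobule layers L1–L10
  and central/portal zones; metastasis proximity from landmark cell
  types; landmark-gene niche clustering.
- **Niche-resolved statistics** — zonated-gene detection with an ordered
  lobule-layer covariate and two-group differential expression on
  fragment pseudobulks (negative-binomial quasi-likelihood F-tests via
  edgeR, sample as blocking factor, BH-adjusted), and cell-type
  abundance testing.
- **Ligand–receptor scoring** — mean-of-means interaction scores with
  multi-subunit complexes (minimum over components) and upper-tail
  cluster-label permutation p-values, p = (b+1)/(n+1).
- **Spatial validation operators** — segment label expansion, transcript
  assignment, MAD-based segment filtering, polygon area annotation,
  radius neighbor graphs, and a colocalization permutation test between
  ROI groups with a signed cross-slide score.
- **A synthetic-data generator** with full ground truth (zonation
  gradients, composition shifts, hashing contamination, TOF noise,
  planted spatial attraction), so every stage has a parameter-recovery
  test without external data.

## Worked example

```r
library(fragseq)

cfg <- lobule_sim_config(n_fragments = 100)
sim <- simulate_lobule_experiment(cfg, seed = 1)
exp <- sim$experiment
exp
#> FragmentExperiment: 100 genes x 2889 cells; 100 fragments
#>   cells: assigned 2889, NEGATIVE 0, DOUBLET 0, UNASSIGNED 0

# hashing-based cell-to-fragment classification
h  <- simulate_hashing_counts(sim$truth$cell_fragment, cfg, seed = 2)
cl <- classify_cells(h$counts)
table(cl$call)
#>  DOUBLET NEGATIVE POSITIVE
#>      151      140     2598
exp <- attach_fragments(cl, exp,
                        barcode_map = setNames(names(h$barcode_of),
                                               h$barcode_of))

# zonation coordinates from landmark genes in LEC pseudobulks
panel <- filter_landmarks(simulate_landmark_panel(cfg))
pb  <- fragment_pseudobulk(exp, "LEC", min_cells = 5, mode = "mean")
zon <- group_zone(bin_layers(compute_zc(pb, panel)))
head(zon, 3)
#>   fragment  plm_sum  clm_sum    zc_raw zc_rescaled layer   zone
#> 1     F004 18.33630 11.20193 0.6207651   0.9868775   L10 portal
#> 2     F008 17.07912 14.25730 0.5450245   0.7280430    L8 portal
#> 3     F009 16.39220 13.32556 0.5515962   0.7505009    L8 portal
cor(zon$zc_rescaled, sim$truth$zc[zon$fragment], method = "spearman")
#> 0.988
```

Each row is one fragment: `plm_sum`/`clm_sum` are its portal and central
landmark sums after per-gene max-normalization, `zc_raw` the coordinate
pLM/(pLM+cLM), `zc_rescaled` the min–max rescaled coordinate (0 = most
central, 1 = most portal fragment), and `layer`/`zone` its decile lobule
layer and vein group. The reconstruction orders fragments almost
perfectly along the simulated lobule axis (Spearman 0.988 against the
generator's hidden coordinate).

Zonated genes are then detected on sum-mode pseudobulks with the layer
as an ordered covariate:

```r
zl  <- bin_layers(zon, merge_extremes = TRUE)
pbs <- fragment_pseudobulk(exp, "LEC", min_cells = 5, mode = "sum")
common <- intersect(rownames(pbs), zl$fragment)
de <- zonated_de(pbs[common, ], zl$layer[match(common, zl$fragment)],
                 exp$fragments$sample[match(common, exp$fragments$fragment)])
head(de[order(de$p), c("gene", "coef", "p", "fdr")], 5)
#>     gene       coef            p          fdr
#> 31 pLM11  0.4147078 1.740986e-31 1.740986e-29
#> 23 pLM03  0.4109426 4.046873e-30 1.735730e-28
#> 14 cLM14 -0.3705719 6.532011e-30 1.735730e-28
#> 39 pLM19  0.4121630 6.942920e-30 1.735730e-28
#> 17 cLM17 -0.3758879 9.049187e-30 1.809837e-28
```

Portal landmarks come out with positive layer coefficients (log2 change
per layer step), central landmarks negative, all at vanishing FDR —
exactly the planted gradients.

A configuration-driven end-to-end run (simulation → demultiplexing →
sorter → zonation → statistics) with a hashed output manifest is
available via `run_pipeline()`; a thin command-line wrapper lives at
`inst/scripts/fragseq`.

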