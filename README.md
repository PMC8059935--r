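# hexspat

Analysis toolkit for spatially barcoded, split-pool combinatorially indexed
single-cell RNA-seq. The assay it supports seals a fixed tissue slice onto a
hexagonal array of microwells (500 µm center-to-center); each well's reverse
transcription primer carries a 16-nt spatial barcode, and a second round of
PCR indexing yields a combinatorial cell barcode, so that after sequencing
every cell's transcriptome can be mapped back to its well of origin. With
768 spatial barcodes and 384 PCR indices, up to 768 × 384 = 294,912 cells
are addressable.

The package is aimed at computational biologists working with this class of
microwell spatial scRNA-seq data (or methods developers benchmarking
against it) and covers the workflow downstream of alignment:

- **hex-array geometry** — axial-coordinate well maps, hexagonal graph
  distances, concentric well layers, TSV well-map I/O;
- **demultiplexing** — read-1 parsing (10-nt UMI + 16-nt spatial barcode),
  Hamming-distance barcode correction against the well map,
  UMI-deduplicated sparse cells × genes matrices, per-cell QC filters
  (500–10,000 UMIs, 100–15,000 genes, ≤1% mitochondrial);
- **species-mixing QC** — per-cell species calls under the 66% majority
  rule, barcode collision rates, Lin's concordance correlation against the
  21-column mixing gradient;
- **ambient RNA decontamination** — per-cell counts modeled as a mixture of
  the cluster's native expression φ_k and a contamination profile η_k
  aggregated from the other clusters, with a Beta-distributed per-cell
  contamination proportion θ_c, fitted by EM;
- **tumor-proximity scoring** — the layered score
  s = (u₁ p + Σ_l u_l p_l) / W with exponential-decay layer weights
  u_l ∝ 1/d^l (d = 1.05, L = 10 layers, normalized to sum 1), where p is a
  well's tumor fraction and p_l the cell-number-weighted tumor fraction of
  its layer-l neighbors; plus the seeded linear variant
  s = max(0, 1 − l/L);
- **gene modules** — multiplicative-update NMF (rank 20 by default) with
  descending-coefficient gene rankings, longest-dominating-prefix top-gene
  selection, cross-tissue module matching by top-200 gene overlap (pairs
  under 25% dropped), per-module cell-type fractions and spatial high/low
  projection;
- **proximity-associated differential expression** — per-gene
  negative-binomial GLM on a cubic B-spline basis of the proximity score
  with library-size offset, joint Wald test of the spline coefficients,
  Benjamini–Hochberg correction, and classification of significant genes
  into intratumor / boundary / intratissue by fitted-curve peak;
- **synthetic data** — seeded generators for tumor/tissue arrays, the
  species-mixing gradient, planted ambient contamination, and full
  four-file FASTQ libraries for demultiplexing round trips.

## Worked example

Simulate a species-mixing gradient run with 5% planted barcode collisions
and Beta(2, 8) ambient contamination, then estimate and remove the
contamination:

```r
library(hexspat)

bn  <- simulate_barnyard(n_rows = 12, cells_per_well = 8,
                         collision_rate = 0.05, seed = 42)
amb <- inject_ambient(bn$counts, clusters = bn$truth$cells$species,
                      alpha = 2, beta = 8, seed = 43)

collision_rate(amb$counts$cell_meta$species)
#> [1] 0.1547151
gradient_concordance(amb$counts)$ccc
#> [1] 0.9930301

cl  <- ifelse(amb$counts$cell_meta$human_umis >=
              amb$counts$cell_meta$mouse_umis, "human", "mouse")
fit <- fit_decontamination(amb$counts, cl, seed = 44)
contamination_summary(fit)
#>   cluster n_cells median_theta_pct
#> 1   human    1059         16.02448
#> 2   mouse     977         16.47316

clean <- decontaminate(amb$counts, fit)
collision_rate(clean$cell_meta$species)
#> [1] 0
```

The raw collision rate (15.5%) is inflated by ambient transcripts: the
planted contamination (Beta(2, 8), mean 20%; realized per-cluster medians
of ~16% recovered above) pushes many single-species cells below the 66%
purity threshold. Removing the estimated contamination signature restores
the species separation, and the column-wise human fraction tracks the
printed gradient design almost perfectly (CCC = 0.993).

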