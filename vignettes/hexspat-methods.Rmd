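---
title: "Models and methods behind hexspat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hexspat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexspat)
```

This vignette documents the statistical models, geometric conventions, and
numerical choices behind hexspat, in the spirit of a methods supplement: it
states what each stage assumes, which knobs matter, and what the synthetic
data generator does and does not emulate. It states no empirical result
that the package's tests and acceptance script do not themselves compute.

## The assay and its containers

The assay partitions a fixed tissue slice over a hexagonal array of
microwells at 500 µm pitch. Each well's RT primer carries a 16-nt spatial
barcode; a second split-pool round adds one of 384 PCR (i5) indices, so a
cell barcode is the pair (spatial barcode, PCR index). Read 1 is sequenced
for 26 cycles and is pure barcode chemistry — a 10-nt UMI followed by the
16-nt spatial barcode; read 2 is cDNA; index read 2 carries the i5 index.

A `well_array` stores wells in offset coordinates `(row, col)` at the file
boundary and axial coordinates `(q, r)` internally ("odd-r" packing: odd
rows shifted half a pitch right, `q = col - (row - row %% 2) / 2`,
`r = row`). Axial coordinates make the two workhorse operations one-liners:
the hexagonal graph distance is `(|dq| + |dr| + |dq + dr|) / 2`, and layer
`l` of a well is the set of wells at distance exactly `l` (6·l wells on an
unbounded grid; truncated at chip edges, with no wrap-around — the chip is
physical). The chip dimensions are nowhere dictated by the chemistry; we
default to 24 × 32 = 768 wells, the spatial-barcode count, which matches a
microscope-slide aspect ratio and the column-gradient design of the mixing
experiment. Both dimensions and the hex orientation convention are
configurable; only the odd-r convention is implemented because the distance
and layer math is orientation-invariant after the offset-to-axial map.

## Demultiplexing

Barcode correction accepts the unique whitelist entry within
`max_hamming = 1` substitutions and discards ambiguous or unmatched reads —
ambiguity is never guessed. Generated whitelists enforce pairwise Hamming
distance ≥ 3 (checked at construction), which makes single-error correction
exact. UMI collapse is exact-match within (cell, gene): the assay's UMIs
are 10-nt (~10⁶ sequences), so directional-graph collapse would change
little at these depths and is deliberately not implemented. PCR indices are
matched exactly; index-read demultiplexing errors are handled upstream by
the base-calling pipeline.

Cell filters default to the microwell assay's bounds — 500–10,000 UMIs,
100–15,000 detected genes, ≤ 1% mitochondrial UMIs (gene-symbol prefix
`mt-`/`MT-`, configurable since references differ) — all inclusive at the
boundary. Droplet-based data conventionally uses wider bounds; the bounds
are plain arguments.

## Species QC

In a mixed human/mouse run, a cell is called for the species carrying at
least 66% of its human+mouse UMIs, else it is a collision (two cells of
different species under one barcode). The threshold is inclusive at the
boundary, reading "less than 66% ⇒ collision" literally. Lin's concordance
correlation coefficient is computed with population (1/n) moments, as in
its original definition; the difference from sample moments is O(1/n) and
immaterial at the column counts involved. The built-in gradient design is
the 21-column pattern (human fraction 1 → 0 → 1 in steps of 0.1, 11
distinct ratios) used to check that observed column compositions track the
deposited ones.

## Ambient decontamination

Observed counts of cell *c* in cluster *k* are modeled as a mixture: each
transcript is native with probability `1 − θ_c` (drawn from the cluster's
expression distribution φ_k over genes) or ambient with probability `θ_c`
(drawn from a contamination distribution η_k). θ_c has a Beta(α, β) prior,
default uninformative (1, 1). η_k is the count-weighted average of φ_j
over clusters j ≠ k, recomputed each M-step — contamination is whatever
the *other* populations shed. Cluster labels are an input; this module
does not cluster.

Inference is plain EM with point estimates and a MAP update for θ, rather
than the variational treatment sometimes used for this model family: the
generative model is what matters downstream, EM on it is simpler, and its
fixed points are directly testable (on constructions with disjoint cluster
supports and per-cell varying contamination, the EM estimate of θ equals
the analytic foreign-count fraction to 1e-6 — asserted in the tests).
Because η is tied to φ, the procedure is generalized EM; the objective
trace is asserted non-decreasing up to a 1e-8 relative numerical
tolerance. θ is clamped to [1e-6, 1 − 1e-6], profile distributions carry a
1e-12 pseudocount, and convergence is declared when the objective moves
less than `tol` (default 1e-4) or after `max_iter = 200` iterations.

Correction replaces each count by its expected native component
(`x · P(native | gene, cell)`), floored to integers for downstream count
models, with the unrounded matrix attached; corrected counts never exceed
raw ones, and per-cell totals shrink to ≈ (1 − θ_c) of raw. Values are
snapped (+1e-9) before flooring so exact-integer expectations survive
floating-point noise. Before fitting, `flag_cross_species_outliers`
implements the control-population rule used with mixed-species spike-ins:
mouse genes with natural `log(total counts + 1) > 6` inside human cells
are flagged for removal, human genes never. The pipeline fixes the order
outlier-removal → fit/decontaminate → cell filters.

## Proximity scores

For well *w* with `t_w` tumor+reference cells of which a fraction `p_w`
are tumor, the layered score is

> s_w = ( u₁·p_w + Σ_{l=1..L} u_l·p_{w,l} ) / W

where `p_{w,l}` is the cell-number-weighted mean tumor fraction over the
wells of layer `l` that contain scored cells, and `u_l = (1/d^l) / Σ 1/d^l`
are exponential-decay weights, `d = 1.05`, `L = 10` — a decay gentle enough
to grade a 10-layer neighborhood (u₁/u₁₀ = 1.05⁹ ≈ 1.55). The well's own
composition deliberately shares the layer-1 weight. Two choices are ours:

- **Normalization.** The raw sum has total weight `1 + u₁ > 1`, and edge
  wells or empty layers drop terms; we divide by the realized total weight
  `W` so `s ∈ [0, 1]` always, matching the score's 0-to-1 color-scale
  semantics. Whether the original analysis renormalized at tissue edges is
  not documented; renormalization is the only choice that keeps the
  uniform-composition fixed point (`p ≡ c ⇒ s ≡ c`) exact on bounded
  arrays.
- **Orientation.** `p` defaults to the *tumor* fraction so s ≈ 1 means
  tumor-rich, the figure-level semantics of such maps; the mirrored
  reference-fraction convention is one flag away
  (`orientation = "reference"`), the two being exact reflections
  (s ↦ 1 − s, asserted in tests).

On a straight tumor/tissue boundary with uniform cells per well the two
straddling wells average 0.5, and the score is monotone along rays at full
chip scale (24 × 32); on much smaller arrays the L = 10 neighborhood is
edge-truncated everywhere and strict monotonicity degrades to a monotone
trend — the tests distinguish the two regimes explicitly.

The seeded linear variant, for tissues where the tumor sits at one end,
sets chosen seed wells to 1 and decays linearly by hexagonal layer:
`s = max(0, 1 − l/L)` with `l` the distance to the nearest seed, 0 from
layer 10 outward. Seed wells are a user input, as seed selection is a
judgment call about the tissue.

## Gene modules

Expression input is prepared by depth normalization (10,000 per cell),
log1p, per-gene standardization, and clipping negatives to zero — a
deliberate, documented approximation of variance-stabilizing regression
residuals (the regularized NB regression machinery itself is out of
scope). Factorization is Lee–Seung multiplicative-update NMF minimizing
Frobenius error, rank 20 by default, uniform random initialization under a
seed, stopping on relative objective change < 1e-5; an optional nonsmooth
interposition matrix `S = (1−ω)I + (ω/r)11ᵀ` is available (`smoothing`,
default 0) for sparser modules. Downstream operations depend only on the
per-module gene ranking, which is robust to the smoothing choice.

"Top contributing genes" of a module is the longest prefix of its
descending-coefficient ranking in which every gene's coefficient is
*strictly* larger in this module than in any other; the scan stops at the
first violation (ties therefore end the prefix). Cross-tissue matching
takes, for each module of tissue A, the tissue-B module with the largest
overlap among top-200 genes (ties toward the smaller B index, reported),
and drops pairs sharing fewer than 25% — the boundary is inclusive, so
exactly 50/200 survives. Spatial projection computes per well the median
over its cells, gene-wise, then the mean over module genes; the global
high/low threshold is the cells-per-well-weighted average of these values.
"Above the weighted average" is strict: equality labels a well low. We
weight the *threshold* (not the per-well statistic) by cell counts — the
natural reading that keeps per-well values comparable across wells.

## Proximity-associated differential expression

For each gene in a (typically cell-type-subsetted) matrix, counts are
regressed on a cubic B-spline basis of the per-cell proximity score
(`n_knots = 4` degrees of freedom) under a negative-binomial GLM with
log-library-size offset; the null hypothesis — no association with the
score — is tested by a joint Wald chi-square on the spline coefficients.
This NB-GLM replaces the NB-GAM smoother of trajectory-inference toolkits:
the tested null is identical, and the fixed low-df spline keeps the test
fast and its degrees of freedom explicit. Dispersion is per-gene method of
moments from the full-model Poisson fit (`θ = Σμ² / Σ[(y−μ)² − μ]`,
clamped to [1e-3, 1e8]), then the NB family is refitted at that θ.
Zero-variance genes get p = 1 and a flag; non-converging fits are flagged
and excluded. P-values are Benjamini–Hochberg adjusted (via `p.adjust`;
the test suite checks it against the literal step-up definition), and
genes significant at FDR 0.05 are classified by the argmax of their
fitted curve on a 50-point score grid: peak in the top third of the score
range → intratumor, bottom third → intratissue, otherwise boundary (flat
curves → boundary, flagged). The thirds rule is our concretization of a
"broadly divided into three groups" criterion that was never formalized;
it is deterministic and auditable. Cells with NA scores (unscored wells)
are excluded before fitting. Calibration is asserted by simulation: type-I
error within [0.03, 0.07] at α = 0.05 over 1,000 null genes (250 cells
each), and power ≥ 0.8 for a 2-fold log-linear ramp at 500 cells and
dispersion 0.5.

## The synthetic-data generator

All generators are pure functions of (design, seed); the seed is threaded
through a save/restore wrapper so library state is never perturbed. The
defaults are the profiled assay's conditions, chosen once: a 768-well
24 × 32 array; 13 cells expected per well (Poisson) for tissue runs;
per-cell libraries around a thousand UMIs (log-normal per-gene baselines,
meanlog log 1.5, sdlog 1, over 400 genes); NB dispersion 0.5; 25 marker
genes per cell type at 8-fold enrichment; a small mitochondrial gene set
at ~0.5% of the library so the 1% filter is exercised from both sides;
tumor wells dominated by MC38 cells and tissue wells by hepatocytes with
immune/stromal types mixed through both; gradient runs at 10 cells per
well fixed (noiseless mode, where tenths make the printed ratios exact) or
Poisson(8) otherwise; ambient contamination Beta(2, 8) (mean 20%).

FASTQ emission serializes every molecule with a distinct UMI within its
(cell, gene) and duplicates reads per molecule by a shifted geometric law
parameterized directly by sequencing saturation (default 0.46, typical of
these libraries; mean reads/UMI = 1/(1−0.46)). Substitution errors at
`error_rate` per base are injected into read 1 only: gene assignment in
this synthetic path stands in for the delegated aligner, whose error
profile is out of scope, and index reads are demultiplexed upstream. Gene
identity travels as a base-4 (A,C,G,T) encoding of the gene index in the
first 12 nt of read 2, keeping the files valid DNA FASTQ without bundling
an aligner; `read_tagged_fastq` decodes it back.

What the generator does *not* emulate: quality-score-dependent error
profiles and indels; transcript-level effects (isoforms, gene length);
doublet transcriptomes beyond species co-encapsulation; spatial
autocorrelation of expression within a domain beyond what cell-type
composition induces; batch effects across slices. Passing tests on this
generator therefore certify the algorithms' contracts — barcode
arithmetic, mixture recovery, score geometry, test calibration — not
robustness to every artifact of real libraries.

## Problem sizes and reproducibility

The shipped test suite runs at desk scale, chosen to finish in about a
minute while keeping estimates stable: decontamination recovery on ~2,000
cells × 500 genes, DE calibration on 1,000 null genes × 250 cells and 100
planted genes × 500 cells, round trips on a few hundred cells, exhaustive
BFS cross-checks on arrays up to 12 × 12. The pipeline writes a resolved
config, a manifest of md5 checksums (excluding the timestamped log), and
byte-identical artifacts for identical (config, seed).

## Known limitations

- EM decontamination assumes cluster labels are broadly correct; heavily
  contaminated cells can be mislabeled by the majority-species heuristic,
  which slightly biases φ. The disjoint-support tests bound this in the
  clean limit only.
- Method-of-moments dispersion is less efficient than ML at very low
  counts; the calibration band is asserted at the simulated depths, not
  universally.
- The layered score's renormalization at edges means edge-well scores mix
  information from fewer wells; they are comparable in range but noisier.
- Multiplicative-update NMF converges to local optima; module content can
  depend on the seed, which is why the seed is a first-class argument and
  runs are reproducible rather than unique.
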