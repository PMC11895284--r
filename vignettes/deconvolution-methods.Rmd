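---
title: "Methods: compartment and genetic-origin deconvolution of single cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartment and genetic-origin deconvolution of single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scorigins)
```

## The problem

Dissociating a solid tissue for scRNA-seq captures every cell in the
piece — including immune cells that were merely passing through the
vasculature at the moment of collection. Blood-borne and tissue-resident
immune cells of the same type are transcriptionally similar, so standard
clustering and annotation do not separate them, and downstream analyses
(differential expression, pathway enrichment, cell–cell communication)
silently mix the two populations. Some tissues additionally contain
cells from more than one individual — the placenta mixes maternal and
fetal cells — which adds a second, genetic axis of confounding.

scorigins deconvolutes both axes: a reference-guided classifier splits
annotated immune cells into *blood* vs. *expected tissue-resident*
compartments, and an optional genotype step demultiplexes barcodes into
*N* genetic origins with mosaic-doublet detection.

## Blood vs. tissue-resident classification

For each annotated immune cell type (by default: monocytes,
macrophages, T-cells, regulatory T-cells, plasma cells, NK cells,
B-cells), the classifier:

1. normalizes query and whole-blood reference counts (counts-per-10k,
   log1p);
2. restricts both to shared highly variable genes (top 2000 by
   dispersion on the concatenated matrix);
3. embeds query and reference cells **jointly** into a shared
   d-dimensional latent space (d = 10, the top 10 latent variables):
   features are z-scaled on the concatenation, a d-dimensional PCA is
   computed, and — by default — the PCA coordinates are further embedded
   by UMAP;
4. computes each query cell's vector of Euclidean distances to every
   reference cell (its *distance profile*);
5. clusters the distance profiles by k-means with k = 2;
6. labels the cluster whose cells are on average closer to the
   whole-blood reference as *blood*, the other as *tissue*.

The intuition: blood immune cells in the query are drawn from the same
population as the whole-blood reference, so their distance profiles are
uniformly small; genuine tissue residents sit in a shifted
transcriptional state and are uniformly farther away.

### Design choices

* **Joint embedding.** Distances between query and reference cells are
  only meaningful if both are embedded by the same transform. We pass
  the concatenated matrix through one z-scale + PCA (+ UMAP), instead
  of anchor-based dataset integration, because the joint transform is
  deterministic, reference-free, and treats query and reference
  symmetrically. The embedding is recomputed per cell type, so each
  type's distances live in a space dominated by that type's own
  variation.
* **UMAP by default, PCA for exactness.** UMAP sharpens cluster
  structure and is the default; PCA is available
  (`embed_method = "pca"`) and is bit-reproducible (component signs are
  fixed by making the largest-magnitude loading positive), which the
  deterministic tests rely on. UMAP runs with `n_neighbors = 30`
  (capped at n − 1), `min_dist = 0.3`, single-threaded, under a fixed
  seed, and is likewise reproducible run-to-run.
* **Clustering the full profile.** k-means operates on the whole
  distance-profile row, not on a scalar summary — the profile preserves
  geometry (which reference neighborhoods a cell is close to), and
  degenerates gracefully to the scalar behaviour when one direction
  dominates.
* **Canonical ordering.** k-means assignments depend on row order
  through the random restarts; rows are therefore visited in an order
  derived from the data values themselves (row means, then
  lexicographic), making calls invariant to both cell order and barcode
  renaming under a fixed seed.
* **Guards.** Cell types with fewer than `min_cells = 20` query cells
  are left `unassigned` (k-means on a handful of cells is noise); an
  exact tie between cluster mean distances is broken toward cluster 0 =
  blood with a warning; if an annotated reference lacks a requested
  type, that type is skipped with a warning. Multi-sample experiments
  should be classified one sample at a time (distances across batches
  conflate batch and compartment).

## Genotype demultiplexing

Where the tissue mixes individuals, ref/alt allele counts at known SNP
positions (extracted upstream from the BAM with a variant caller; this
package consumes the count table) identify each barcode's genetic
origin. Variants with population minor allele frequency above 10% are
excluded (`filter_snps`, boundary-inclusive: MAF = 10% is kept), since
rare variants are the most informative of individual identity; variants
with no coverage are dropped.

The model (`fit_genotype_mixture`) is a freemuxlet-like binomial
genotype mixture, self-contained rather than a wrapper. Each origin
k has a diploid dosage profile $d_{kv} \in \{0, 0.5, 1\}$; a read at
variant v from a cell of origin k is alternate with probability

$$p_{kv} = d_{kv}(1 - \varepsilon) + (1 - d_{kv})\,\varepsilon,$$

with a fixed sequencing error rate ε = 0.01, so a cell's log-likelihood
is $\sum_v \big[a_v \log p_{kv} + r_v \log (1 - p_{kv})\big]$. EM
alternates posterior responsibilities with an exhaustive per-variant
dosage maximization (three candidates, responsibility-weighted) and a
mixing-weight update; it is initialized by k-means on per-cell
alt-fraction vectors (uncovered variants imputed at the population MAF)
and the observed-data log-likelihood is asserted non-decreasing at
every iteration.

*Mosaic doublets* — one barcode carrying a 50/50 genetic mixture of two
individuals — are scored by adding, for every unordered origin pair,
a category whose dosage profile is the pair average. A doublet prior
(default 0.05) is split evenly over pairs, `1 − 0.05` over singlets by
mixing weight; cells whose maximum posterior falls below 0.8 are
`ambiguous`. Origin indices are mapped to biological labels through an
*anchor* cell type of known origin (trophoblasts are fetal): the origin
holding the anchor majority gets the anchor's label; an exact 50/50
split is an error demanding manual assignment.

Numerical choices: ε is fixed, not estimated — at per-variant coverage
near 2 reads the likelihood cannot separate error rate from dosage
reliably; dosages are restricted to the three diploid values for
identifiability at low coverage; dosage ties break toward the smaller
value; posteriors are computed with the log-sum-exp construction.

## Synthetic data

Two generators make every stage testable offline with planted truth.

**Expression mixtures** (`simulate_expression`) use a latent-factor
model: cells live in a 10-dimensional latent space where each cell type
has a center and a fixed random unit *shift direction*; blood cells sit
at the center, tissue cells are displaced by `delta` along the
direction, and all cells receive isotropic latent noise with sd
`within_sd`. Latent coordinates map to per-gene log-expression through
a random loading matrix over a baseline profile, then softmax +
multinomial sampling at a fixed library size. Planting the geometry in
a latent space — rather than directly in gene space — is what makes
`delta` and `within_sd` meaningful: the loading map amplifies the
coherent latent directions far above the count-sampling noise floor, so
the separation-to-noise ratio `delta / within_sd` is approximately what
any faithful embedding of the counts sees. Defaults (4 cell types, 250
cells/type/compartment, 1000 genes, 5000 reads/cell, `within_sd` 0.3,
`delta` 1.5 = 5 × `within_sd`, an equally sized blood-only reference)
define the standard evaluation condition; `delta = 0` is the matched
null. The generator deliberately omits dropout, ambient RNA and
batch structure, so passing tests demonstrate the geometry of the
method, not robustness to every artefact of real data.

**Allele counts** (`simulate_allele_counts`): per variant a population
MAF is drawn from Beta(1, 5) truncated to (0, 0.5]; per origin a dosage
from Hardy–Weinberg proportions at that MAF; cells are singlets (or
50/50 doublets at rate 0.05); depth is Poisson(2) per cell × variant
and alternate reads Binomial(depth, p) under the same read model the
fitter uses. Defaults (2 origins, 200 cells, 500 SNPs) are the standard
demultiplexing evaluation condition. Doublets are genetic only —
expression and genotype doublets are simulated independently, matching
the mosaic-doublet definition.

## Evaluation

`auc_score` is the rank-based (Mann–Whitney) AUC with midranks for
ties; `aucpr` is the step-summed area under the precision–recall curve
(trapezoids on PR are biased); `f_score` is 2PR/(P+R) with the
no-predicted-positives convention F = 0 + warning, and `macro_f1`
averages over the classes present in the truth. `benchmark_pipeline`
runs a pipeline over independently seeded replicates — five by default,
matching the replication protocol — and reports per-replicate and mean
metrics. For compartment AUC, each cell's `mean_ref_distance` is the
natural score for "tissue-ness".

Problem sizes in the shipped tests (chosen so the full suite exercises
the standard conditions while smaller unit fixtures stay instant): the
compartment benchmark runs the 4 × 250 × 2 condition over seeds 1–5
with the default UMAP embedding; unit tests use PCA and smaller
mixtures where only correctness of the plumbing is at stake.

## Known limitations

* The blood/tissue step assumes the whole-blood reference is on the
  same measurement scale as the query after CP10k/log1p; no explicit
  batch correction is applied beyond the shared transform.
* k = 2 presumes both compartments are present within each cell type;
  a type that is entirely blood-borne will still be split, though the
  null-control behaviour (AUC ≈ 0.5 at `delta = 0`) shows no systematic
  hallucination of separation against planted truth.
* The genotype model fixes 50/50 doublet composition and diploid
  dosages; unequal mixtures and copy-number variation are out of scope.
* Anchor-based origin labelling is defined for N = 2.
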