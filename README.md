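# scorigins

Deconvolution of barcoded single cells by **blood vs. tissue-resident
compartment** and by **genetic origin**.

## The problem

Dissociated tissue scRNA-seq inevitably captures immune cells that were
circulating in the tissue's blood vessels at collection time. These
blood-borne cells are transcriptionally close to genuine
tissue-resident immune cells of the same type, so they contaminate
every downstream comparison (differential expression, pathway
enrichment, cell–cell communication) unless removed. Tissues such as
the placenta add a second axis: cells from two genetically distinct
individuals (maternal and fetal) share one library. scorigins is for
anyone analysing solid-tissue scRNA-seq who needs either axis resolved.

## The methods

**Compartment classifier.** For each annotated immune cell type, query
cells and a whole-blood reference are embedded jointly: CP10k/log1p
normalization, top-2000 highly variable genes, z-scaled PCA to the top
*d* = 10 latent variables, optionally refined by UMAP (the default).
Each query cell *i* gets a distance profile
$D_{ij} = \lVert z_i - z_j^{\mathrm{ref}} \rVert_2$ over all reference
cells *j*; the profiles are clustered by k-means (*k* = 2), and the
cluster with the smaller mean distance to the reference is called
**blood**, the other **tissue**.

**Genotype demultiplexer.** From a per-cell × per-variant table of
ref/alt read counts, SNPs with population MAF > 10% are excluded
(boundary inclusive) and a binomial genotype-mixture model is fitted by
EM: origin *k* has diploid dosages $d_{kv} \in \{0, 0.5, 1\}$, a read is
alternate with probability $p = d(1-\varepsilon) + (1-d)\varepsilon$
(ε = 0.01). Mosaic doublets — one barcode with a 50/50 genetic mixture
of two individuals — are scored as pair-averaged dosage profiles under a
doublet prior (0.05); cells below a 0.8 posterior are `ambiguous`.
Origins are mapped to biological labels via an anchor cell type
(e.g. trophoblasts ⇒ fetal).

Synthetic generators with planted ground truth
(`simulate_expression()`, `simulate_allele_counts()`) and the
evaluation metrics (`auc_score()`, `f_score()`, `aucpr()`,
`benchmark_pipeline()`) make the whole pipeline testable offline. See
`vignettes/deconvolution-methods.Rmd` for the full model description.

## Worked example

```r
library(scorigins)

# --- blood vs. tissue ------------------------------------------------
sim <- simulate_expression(n_cell_types = 2,
                           cells_per_type_per_compartment = 100,
                           n_genes = 500, ref_cells_per_type = 80,
                           seed = 42)
fit <- classify_compartments(sim$query, sim$query_ann, sim$ref,
                             ref_ann = sim$ref_ann,
                             cell_types = c("type1", "type2"), seed = 42)
fit
#> Blood/tissue compartment classification
#>   400 cells: blood = 201, tissue = 199
#>   embedding: umap, d = 10, k = 2
auc_score(fit$calls$mean_ref_distance,
          sim$query_ann$compartment == "tissue")
#> [1] 0.999

# --- genetic origin --------------------------------------------------
gsim <- simulate_allele_counts(seed = 42)   # 2 origins, 200 cells, 500 SNPs
ac   <- filter_snps(gsim$counts)            # MAF <= 10% and covered
m    <- fit_genotype_mixture(ac, seed = 42)
m
#> genotype_mixture: 2 origins, 196 variants, 200 cells
#>   mixing weights: 0.477, 0.523
#>   log-likelihood -9675.93 after 4 EM iterations (converged)
table(call_doublets(ac, m)$call)
#>       0       1 doublet
#>      90      98      12
```

The classifier recovers the planted compartments almost perfectly
(AUC 0.999: blood cells sit close to the whole-blood reference in the
shared latent space, tissue cells are uniformly shifted), and the
mixture model splits the 200 cells into two origins near the simulated
50/50 mix, flagging 12 barcodes as mosaic doublets (10 were planted;
low-coverage singlets account for the difference at this depth).

A shell entry point wraps the same functions:

```sh
exec/scorigins simulate expression --out data --seed 1
exec/scorigins run --config config.yaml --seed 1
```

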