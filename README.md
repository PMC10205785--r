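# adept

Robust spatial-domain clustering of spatial transcriptomics (ST) data
with a graph attention autoencoder, differentially-expressed-gene (DEG)
list selection, and dropout imputation.

## Who this is for

Analysts of sequencing-based ST (10x Visium) or image-based ST
(STARmap-style) data who need to partition spots or cells into
spatially coherent domains — cortical layers, tumour regions — and want
a clustering that is robust to the dropout and quality variation that
plague ST matrices, plus a denoised expression matrix as a by-product.

## The method

Spots are nodes of a spatial k-nearest-neighbour graph (k = 6,
self-loops included, symmetrized). A graph attention autoencoder embeds
each spot: layer *l* of the encoder computes

> h⁽ˡ⁾(u) = ELU( Σ_{v ∈ N(u)} α_uv W⁽ˡ⁾ h⁽ˡ⁻¹⁾(v) ),

with attention coefficients α_uv obtained by a softmax over N(u) of
σ(aᵀ[W h(u) ⊕ W h(v)]), where σ is the sigmoid and ⊕ concatenation.
The encoder maps the normalized expression (library-size scaled,
log1p) through widths *g* → 512 → 32; a mirrored decoder reconstructs
the input, and Adam (lr 1e-3, weight decay 1e-5, 1000 iterations)
minimizes the mean squared reconstruction error. A full-covariance
Gaussian mixture model clusters the 32-dim embeddings.

Quality control and refinement both revolve around the **non-zero
rate** (fraction of non-zero matrix entries):

1. genes are filtered by the smallest minimum-count threshold that
   brings the matrix's non-zero rate to 0.14 (floor threshold 5 for
   high-quality data; skipped for image-based panels);
2. after an initial clustering, every gene is tested one-vs-rest per
   cluster with a Mann–Whitney rank-sum test (U = R − n(n+1)/2,
   min(U_x, U_y) driving a tie- and continuity-corrected normal
   p-value); candidate DEG list sizes whose top-gene unions have a
   non-zero rate inside 0.3–0.4 are selected;
3. for each selected list, the sub-matrix is re-embedded and
   re-clustered, and every zero entry is imputed by the mean of the
   non-zero values of its gene within its cluster
   (E[x_ij] = Σ_{j′∈cluster} x_ij′ / ‖cluster‖, dropout spots
   excluded); the K imputed matrices are averaged over their gene
   union;
4. a final embedding and clustering of the merged imputed matrix gives
   the domain labels.

The package also ships the external metrics used to evaluate such
clusterings (adjusted Rand index, Fowlkes–Mallows score, purity), a
cross-dataset method-ranking procedure, a synthetic layered-tissue
generator with planted markers and controlled dropout, Visium/tabular
readers and writers, and a small command line interface
(`inst/cli/adept.R`, launcher in `scripts/adept`).

## Worked example

```r
library(adept)

# synthetic cortical-layer tissue: 16 x 16 spots, 4 layers, 200 genes,
# 10 markers per layer, 30% dropout
sim <- simulate_layered_tissue(sim_config(seed = 1))
fit <- adept(sim$dataset, n_clusters = 4, seed = 1)
print(fit)
#> adept fit: 256 spots, 200/200 genes kept, 4 domains (seed 1)
#>   min-count threshold: 5
#>   DEG lists used: 2 (union of 94 genes)
#>   initial ARI: 0.6479  final ARI: 0.8348
```

The printed numbers mean: no gene fell below the minimum-count
threshold (the simulated data are high quality, so the floor threshold
5 applies); two DEG list sizes had union sub-matrices inside the
0.3–0.4 non-zero-rate window; and agreement with the generating layers
(adjusted Rand index) improved from 0.65 after the initial embedding to
0.83 after imputation and re-embedding. `labels(fit)` returns the
domain labels, `fitted(fit)` the denoised (imputed) matrix, and
`plot(fit)` draws the domains in space.

To score published method-by-dataset tables and rank tools:

```r
rank_methods(benchmark_scores("ari"))
#>            sum_rank avg_rank best
#> ADEPT            12      1.2    8
#> STAGATE          23      2.3    1
#> SpaGCN           35      3.5    1
#> CCST             41      4.1    0
#> SEDR             43      4.3    0
#> BayesSpace       56      5.6    0
```

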