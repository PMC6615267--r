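# oae — orthogonality-constrained Poisson autoencoders for interpretable single-cell analysis

`oae` is an R package for researchers who want a dimensionality
reduction of single-cell RNA-seq counts whose latent units can be *read*:
after specialized training, each hidden unit of a shallow autoencoder
tends to model one biological module, and gene-set saliency scores make
that correspondence explicit.  Typical users are computational biologists
who have a cells × genes raw count matrix, a GMT file of signatures
(e.g. MSigDB Hallmark or custom hematopoietic sets), and optionally a
per-cell grouping, and who want to know *which pathways drive which
latent directions* — for the whole dataset or as a contrast between two
cell populations.

## The model

A cells × genes count matrix is fed, raw and unnormalized, through an
autoencoder with hidden sizes 128 → 64 → 128 and SoftPlus after every
layer (so reconstructions ŷ are strictly positive rates).  Training
minimizes

    Loss = mean(ŷ − x·log(ŷ + ε)) + λ·‖I − WWᵀ‖_F

the Poisson negative log-likelihood of the counts plus a soft
orthogonality penalty on W, the final encoder weight matrix (rows =
representation units).  The penalty disentangles the 64-unit
representation layer; the count likelihood handles zero inflation without
any preprocessing.  Optimization is stochastic gradient descent with
Nesterov momentum at batch size 1 — one update per cell, no mini-batches —
with a seeded held-out cell fraction for early stopping.

Interpretation uses **guided backpropagation saliency maps**: the
gradient of one representation unit with respect to every input gene,
with negative gradients clipped at each nonlinearity on the backward
pass.  Mean |saliency| over cells, averaged over the genes of each set,
min–max scaled, yields a sets × units **impact matrix**; subtracting two
groups' unscaled scores and dividing by the maximum absolute difference
yields a signed contrast in [−1, 1].

## Worked example

Everything below is computed from the package's synthetic benchmark
generator, so it runs anywhere, with no external data.  We plant 3 gene
modules in 200 cells × 150 genes (plus 3 decoy gene sets), train, and ask
which hidden units the planted sets map to:

```r
library(oae)

bench <- default_benchmark(seed = 1, n_cells = 200, n_genes = 150,
                           n_modules = 3, genes_per_module = 25)
fit <- oae(bench$counts, grouping = bench$truth$grouping,
           layer_dims = c(32, 16, 32), seed = 1)
fit
#> Orthogonality-constrained Poisson autoencoder
#>   architecture: 150 -> 32 -> 16 -> 32 -> 150 (softplus)
#>   lambda: 0.1   learning rate: 0.001   momentum: 0.9
#>   trained: 100 epochs (best epoch 100)
#>   best test loss: 0.42474   ||I - WW'||_F: 0.0004
```

The penalty has driven the encoder rows essentially orthonormal
(‖I − WWᵀ‖_F ≈ 4·10⁻⁴).  Now score the six gene sets (3 planted, 3
decoys) against the 16 representation units:

```r
imp <- pathway_impact(fit, bench$counts, bench$signatures)
imp
#> Impact matrix (unit_interval): 6 sets x 16 units, from 200 cells
#>             U1    U2    U3    U4    U5    U6    U7    U8
#> module_1 0.424 0.002 0.435 0.326 0.275 0.109 0.324 0.512
#> module_2 0.519 0.001 1.000 0.240 0.277 0.133 0.358 0.339
#> module_3 0.465 0.000 0.581 0.216 0.445 0.093 0.366 0.706
#> decoy_1  0.331 0.002 0.450 0.200 0.251 0.100 0.287 0.331
#> ...

match_modules_to_units(unclass(imp)[1:3, ])$scores
#> module_1 module_2 module_3
#>    0.923    1.000    0.706
```

Each planted module is matched one-to-one (Hungarian assignment) to a
distinct hidden unit with impact 0.71–1.00, while the decoy sets stay in
the background band — the representation has deconvoluted the planted
programs.  The benchmark's group B doubles module-1 activity and halves
module-2 activity; the signed group contrast recovers exactly that, at
the matched units:

```r
labs <- as.character(bench$truth$grouping)
cmp <- compare_groups(fit, bench$counts[labs == "B", ],
                      bench$counts[labs == "A", ], bench$signatures)
m <- match_modules_to_units(unclass(imp)[1:3, ])
round(cmp[cbind(c("module_1", "module_2"),
                colnames(imp)[m$assignment[1:2]])], 3)
#> [1]  0.259 -0.635
```

positive for the doubled module, negative for the halved one.
`plot(imp)` draws the sets × units heatmap (high-impact rows only, by
default); `encode(fit, counts)` returns the 16-dimensional
representation, `embed_umap()` a seeded 2-D embedding of it, and
`kmeans_cluster()` + `nmi()` quantify clustering agreement between raw
input, representation and external labels.

A file-based workflow (simulate → train → impact → compare → evaluate)
with JSON run manifests is available both as R functions (`cmd_train`,
`cmd_impact`, ...) and as a thin command-line wrapper:

```sh
Rscript inst/cli/oae.R train --counts counts.tsv --signatures sets.gmt \
    --out fit/ --seed 1 --lambda 0.1
```

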