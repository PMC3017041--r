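# eigensig

PCA-based ranking of genes that express most differently between two groups
of assays in a gene × assay expression matrix.

Expression studies (microarray, bulk or single-cell RNA quantification)
produce matrices with tens of thousands of genes and a handful of assays.
When a principal component separates the assays into two biologically
meaningful groups — treated vs untreated, mutant vs wild-type — the natural
question is *which genes drive that separation*. `eigensig` answers it with
contribution statistics derived from the PCA itself, so the assay grouping
and the per-assay weights are driven by the data rather than imposed a
priori.

## The statistics

Let **X** be the m × n matrix of expression values x_ij (genes i, assays j)
and **Z** its column-standardized form, z_ij = (x_ij − x̄_j)/s_j.

* **Eigengene (EG) analysis** decomposes the assay correlation matrix of
  **Z**; component j has loading vector ℓ_j (one entry per assay) and
  scores S = Z L. The mean contribution of gene i to component j within an
  assay group A is ḡ_i^A = (1/n_A) Σ_{k∈A} ℓ_kj z_ik.
* **Eigenassay (EA) analysis** decomposes the gene covariance matrix of
  **X**ᵀ (computed through the n × n dual problem, so the m × m matrix is
  never formed); the group contribution of gene p is ℓ_pj · x̄_p^A on raw
  values.
* **T_diff** = ḡ^A − ḡ^B: the differential contribution, the package's
  primary ranking statistic.
* **T_scaled** = T_diff / [ s_pooled,z ·
  √(Σ_A ℓ²/n_A² + Σ_B ℓ²/n_B²) ]: T_diff divided by its estimated standard
  deviation (loadings treated as fixed). A unit-variance variant drops the
  per-gene pooled sd when assay variability is homogeneous.
* **T_pooled**: the classical pooled two-sample Student t per gene — the
  loading-free comparator. Scaling the EA differential contribution cancels
  the loading and reduces exactly to T_pooled, which is why no EA scaled
  statistic exists.

Signature sizes are chosen by the **inflection method** (cut at the largest
drop in the ranked-statistic curve) or by a **q-value threshold** (Storey
single-λ estimator on T_pooled p-values, df = n_A + n_B − 2).

## Worked example

```r
library(eigensig)

# simulate 4,000 genes x 10 assays; 100 planted genes shifted by delta = 1
# in the five Group-A assays, noise sd 0.2 around a baseline of 5.3
cfg <- simulation_config(m = 4000, n_sdg = 100, delta = 1, sigma = 0.2,
                         seed = 6)
ds  <- generate_dataset(cfg, trial_index = 1)

z <- standardize(ds$matrix)
d <- eigengene_decomposition(z, grouping = ds$grouping)
separation_report(d, 1, ds$grouping)
#> SeparationReport PC1: gap = 0.3995, normalized = 7.76, separated

s <- rank_genes(t_diff(eg_group_contributions(z, d, 1, ds$grouping)),
                "absolute")
s <- inflection_cutoff(s)
s
#> RankedSignature: 4000 genes (0 flagged), rank_by = absolute, cutoff = 100 (inflection)
length(intersect(signature_genes(s), ds$truth_ids))
#> [1] 100
```

PC1 cleanly separates the two assay groups (the between-group gap is nearly
eight times the within-group spread), and the inflection cutoff lands at 100 — exactly
the planted signature, with no false discoveries.

A command-line front end with `decompose`, `rank`, `cutoff`, `simulate` and
`benchmark` subcommands is installed at `inst/cli/eigensig`:

```sh
Rscript inst/cli/eigensig rank --matrix X.tsv --group-a 1,2,3,4,5 \
    --group-b 6,7,8,9,10 --statistic t_diff --mode EG --pc 1 --out ranked.tsv
```

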