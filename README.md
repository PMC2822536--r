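# bimodr

Detection, normalization and cross-study meta-analysis of **bimodally
expressed genes** in cohort-scale expression matrices (bulk microarray or
similar log-scale data).

In many disease cohorts a subset of genes does not vary smoothly across
samples but switches between two distinct expression levels — two *modes* —
that track a binary biological condition (amplicon status, receptor
subtype, tissue state). Such genes are natural binary biomarkers, but raw
intensities are notoriously incomparable across studies and array
platforms. `bimodr` implements a complete workflow for finding these genes,
putting them on a platform-independent −1/+1 scale, grouping the ones that
switch synchronously, and comparing results across datasets. It is aimed at
computational biologists doing expression meta-analysis and at
methodologists who want a fast, assumption-light alternative to
Gaussian-mixture fits.

## The method

For gene *i* with signals *e*<sub>*ij*</sub> across *M* samples, consider
every partition of the **sorted** signals into a lower subset *L* (the *k*
smallest values) and an upper subset *U*. The optimal partition minimizes
the within-subset sum of squares

  γ<sub>*i*</sub> = Σ<sub>*j*∈*L*</sub> (*e*<sub>*ij*</sub> − *l*<sub>*i*</sub>)² + Σ<sub>*j*∈*U*</sub> (*e*<sub>*ij*</sub> − *u*<sub>*i*</sub>)²,

where *l*<sub>*i*</sub> = ⟨*L*⟩ and *u*<sub>*i*</sub> = ⟨*U*⟩ are the subset
means — the classical one-dimensional two-means objective, solved exactly by
an O(*n*) scan over the *n* − 1 admissible splits. The split defines a
threshold *T*<sub>*i*</sub> = (max *L* + min *U*)/2 and a t-like separation
statistic

  τ<sub>*i*</sub> = (*u*<sub>*i*</sub> − *l*<sub>*i*</sub>) / √(γ<sub>*i*</sub>/*M*).

For iid Gaussian signals τ converges to 2·√(2/π)/√(1 − 2/π) ≈ **2.647**
(optimal split at the mean; half-normal moments), so τ above ~2.64 flags a
wider-than-normal, typically bimodal, distribution. Supporting machinery:
a <5% small-subset outlier rule, a standard-deviation percentile filter,
piecewise-linear **bimodal normalization** sending (*l*, *T*, *u*) to
(−1, 0, +1) (exactly invariant under per-gene affine platform distortions),
control-sample orientation of the scale, cosine-distance **"close
neighbors"** group discovery with per-sample **barcoding** (e.g. `1-2-1`),
and one-sided hypergeometric (Fisher) enrichment computed in log space.

## Worked example

```r
library(bimodr)

sim <- simulate_cohort(simulation_config(n_genes = 500, n_samples = 150,
                                         n_groups = 2, group_size = 4,
                                         n_controls = 10, seed = 42))
d <- sim$datasets[[1]]
fits <- detect_bimodal(d)             # tau > 2.64 + sd filter, 5% outlier rule
fits[fits$is_bimodal, c("gene", "n", "l", "u", "T", "tau")][1:3, ]
#>     gene   n        l        u        T      tau
#> 2 G00002 150 3.875245 4.705945 4.296679 2.653838
#> 4 G00004 150 5.782691 8.792661 7.310316 6.445862
#> 5 G00005 150 4.901972 7.854354 6.597574 5.818821

norm <- orient_by_controls(normalize_dataset(d, fits), d, fits)
norm
#> NormalizedDataset: 259 genes x 150 samples (as-is 51, flipped 0, excluded 208)

grp <- find_close_group(sim$truth$group_membership$group1[1], norm)
grp
#> GeneGroup 'G00292': 4 members
#>   G00292 (d=0.000)
#>   G00367 (d=0.219)
#>   G00297 (d=0.236)
#>   G00500 (d=0.243)

head(barcode_samples(list(grp), norm), 3)
#>       sample barcode    G00292
#> S0001  S0001       2 1.0453745
#> S0002  S0002       2 0.8885319
#> S0003  S0003       2 0.7585166

hypergeom_enrichment(866, 609, 69, 40599)
#> Enrichment: 69/866 of list in annotation (609 of 40599 in universe)
#>   one-sided p = 1.169e-29 (log10 p = -28.93)
```

Reading the output: each fitted gene reports its lower/upper mode means
(`l`, `u`), the inter-mode threshold `T` and the separation `tau`; `G00002`
sits barely above the Gaussian baseline while the planted bimodal genes
score τ ≈ 6. Orientation against the 10 control samples keeps the 51 genes
whose controls fall cleanly in one mode (the 208 excluded genes are
borderline calls whose controls straddle the threshold — a useful
specificity screen in itself). The recovered group is exactly the planted
4-gene module, and each sample's barcode digit reads the group's mode
(`2` = control-like mode, group mean ≥ 0).

The same pipeline is scriptable from a shell via the installed wrapper:

```sh
bimodal detect --matrix expr.tsv --out fits.tsv
bimodal normalize --matrix expr.tsv --fits fits.tsv --controls samples.tsv --out norm.tsv
bimodal groups --norm norm.tsv --query ERBB2 --out group_ERBB2.tsv
```

(see `system.file("scripts", "bimodal", package = "bimodr")`).

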