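# nirmreg

Bayesian semiparametric regression of observed on expected amino-acid
property distances, for detecting codon sites that conserve or radically
change physicochemical properties in protein-coding alignments.

## What it does

Given a codon alignment with reconstructed ancestral sequences and a rooted
phylogeny, `nirmreg` computes, per codon site *i* and property *j* (e.g.
hydropathy, molecular volume, polarity):

* the observed mean distance *y*<sub>ij</sub> — mean |score difference|
  over the nonsynonymous substitutions at site *i* read off parent–child
  node pairs;
* the expected mean distance under single-step neutral mutation
  *x*<sub>ij</sub> = Σ<sub>k</sub> F<sup>i</sup><sub>k</sub>
  Σ<sub>l</sub> D<sup>ij</sup><sub>kl</sub> ⁄ Σ<sub>k</sub>
  F<sup>i</sup><sub>k</sub> N<sub>k</sub>, a codon-frequency-weighted
  average over the ≤ 9 single-nucleotide neighbors of each codon.

Both are standardized to [0, 1] by the property's maximum pairwise score
difference and related by the regression

y\*<sub>ij</sub> ~ N(β<sub>ij</sub> x\*<sub>ij</sub>, σ²<sub>ij</sub> ⁄ n<sup>O</sup><sub>i</sub> if β<sub>ij</sub> ≠ 0, else σ²<sub>ij</sub>),

so β ≈ 1 means neutrality, β ≪ 1 conservation, β ≫ 1 radical change, and
β = 0 exact conservation. The matrix [β<sub>ij</sub>, σ²<sub>ij</sub>]
carries a **nested infinite relational model** prior — a stick-breaking
Dirichlet process clustering correlated *properties*, and within each
property cluster a nested Dirichlet process clustering *sites*, with a
spike-and-slab base measure putting positive mass on β = 0. Inference uses
a truncated blocked Gibbs sampler; all summaries (pairwise co-clustering
probabilities, per-cell posterior means/quantiles) are label-invariant.

The package also ships the distance layer (genetic code, codon
neighborhoods, Fitch-parsimony ancestral fallback), seven embedded
property scales, two simulation-study generators (block-structured
coefficients; codon sequences under property-conserving/-radicalizing
substitution regimes), broom-style `tidy()`/`glance()` methods, ggplot2
`autoplot()`s, and a thin CLI (`inst/cli/nirmreg.R`) with
`simulate | distances | fit | summarize` subcommands.

## Worked example

Block-structured data with four property clusters (16 properties, 40
sites, eight blocks, coefficients from N(1, 0.25), noise variance 0.001),
fitted with five pooled random-partition chains:

```r
library(nirmreg)

sim <- simulate_block_data(sim_block_scenario(n_sites = 40, n_properties = 16,
                                              row_clusters = c(2, 2, 2, 2)),
                           seed = 1)
fit <- fit_nirm(sim$data, K = 15, L = 15, iterations = 3000, burn_in = 1000,
                thin = 2, hyper = simulation_hyperpriors(), seed = 101,
                chains = 5)
fit
#> Nested-DP property-distance regression fit
#>   40 sites x 16 properties; K = 15, L = 15
#>   5000 retained draws (5 chains, 3000 iterations, 1000 burn-in, thin 2)
#>   posterior modal number of property clusters: 4
```

The posterior modal number of property clusters equals the generating 4.
Pairwise co-clustering probabilities recover the generating partition
(properties 1–4, 5–8, 9–12, 13–16):

```r
round(cocluster_properties(fit)[c(1, 4, 5, 8, 9, 12, 13, 16),
                                c(1, 4, 5, 8, 9, 12, 13, 16)], 2)
#>     P01 P04 P05 P08 P09 P12 P13 P16
#> P01 1.0 1.0 0.2 0.2   0   0   0   0
#> P04 1.0 1.0 0.2 0.2   0   0   0   0
#> P05 0.2 0.2 1.0 1.0   0   0   0   0
#> P08 0.2 0.2 1.0 1.0   0   0   0   0
#> P09 0.0 0.0 0.0 0.0   1   1   0   0
#> P12 0.0 0.0 0.0 0.0   1   1   0   0
#> P13 0.0 0.0 0.0 0.0   0   0   1   1
#> P16 0.0 0.0 0.0 0.0   0   0   1   1
```

(The 0.2 entries are one of the five chains holding two close clusters
together — exactly the ambiguity the pooled co-clustering matrix is meant
to expose.) Per-cell posterior summaries classify each site × property:

```r
head(beta_summary(fit)[beta_summary(fit)$property == "P01", ], 3)
#>    site property beta_mean p_zero  q2.5   q25   q50   q75 q97.5 class
#> 1     1 P01          0.676      0 0.632 0.675 0.683 0.688 0.697 conserved
#> 2     2 P01          0.676      0 0.632 0.675 0.683 0.688 0.697 conserved
#> 3     3 P01          0.676      0 0.632 0.675 0.683 0.688 0.697 conserved
```

and the posterior means track the generating coefficients at r = 0.995.
For sequence data, `simulate_codon_sequences()` →
`fitch_ancestral()`/your own reconstruction → `distance_data()` →
`fit_nirm()` chains the full pipeline; `cocluster_sites(fit, "h")` and
`plot_beta_sites(fit, "h")` summarize the site level.

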