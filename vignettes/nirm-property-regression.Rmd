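---
title: "Semiparametric regression of amino-acid property distances with a nested Dirichlet-process prior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semiparametric regression of amino-acid property distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirmreg)
library(dplyr)
```

## The scientific problem

Whether a codon site in a protein-coding gene tolerates amino-acid change
depends on which *physicochemical properties* the encoded residue must
preserve. A site may accept substitutions freely as long as, say,
hydropathy is maintained, while changing volume radically. `nirmreg`
quantifies this per site and per property by comparing, for each codon site
$i$ and property $j$,

* the **observed mean distance** $y_{i,j}$: the mean absolute difference in
  property score over all nonsynonymous substitutions inferred at site $i$
  (substitutions are read off parent–child node pairs of a phylogeny whose
  internal nodes carry reconstructed ancestral sequences), and
* the **expected mean distance** $x_{i,j}$: the neutral single-step
  expectation
  $$x_{i,j} = \frac{\sum_k F_k^i \sum_l D^{i,j}_{k,l}}{\sum_k F_k^i N_k},$$
  a codon-frequency-weighted average of score differences over all
  single-nucleotide nonsynonymous neighbors ($F_k^i$ is the frequency of
  codon $k$ among the extant sequences at site $i$, $N_k$ the number of
  nonsynonymous single-step neighbors of codon $k$, and $D^{i,j}_{k,l}$ the
  absolute score difference for neighbor pair $(k,l)$).

Both are standardized by the property's maximum pairwise score difference,
so every property lives on $[0,1]$ and the regression coefficients share a
common prior scale. Sites with no nonsynonymous change, no possible
single-step nonsynonymous mutation, or an alignment gap in any sequence are
removed before modeling.

## The model

The standardized distances are related through a heteroscedastic regression
through the origin:
$$y^*_{i,j} \mid \beta_{i,j}, \sigma^2_{i,j} \sim
  \begin{cases} N(\beta_{i,j} x^*_{i,j},\; \sigma^2_{i,j}) & \beta_{i,j} = 0\\
                N(\beta_{i,j} x^*_{i,j},\; \sigma^2_{i,j}/n_i^O) & \beta_{i,j} \neq 0,
  \end{cases}$$
where $n_i^O$ is the number of observed nonsynonymous changes at site $i$:
a site observed many times is measured more precisely. $\beta_{i,j}
\approx 1$ means neutrality with respect to property $j$; $\beta_{i,j} \ll
1$ conservation; $\beta_{i,j} \gg 1$ radical change; $\beta_{i,j} = 0$
exact conservation (possible because chemically similar residues can share
a score).

Properties are correlated — hydropathy and polarity track each other
closely — so treating the $J$ columns of $[\beta_{i,j}]$ as independent
wastes information and multiplies parameters. The prior on the matrix
$[\theta_{i,j}] = [\beta_{i,j}, \sigma^2_{i,j}]$ is a **nested infinite
relational model**: a stick-breaking Dirichlet process
$$F = \sum_{k=1}^{\infty} \Pi_k \delta_{\theta^*_k}, \qquad
  \Pi_k = v_k \prod_{s<k}(1 - v_s),\; v_k \sim \mathrm{Beta}(1, \rho)$$
clusters property *columns*; within column cluster $k$ a second
stick-breaking process with weights $w_{l,k}$ (sticks
$\mathrm{Beta}(1,\gamma_k)$) clusters *sites*, and each (site cluster,
property cluster) atom $\varphi_{l,k} = (\phi_{l,k}, \vartheta^2_{l,k})$ is
drawn from a spike-and-slab base measure
$$G_{0lk} = \lambda\, 1\{\phi_{l,k} = 0\}\, p_1(\vartheta^2_{l,k}) +
  (1-\lambda)\, N(\phi_{l,k} \mid \alpha_k, \vartheta^2_{l,k}/V_0)\,
  p_2(\vartheta^2_{l,k}),$$
with inverse-gamma $p_1, p_2$. The spike gives positive posterior mass to
*exact* conservation; the nested structure clusters correlated properties
and, within each property group, sites with a common coefficient. Both
sites and properties are exchangeable a priori.

Hyperpriors are conjugate throughout: $\rho, \gamma_k \sim
\mathrm{Ga}(1,1)$, $\lambda \sim \mathrm{Beta}(2,8)$ (about 20% of unique
coefficients expected to be exactly zero a priori), $\alpha_k \sim N(1,
0.25)$ (prior neutrality). Throughout the package an inverse-gamma
$\mathrm{IG}(a, b)$ has density $\propto x^{-(a+1)} e^{-1/(bx)}$ and mean
$1/\{b(a-1)\}$; the defaults $\mathrm{IG}(2, 100)$ (spike variance, mean
0.01), $\mathrm{IG}(2, 10)$ (slab variance, mean 0.1) and $V_0 = 10$ (the
ratio of the two variance means) are the settings used for sperm-lysin
style analyses of real alignments. This is the only parameterization under
which those printed prior means are consistent, which is why the package
adopts it everywhere.

## Posterior computation

Inference is by a blocked Gibbs sampler on the finite stick-breaking
truncation: the column process is cut at $K$ atoms ($v_K = 1$) and each row
process at $L$ ($u_{L,k} = 1$). Conditional on a concentration guess, the
expected truncation error is $\{\rho/(1+\rho)\}^{K-1}$;
`choose_truncation(rho, tol)` inverts this, and values of 25–35 are
typical. One sweep updates, in order: column indicators $\zeta_j$
(categorical over $K$, computed in log space with max-subtraction), column
sticks, row indicators $\xi_{i,k}$ for *every* $k$ — clusters owning no
columns fall back to their prior weights, keeping the nested partition
well defined for any column move — row sticks, atoms, $\lambda$,
$\alpha_k$, and the concentrations $\rho, \gamma_k$ via the standard
auxiliary-variable beta/gamma-mixture step.

Atoms are updated jointly: the spike indicator $\psi_{l,k}$ is drawn from
its marginal (both $\phi$ and $\vartheta^2$ integrated out in closed
form — a normal-inverse-gamma marginal likelihood on each side), then
$\vartheta^2_{l,k}$ from its inverse-gamma conditional and $\phi_{l,k}$
from its normal conditional. In the likelihood terms of the indicator
updates the variance is $\vartheta^2_{l,k}$ when $\phi_{l,k} = 0$ and
$\vartheta^2_{l,k}/n_i^O$ otherwise, per site.

One subtlety deserves a note. The stick conditionals count *indicators*:
$m_k$ columns for the column sticks and the number of *sites* assigned to
each row atom for the row sticks — one row indicator exists per (site,
column cluster) and is shared by all columns in the cluster. Counting
cells instead (sites × columns) looks superficially plausible but is
inconsistent with the generative construction in which each indicator is a
single categorical draw; the package's successive-conditional
(Geweke-style) validation test distinguishes the two and passes only with
indicator counts.

### Initialization and multimodality

Chains are initialized randomly: column indicators by a *balanced random*
assignment that spreads columns across distinct clusters, row indicators
uniformly, atoms from the base measure, scalars from their priors. The
dispersed column start matters. If two truly distinct column clusters are
placed together at initialization, the early compromise fit inflates the
shared atom variances, and that variance-inflated merged state is
essentially absorbing for a conditional sampler of this kind: leaving it
requires freshly drawn prior atoms to outfit an adapted (if wrong)
configuration in one step. Starting dispersed means merges only happen
when the likelihood genuinely favors them. Even so, when two column
clusters are moderately close the sampler can occasionally freeze them
together; split–merge moves, the standard remedy, are outside this
package's scope, so the practical guidance is the multi-chain protocol:
run several chains (`chains = 3` or `5`; `fit_nirm()` pools the draws) and
compare per-chain traces via `tidy()`/`autoplot()`. No relabeling is ever
attempted; every reported summary — pairwise co-clustering probabilities,
per-cell posterior means and quantiles — is invariant to label switching
by construction.

### Numerical policy

Categorical updates subtract the row maximum before exponentiating; a state
in which every candidate has zero probability raises an error rather than
sampling arbitrarily. Variances are never clamped: a computed non-positive
inverse-gamma scale (mathematically impossible) or an underflowing
variance raises an error, since either signals an implementation defect,
not a numerical nuisance. Quantiles of nonzero coefficient draws are
reported as `NA` when every draw sits in the spike.

## Shipped property scales

Seven classical scales are embedded: Kyte–Doolittle hydropathy (`h`),
Grantham molecular volume (`M_v`), polarity (`p`) and composition (`c`),
Zimmerman isoelectric point (`pH_i`), residue molecular weight (`M_w`) and
Cohn–Edsall partial specific volume (`V^0`). These are score sets whose
published values are unambiguous; analyses needing other scales supply an
AAindex-style TSV via `read_property_table()`. Users should be aware of
what the scales measure: partial specific volume is a *per-gram packing*
quantity dominated by aliphatic hydrophobics, so its distances track
hydropathy (rank correlation about 0.5 over single-step nonsynonymous
codon pairs) and are nearly uncorrelated with molecular-volume distances —
a chemical fact that shapes which properties co-cluster (see the
simulation discussion below).

## What the generators emulate

### Block-structured coefficients

`simulate_block_data()` draws a block-structured coefficient matrix —
property clusters, nested site groups, one coefficient per block from
$N(1, 0.25)$ — and observations $y^* = \beta x^* + \varepsilon$,
$\varepsilon \sim N(0, 0.001)$. Defaults are 94 sites, 32 properties, four
property clusters and twelve blocks. Real expected distances can be
supplied; otherwise $x^*$ is uniform on $(0.2, 0.9)$, chosen to span the
informative part of the standardized scale. For fitting such data the
package provides `simulation_hyperpriors()`, which matches the
variance-component prior means to the generating values (observation
variance 0.001, coefficient variance 0.25, hence $V_0 = 0.004$): with the
real-data defaults ($V_0 = 10$) the slab prior couples the coefficient
spread to a tiny observation variance and shrinks block coefficients
toward the cluster mean, which is appropriate for distance data on the
natural scale but not for this synthetic design. This generator exercises
the sampler exactly: the model's likelihood is the generating likelihood.

What it does *not* emulate: distance data derived from sequences have
heteroscedastic, non-Gaussian residuals, zeros from score-identical
substitutions, and $x^*$ correlated across properties; passing recovery
tests on block data therefore validates the *inference machinery*, not the
distance layer.

### Sequences under property-biased regimes

`simulate_codon_sequences()` evolves codon sequences down a balanced
genealogy under a GY94-style Markov process restricted to single-nucleotide
changes: transition/transversion ratio $\kappa = 2$, uniform codon
frequencies, synonymous and nonsynonymous changes at equal baseline rate,
rescaled to one expected substitution per codon per unit branch length.
Disjoint site regions follow regimes: `conserve(p)` multiplies each
nonsynonymous rate by $e^{-b\,d_p/d_{p,\max}}$, `radicalize(p)` by
$e^{+b\,d_p/d_{p,\max}}$, after which the generator is rescaled to unit
mean rate (so regimes differ in *which* changes happen, not how many).
Defaults: 20 sequences of 90 codons; sites 1–30 neutral, 31–60 conserving
volume, 61–90 radicalizing hydropathy; branch length 0.2; $b = 6$. The
bias default was calibrated against the generator's own behavior: at
$b = 6$ the conserve region's mean per-substitution volume distance is
roughly half the neutral value (a regime that plainly "conserves volume"),
while $b = 3$ barely moves it and $b \geq 9$ starts to freeze the process.
The published description of this design is qualitative, and the
exponential tilting here is one concrete realization of it.

`simulate_distance_data()` runs the full pipeline on such sequences,
reconstructing ancestral sequences with codon-level Fitch parsimony
(deterministic, lexicographic tie-breaks). Parsimony systematically
undercounts multiple hits relative to model-based reconstruction, so
observed distances — and hence fitted coefficients — are attenuated
relative to what a codon-model reconstruction would give; the fallback
exists to keep the pipeline self-contained and testable, and production
analyses should supply node-labeled reconstructed sequences.

A consequence of the scale chemistry noted above: in this design the
radical-hydropathy region necessarily also radicalizes partial specific
volume, so the fitted model robustly pairs `h` with `p` but tends to place
`V^0` with the hydropathy pair rather than with `M_v`, and the isoelectric
point often rides along (radical hydropathy changes involve charged
residues). Recovering a clean three-cluster structure
$\{h,p\},\{M_v,V^0\},\{pH_i\}$ would require a volume-correlated `V^0`
score set, which the embedded scales do not provide.

## Problem sizes used in the test suite

The automated checks run, by design, at desk scale: sampler-vs-oracle
agreement on $2\times2$ problems; prior recovery and Geweke-style
joint-distribution checks on a $4\times3$ matrix with $K=L=3$; block
recovery at 40 sites × 16 properties (four clusters, eight blocks,
$K=L=15$, 3000 iterations, 1000 burn-in); and the sequence design at its
published size (20 × 90 codons). These sizes were chosen so each check
isolates one claim — correctness of the conditionals, stationarity,
structure recovery — at the smallest size where the claim is meaningful.

## Known limitations

* No split–merge or marginal (Pólya-urn) moves: multimodal posteriors with
  nearly-overlapping column clusters can trap single chains (see above);
  use several chains.
* Sites are exchangeable a priori; no spatial or structural dependence
  along the sequence.
* Alignment, phylogeny and ancestral-reconstruction uncertainty is not
  propagated; distances are treated as data.
* One substitution event is counted per parent–child codon pair whose
  amino acids differ, regardless of how many nucleotides changed.
* The classification bands in `beta_summary()` are reporting conventions;
  only the strong-conservation cutoff (posterior mean < 0.4) is anchored
  in published practice, and the radical cutoff (default 1.2) is a
  documented convention exposed as a parameter.
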