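---
title: "Methods: diversity, co-occurrence networks and drivers along salinity gradients"
author: "saltgrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, co-occurrence networks and drivers along salinity gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`saltgrad` analyses bacterial and archaeal ASV tables collected along a
natural salinity gradient: alpha diversity and its group contrasts,
community dissimilarity and its permutation tests, sparse co-occurrence
network inference, assembly-process classification of network links,
community cohesion and spectral fragility, stress-threshold gradient
models, and a random-forest / mixed-model / piecewise-SEM driver cascade.
A synthetic-community generator with planted ground truth exercises every
stage end to end, so the pipeline's quantitative guarantees (edge
recovery, process classification, threshold and driver recovery, error
control) are tested against known truth rather than asserted.

# The data model

The central container is `AsvExperiment`, a `SummarizedExperiment` with a
single `counts` assay (taxa as rows, samples as columns), per-sample
metadata in `colData` (salinity in psu, the three-way stress class, nine
soil variables, climate, coordinates, wetland id) and a domain tag
(bacteria, archaea, or `multi` for concatenated cross-domain tables).
Stress classes follow the standard wetland classification: freshwater at
salinity <= 1 psu, brackish in (1, 35], saline above 35 psu, with closed
boundaries exactly as printed.

Counts are rarefied by seeded subsampling without replacement (a
multivariate hypergeometric draw per sample), because rarefaction depth
equalisation should not introduce replacement noise; all-zero taxa are
kept and flagged so taxon indices remain stable. Two compositional
transforms are provided: the Hellinger transform (square root of relative
abundance; the input to Bray-Curtis dissimilarity) and the centered
log-ratio (CLR) transform with a configurable pseudocount (default 1),
the standard pre-step for covariance-based network inference on
compositions.

# Network inference

Co-occurrence networks are inferred from CLR-transformed counts by sparse
regression along a 30-point log-spaced lambda path: Meinshausen-Buhlmann
neighborhood selection by default (a lasso of each taxon on all others,
OR-symmetrised, which is robust at moderate sample sizes), or a graphical
lasso solved by block coordinate descent for users who prefer a joint
precision estimate. The regularisation level is chosen by StARS: 50
subsamples of size min(10 sqrt(n), 0.8 n), per-lambda edge instability
D = mean 2 xi (1 - xi) over selection frequencies xi, monotonised from
the sparse end, and the densest lambda with instability at or below 0.05
is selected. Edge weights are the symmetrised maximum-magnitude lasso
coefficients at the selected lambda; the sign of the weight is the edge
sign (co-presence vs mutual exclusion). Provenance (method, lambda path,
instability path, subsample plan seed) is stored with every network so
results are reproducible from the object alone.

Taxa enter the global network only if observed in strictly more than 20%
of samples with total abundance strictly greater than 100 reads;
per-habitat sub-networks are induced subgraphs on taxa exceeding 30%
within-habitat occurrence and 100 mean reads, with edges inherited from
the global network. The strict inequalities are deliberate and tested.

# Link-process classification

Each network link is assigned an assembly process by sequential
Mantel-type permutation tests on its co-variation signal: for edge
(i, j) the signal is the Euclidean distance between samples in the
two-dimensional space of the pair's CLR values. The signal is correlated
(Spearman, one-sided) against great-circle geographic distance first and
environmental dissimilarity (Euclidean on standardised metadata columns)
second, with Benjamini-Hochberg adjustment across edges within each test
family; significant-vs-geography links are labelled spatial, then
significant-vs-environment links environmental, and the residue is the
putative biotic set. Zero-variance signals are flagged degenerate and
excluded from the biotic set rather than guessed.

A consequence worth understanding: under a blocked survey design
(replicates clustered within sites, salinity constant within sites), any
link whose taxa respond to site-level conditions has a signal that
correlates with both geography and environment, and the sequential filter
legitimately assigns it to those processes. Only links whose co-variation
is site-independent (as with the generator's copula couplings) survive as
biotic. This is a property of the method, not a defect; but it means the
biotic subgraph can be very sparse in strongly structured data.

# Cohesion and fragility

Per-taxon connectedness is the mean of the taxon's positive (respectively
negative) link weights, zero when it has none. Per-sample cohesion is the
relative-abundance-weighted sum of connectedness over taxa — a
community-level complexity score computed separately for positive and
negative associations, and for bacteria-archaea links only in the
cross-domain variant. Because of the sparsity consequence above, the
pipeline computes cohesion from the full inferred network by default
(matching the original formulation of the cohesion metric); restricting
to the biotic subgraph is available via `use_biotic = TRUE`, with an
automatic, manifest-flagged fallback to all links when the biotic
subgraph is edgeless.

Robustness is summarised by natural connectivity, the log-mean of the
exponentials of the adjacency eigenvalues (computed with a max-shift to
avoid overflow), on the unweighted adjacency by default. Fragility
removes nodes iteratively — by recomputed degree, recomputed weighted
betweenness, or uniformly at random — and reports the natural-connectivity
curve over a removal-fraction grid plus two summaries: the endpoint drop
and one minus the normalised area under the relative curve. Both are
emitted because the field has no single convention.

# Gradient models and the driver cascade

Responses along the gradient are modelled on log10(salinity) — the
gradient spans more than three orders of magnitude — with three fits:
ordinary least squares; a single-breakpoint segmented regression found by
profile grid search over the interior 5-95% quantile range (201 points),
whose searched breakpoint counts as one extra AIC parameter; and a
penalised cubic spline (GCV-chosen smoothness) as the non-linear
reference. The best model is the lowest-AIC fit with a 2-unit
indifference band favouring the simpler model. Breakpoints are reported
on both the log scale and in psu.

Taxon responders are ranked by Spearman correlation of relative abundance
with salinity, BH-adjusted. Driver screening uses a regression random
forest with response-permutation significance (the forest is refit on
permuted responses; p is the fraction of null importances reaching the
observed one); mixed-model associations use a wetland random intercept,
type-II Wald chi-square tests, BH adjustment, and Nakagawa marginal /
conditional R-squared. The piecewise SEM fits each structural equation as
a linear (mixed) model on standardised variables, derives the
d-separation basis set from the DAG (every non-adjacent pair, the
topologically later variable regressed on both variables' parents plus
the earlier one), and summarises the claims with Fisher's C = -2 sum
ln p, df = twice the number of claims, accepting structure under the
conventional rule 0 < C/df < 2 with p > 0.05. Composite variables are
first principal components of their standardised indicators, sign-aligned
with the first indicator. When a response is constant within the grouping
factor (salinity in a one-value-per-wetland design), its equation is
fitted on group means instead of pseudo-replicating 10 identical values
per wetland.

# The synthetic generator

The generator emulates the study design the pipeline targets: 20 wetlands
x 10 replicates (200 samples), wetland-level salinity spread
log-uniformly over 0.2-440 psu so all three stress classes occur,
replicate coordinates clustered within about a kilometre of their wetland
centre on a Tibetan-Plateau-like extent, and nine soil variables plus
climate with fixed loadings on log-salinity plus noise. Latent
log-abundances sum a Gaussian niche response on the log10(psu) axis
(with an optional strongly negative baseline that turns a taxon into a
habitat specialist, effectively absent away from its optimum), an
optional spatially autocorrelated field (exponential covariance over
great-circle distances), shared-factor couplings for planted edges (the
pairwise latent correlation equals the configured coupling strength; a
shared-factor construction rather than one global copula covariance so
the "sgh" scenario can scale coupling strength with stress), an optional
facilitation factor, and iid noise; counts are one multinomial draw per
sample at fixed depth (default 10,000, the order of typical rarefaction
depths, which keeps tests fast).

Three presets carry the planted ground truth. `null` has no structure and
backs every false-positive check. `sgh` strengthens positive couplings
with the standardised stress level. `paper_like` plants the full
qualitative pattern: a third of bacterial taxa are stress-sensitive, each
with its own threshold on a facilitation/stress factor F (standardised
log-salinity plus wetland noise of sd 1.0 and microsite noise of sd 0.4),
so bacterial richness declines approximately linearly along the gradient
and is mediated by F rather than salinity itself; a positively coupled
bacterial block is boosted by F, so measured positive cohesion tracks the
same factor and emerges as the top standardised predictor of bacterial
richness; archaea combine a low-salinity specialist block with a
halophile block (55% of taxa, niche onset around log10(psu) 1.3), giving
a non-monotone richness curve with a brackish minimum and a saline peak
driven directly by salinity.

Several generator choices were settled by design-phase experimentation
and then frozen, because the observation layer is harsher than intuition
suggests: a specialist must sit roughly 5 latent log-units below the
neutral baseline to clear the multinomial detection floor at depth 10^4;
two-sided stress responses create compositional blow-ups that invert
richness patterns, so suppression is one-sided above a per-taxon
threshold; and without microsite (within-wetland) variation in F, a mixed
model reattributes the mediated cohesion signal to salinity, because the
within-wetland slope it blends in carries no signal. The within-wetland
environmental heterogeneity of the soil variables is exposed as a knob
(`within_wetland_sd`) rather than fixed, since field designs differ.

What the generator does not emulate: sequencing error and chimeras,
variable library sizes, phylogenetic correlation among taxa, temporal
dynamics, and taxon-specific detection biases. Passing recovery tests on
these synthetic communities therefore demonstrates that the estimators
recover what they claim from compositional multinomial data at realistic
scale — not that any particular field dataset satisfies the generative
assumptions.

# Numerical and design choices

* Rarefaction is seeded, one-pass, without replacement; errors list the
  offending shallow samples.
* CLR pseudocount defaults to 1 and is configurable; zero and negative
  values are rejected.
* PERMANOVA, ANOSIM, MRPP, Mantel and partial Mantel and the dbRDA
  models are delegated to vegan (with closed-form and
  exhaustive-enumeration oracles in the test suite); Mantel statistics
  default to Spearman and 999 permutations.
* dbRDA forward selection uses Lingoes correction for negative
  eigenvalues and Blanchet-style double stopping: candidates enter while
  their conditional permutation p is at or below alpha, and selection
  halts once the cumulative adjusted R-squared reaches the full model's
  (the crossing variable is kept — rejecting it can discard a genuine
  lone gradient whenever noise covariates depress the full-model
  adjusted R-squared below its single-variable value). A significant
  global test is required before any selection.
* The LSD test is the classic unprotected variant (pairwise t on the
  pooled ANOVA error), with an optional omnibus gate; Cohen's d uses the
  pooled-SD form without small-sample correction, with magnitude bands
  negligible/small/medium/large at |d| = 0.2, 0.5, 0.8.
* The segmented fit marks itself unsupported when no interior breakpoint
  improves the SSE; AIC comparisons always include its searched
  breakpoint as a parameter.
* StARS instability is monotonised from the sparse end; non-informative
  lambdas are simply never selected.
* Network edge signs must match their weights' signs; this is enforced by
  class validity, not convention.
* The pipeline's stage manifest records parameters, seeds and elapsed
  time per stage. Content-hash stage caching was considered and dropped:
  at the problem sizes this package targets every stage re-runs in
  seconds, and a cache adds binary state that complicates reproducibility
  more than it saves.

# Problem sizes

The test suite and the acceptance script run the pipeline at reduced but
non-trivial scale — 90 bacterial and 50 archaeal taxa over the full
200-sample design for end-to-end runs, 50-100 taxa for network recovery,
25-50 seeded replicates for classification and recovery rates — sizes at
which every stage's statistical behaviour is already representative while
a complete run stays in the minutes range on one core.

# Known limitations

The sequential link classification inherits the identifiability limits of
distance-based tests: site-structured biotic effects are indistinguishable
from environmental ones by construction. The mixed models use a single
random intercept (no random slopes), matching the design they target. The
SEM assumes linear Gaussian equations and tests only the specified
structure; it performs no structure search. The graphical-lasso variant
is intended for small taxon sets; neighborhood selection is the scalable
default.
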