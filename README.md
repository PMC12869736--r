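# saltgrad

Diversity, co-occurrence networks and drivers of soil bacteria and
archaea along natural salinity stress gradients.

`saltgrad` is an R package for microbial ecologists analysing amplicon
(ASV) count tables from surveys that span a wide abiotic stress
gradient — the motivating setting is saline alpine wetlands spanning
0.2–440 psu, with freshwater (salinity ≤ 1 psu), brackish (1–35 psu] and
saline (> 35 psu) classes. It implements the full analysis chain as
tested, reusable functions:

* **Tables & transforms** — TSV/BIOM I/O, seeded rarefaction without
  replacement, Hellinger and centered log-ratio (CLR) transforms,
  stress-class assignment.
* **Diversity** — richness/Shannon/inverse-Simpson, unprotected LSD
  group contrasts with compact letters, Cohen's *d* with the
  negligible/small/medium/large bands (|d| = 0.2/0.5/0.8), shared-ASV
  Venn fractions.
* **Beta statistics** — Hellinger + Bray–Curtis, PCoA, PERMANOVA /
  ANOSIM / MRPP, (partial) Mantel, dbRDA with double-stopping forward
  selection, VIF screening (via vegan).
* **Networks** — CLR + Meinshausen–Bühlmann neighborhood selection (or
  graphical lasso) with StARS stability selection; signed weighted
  `EcoNetwork` objects with full inference provenance; strict
  prevalence/abundance filters and per-habitat sub-networks.
* **Link processes** — sequential Mantel classification of each link
  into spatial / environmental / putative **biotic** associations, with
  BH-FDR across links.
* **Cohesion & fragility** — per-taxon positive/negative connectedness,
  abundance-weighted per-sample cohesion (within- and cross-domain),
  natural connectivity `ln(mean exp(λ))` and removal-curve fragility.
* **Gradient & drivers** — OLS vs segmented (grid-searched breakpoint)
  vs penalised-spline fits under AIC selection, top salinity responders
  with FDR, random-forest screening with permutation significance,
  mixed-model associations (Wald type-II χ², Nakagawa R²), and a
  piecewise structural equation model with Fisher's C
  (`C = −2 Σ ln p`, df = 2k, accepted when 0 < C/df < 2 and p > 0.05).
* **Synthetic communities** — a generator with planted niches, spatial
  fields, copula couplings and a facilitation factor, so every stage is
  validated against recoverable ground truth.

## Worked example

```r
library(saltgrad)

# simulate the flagship scenario and run the full pipeline
bundle <- runPipeline("paper_like", seed = 2,
                      n_taxa_bacteria = 90, n_taxa_archaea = 50)
report <- reportBundle(bundle)

report$diversity
#>     domain      class mean_richness letter
#> 1 bacteria freshwater      89.18000      a
#> 2 bacteria   brackish      84.52500      b
#> 3 bacteria     saline      75.61429      c
#> 4  archaea freshwater      25.44000      b
#> 5  archaea   brackish      23.37500      c
#> 6  archaea     saline      36.90000      a

driverHeadline(bundle)
#>       bacteria        archaea
#> "pos_cohesion"     "salinity"

bundle$gradient$bacteria$richness$fits[, c("model", "AIC", "R2", "breakpoint_psu")]
#>       model      AIC        R2 breakpoint_psu
#> 1       ols 1276.199 0.5235006             NA
#> 2 piecewise 1266.110 0.5559126       1.997623
#> 3    spline 1213.027 0.6787396             NA

networkTopology(bundle$networks$bacteria)
#>   nodes edges pct_negative mean_degree   density clustering modularity
#> 1    90   248     37.09677    5.511111 0.0619226  0.3247029  0.6859971
```

Bacterial richness declines monotonically from freshwater to saline
wetlands while archaeal richness dips in brackish sites and peaks under
high salt (the halophile block takes over); the letters are LSD
groupings at α = 0.05. The segmented fit places the bacterial stress
threshold near 2 psu, and 37% of the inferred bacterial links are
negative (mutual exclusions). `driverHeadline()` reads the standardized
coefficients of each domain's richness equation in the piecewise SEM:
bacterial diversity is best explained by the community's positive
cohesion (its facilitative association complexity), archaeal diversity
by salinity itself — the planted contrast the generator encodes.
Per-class cohesion with Cohen's *d* stars, fragility curves and the rest
of the stage outputs live in the bundle (`bundle$cohesion`,
`bundle$fragility`, `bundle$beta`, `bundle$links`).

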