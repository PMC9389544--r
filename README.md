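# metabosubtype

Metabolic heterogeneity matters clinically in gastric cancer (GC):
HER2/ERBB2-linked rewiring of glycolysis/gluconeogenesis ("GG") and
alanine–aspartate–glutamate ("AAG") metabolism separates patients with
different prognosis and different expected benefit from chemotherapy
versus immunotherapy. `metabosubtype` is an R package for the analysis
chain that establishes such a classification from serum metabolomics and
tumour expression data, built so that every stage can be exercised and
validated on synthetic cohorts with planted ground truth — no downloads,
no private data.

It is aimed at computational biologists who want a tested, scriptable
version of this workflow rather than a collection of one-off analysis
scripts.

## What it computes

**Differential metabolite screen.** For metabolite *g* with positive
intensities, the group contrast between tumour and healthy serum is
tested with an empirical-Bayes moderated t on log2 intensities: the
residual variance is shrunk to
s̃²_g = (d₀·s₀² + d_g·s²_g) / (d₀ + d_g), with the prior (d₀, s₀²)
fitted by method of moments on log s²_g (Smyth 2004), and p-values are
BH-adjusted. A metabolite is called **up** when FDR < 0.05 and raw-scale
fold change FC = mean(GC)/mean(healthy) > 1.2, **down** when FDR < 0.05
and FC < 5/6 (all inequalities strict).

**Weighted metabolite co-expression network analysis (WMCNA).** On
log2-standardized metabolites: soft-threshold scan over β = 1..20
against a scale-free fit target (signed R² ≥ 0.85), unsigned adjacency
a_ij = |r_ij|^β, topological overlap
TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij),
average-linkage clustering of 1 − TOM with a deterministic static cut,
module eigenmetabolites (first principal component, unit variance,
mean-profile orientation), module–trait correlation against the HER2
IHC score (ordinal 0–3 treated numerically), and hub selection by
module membership MM > 0.7 and metabolite significance MES > 0.15 in
trait-significant modules.

**MMI network.** Metabolite–metabolite interaction graph among selected
metabolites with edges where |Pearson r| > 0.4 (strict), exported as
GraphML.

**ssGSEA scoring and two-group GSEA.** Per-sample rank-weighted
enrichment scores (exponent α = 0.25) for immune/metabolic gene sets,
top/bottom-30% grouping, and a permutation-based weighted-KS GSEA with
NES and BH q-values; Spearman correlation of a gene or protein trait
with the score matrix.

**Consensus quadrant subtyping.** Monti-style consensus clustering
(100 reps, 80% item resampling, Ward.D2 on 1 − Pearson distance, k = 3)
of the AAG and GG pathway genes; the most coexpressed gene cluster per
pathway is selected, each sample receives the median z-score of the
selected genes per pathway, and the two medians define four subtypes:
quiescent (AAG ≤ 0, GG ≤ 0), AAG (> 0, ≤ 0), GG (≤ 0, > 0) and mixed
(> 0, > 0). Downstream: subtype-specific molecules (upregulated vs every
other subtype at per-comparison BH FDR < 0.05), per-feature
Kruskal–Wallis screens (retain p < 0.05), and Kaplan–Meier / k-group
log-rank survival comparison for OS and DSS.

All statistical primitives (BH, χ², Wilcoxon, Kruskal–Wallis, moderated
t, KM, log-rank) are implemented in the package and cross-checked in the
test suite against `stats`, `survival` and `limma`.

## Worked example

```r
library(metabosubtype)

## serum metabolome with 50 planted up- (FC 1.5) and 100 down- (FC 2/3)
## regulated metabolites among 1300, 112 GC vs 112 healthy
met <- simulate_metabolome_cohort(metabolome_sim_config(seed = 1))
screen_dems(met$abundance, met$group)
#> Differential metabolite screen: 1300 metabolites; 50 up, 100 down (engine: moderated)
#>   criteria: FDR < 0.05 and fold change > 1.2 or < 0.8333

## expression cohort with planted AAG/GG cores and four subtypes
cfg  <- expression_sim_config(seed = 7)
sim  <- simulate_expression_cohort(cfg)
sets <- make_gene_sets(cfg)
ms <- metabolic_subtype(sim$expr,
                        sets$KEGG_ALANINE_ASPARTATE_AND_GLUTAMATE_METABOLISM,
                        sets$KEGG_GLYCOLYSIS_GLUCONEOGENESIS,
                        consensus_params(seed = 7))
ms
#> Two-pathway quadrant metabolic subtyping
#>   coexpressed genes: AAG 20 / GG 20
#>
#> quiescent       AAG        GG     mixed
#>       104        88       108       100

labels <- setNames(as.character(ms$scores$subtype), ms$scores$sample_id)
adjusted_rand_index(labels[names(sim$truth$subtype)], sim$truth$subtype)
#> [1] 0.9216775

subtype_survival(sim$clinical, labels, "OS")
#> OS survival across 4 subtypes ( 400 used, 0 excluded )
#> 4-group log-rank test
#>   statistic = 41.181  df = 3  p = 5.987e-09
```

The screen recovers exactly the planted 50/100 differential metabolites;
the consensus step selects both planted 20-gene cores; subtype recovery
reaches an adjusted Rand index of 0.92 against the planted truth; and the
planted hazard ratios (GG worst at HR 2, mixed best at HR 0.5) produce a
decisive 4-group log-rank test.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the whole pipeline from scratch against the installed package —
metabolome simulation and DEM screen, WMCNA with HER2 trait statistics
and the hub MMI network, consensus quadrant subtyping with OS and DSS
log-rank tests — logging each stage's summary, and writes the JSON
report to `--out`.

## Further reading

The methods vignette (`vignettes/metabolic-subtyping.Rmd`) documents the
models and assumptions, every tunable threshold with its default and
rationale, what the synthetic generators do and do not emulate, and the
numerical conventions (tie handling, static tree cut, orientation rules,
degenerate inputs).
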