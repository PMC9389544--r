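---
title: "HER2-associated metabolic subtyping: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HER2-associated metabolic subtyping: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabosubtype)
```

This vignette is the package's account of its science: the statistical
models behind each stage, the tunable parameters and why their defaults
are what they are, what the synthetic generators emulate (and what they
deliberately do not), and the numerical conventions a careful user
should know about. It states no empirical result that the test suite or
the acceptance script does not itself compute.

## 1. The analysis chain

Gastric tumours differ in how strongly they engage
glycolysis/gluconeogenesis (GG) and alanine–aspartate–glutamate (AAG)
metabolism, and both pathways track HER2/ERBB2 levels. The package
implements the chain that turns this observation into a patient
classification:

1. **Serum metabolite screen** — which circulating metabolites separate
   tumour from healthy serum;
2. **WMCNA** — which co-abundance modules of metabolites track the HER2
   IHC score, and which members are hubs;
3. **MMI network** — the correlation graph over those hubs, for pathway
   interpretation downstream;
4. **ssGSEA / GSEA** — per-sample immune and metabolic pathway activity
   and its correlation with HER2;
5. **Consensus quadrant subtyping** — a four-class patient
   classification from the two pathway gene programs, with specific
   molecules, immune-feature screens and survival contrasts per class.

## 2. Models and assumptions

### Differential abundance

Intensities are assumed positive and roughly log-normal; group effects
are multiplicative. The test operates on log2 intensities with an
empirical-Bayes moderated t: per metabolite the pooled residual variance
$s^2_g$ (with $d_g = n_1 + n_2 - 2$ df) is shrunk towards a prior
$(d_0, s_0^2)$ estimated by method of moments on $\log s_g^2$
(Smyth 2004), giving

$$\tilde s^2_g = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
  t_g = \frac{\widehat{\Delta}_g}{\tilde s_g \sqrt{1/n_1 + 1/n_2}},$$

with $d_0 + d_g$ df (capped at the pooled residual df). Shrinkage is
what makes the screen stable at metabolome scale, and it guarantees a
positive variance for degenerate (constant) metabolites, which are
flagged. The **fold change is computed on the raw scale** as the ratio
of arithmetic group means — the common metabolomics convention, and
deliberately different from the log-scale test, so both are reported for
audit. A plain Welch-t engine is available (`engine = "welch"`) as a
sensitivity check. FDR is Benjamini–Hochberg across all metabolites
jointly; calls require *strict* inequalities (FDR < 0.05, FC > 1.2 or
FC < 5/6), so a metabolite sitting exactly on a boundary is never
called.

### WMCNA

The network is **unsigned** ($a_{ij} = |r_{ij}|^\beta$): with an
abundance trait on ordinal IHC data, anti-correlated co-regulation is as
informative as correlated, and the source analyses do not state a
signedness. The soft power $\beta$ is chosen as the smallest power whose
signed scale-free fit (regression of log-frequency on log-connectivity
over 10 equal-width bins; sign flipped when the slope is positive)
reaches 0.85. *Caveat*: on small matrices without genuine scale-free
structure the scan can overshoot to large powers, which drives all
topological overlap towards zero and dissolves modules; the fitted power
should be sanity-checked against the mean-connectivity column, and can
be forced (`wmcna(..., power = 4)`) the way published analyses fix a
power around 4.

Modules come from average-linkage clustering of the TOM dissimilarity
$1 - \mathrm{TOM}$ with a **deterministic static cut**: branches are
severed at the absolute height 0.92 on the unit-interval dissimilarity
scale, and clusters below `min_module_size = 5` are left unassigned.
The static cut was chosen over the dynamic hybrid tree cut for
determinism and testability. The quantile-of-merge-heights alternative
was evaluated and rejected: on planted block designs it cuts below the
blocks' final internal merges and splits them, and no merge-height
quantile can simultaneously keep a single all-encompassing module intact
and leave independent noise unassigned, whereas an absolute cut on the
bounded TOM scale does both (this is also the `cutreeStatic` convention
of the WGCNA tradition).

Per module the **eigenmetabolite** is the first principal component of
the standardized member profiles, scaled to unit variance and oriented
to correlate positively with the module mean profile (PC signs are
otherwise arbitrary). Module–trait association is the Pearson
correlation of the eigenmetabolite with the HER2 IHC score; the ordinal
0–3 score is treated numerically by default (a Spearman option exists)
because the scores are a graded staining intensity. **MM** is the
per-metabolite correlation magnitude with its own module's
eigenmetabolite; **MES** is interpreted as the per-metabolite
correlation magnitude with the trait — the hub criterion
"MM > 0.7 and MES > 0.15" is applied per metabolite, which is the only
reading under which a per-metabolite rule is well defined; the
module-level eigenmetabolite–trait correlation is reported separately.
Missing-trait samples are dropped pairwise (the IHC trait typically
exists for a subcohort only).

### MMI network

Edges require $|r| > 0.4$ strictly, computed on the same
log2-standardized scale as the co-expression network for internal
consistency. Isolated nodes are retained in the export so hub lists
remain complete.

### ssGSEA and GSEA

The single-sample score is the Barbie-style integrated difference: with
genes ranked by descending expression (mid-ranks for ties) and rank
weights $r$ from $N$ down to 1,

$$\mathrm{ES} = \sum_i \Big[ P^w_{\mathrm{in}}(i) - P_{\mathrm{out}}(i) \Big],
  \qquad P^w_{\mathrm{in}}(i) =
  \frac{\sum_{j \le i,\, j \in S} r_j^\alpha}{\sum_{j \in S} r_j^\alpha},$$

with $\alpha = 0.25$, the conventional default. Scores are optionally
normalized by the global max − min of the score matrix, making score
differences comparable across sets. Scores depend on expression only
through ranks, so they are invariant under any strictly monotone
per-sample transform — the property the tests verify.

Two-group GSEA ranks genes by the moderated t between the top and bottom
30% groups (the ranking metric is fixed; the grouping fraction uses
`floor(0.3 n)` per tail with ties broken by input order), uses the
weighted Kolmogorov–Smirnov running sum with weight $|t|$, and draws
significance from sample-label permutations: NES is the ES divided by
the mean |permutation ES| of the same sign, and the p-value is the
within-sign permutation tail frequency (never below
$1/(n_{\mathrm{perm}}+1)$), BH-adjusted across sets.

### Consensus subtyping

Consensus clustering follows Monti: 100 resampling rounds, each drawing
80% of the genes (items) without replacement and all samples
(`p_feature = 1`), inner Ward.D2 clustering on $1 -$ Pearson distance
cut at $k = 3$; the consensus matrix is the co-clustering frequency
among co-sampled pairs (0/0 counted as 0), and final labels come from
Ward.D2 on $1 - M$. One seeded RNG stream drives the resampling in a
fixed rep order, so results are bit-reproducible.

$k = 3$ gene clusters per pathway with **one** coexpressed group
selected is the design: the selection rule — the cluster with the
highest mean pairwise *signed* correlation, ties towards the larger
cluster then the lowest label — had to be decided here, since the source
describes "strongly coexpressed" groups without an explicit criterion.
Signed mean correlation (not $|r|$) is used because an anti-correlated
cluster is not a coherent program whose median is meaningful.

Pathway scores are per-sample **medians of z-scored** selected genes.
Z-scoring is essential: the quadrant rule thresholds at 0, which is
meaningless on raw log2 scale but marks cohort-average pathway
expression after standardization. The quadrant rule is boundary
inclusive on the $\le$ side exactly as stated: a sample at (0, 0) is
quiescent.

Specific molecules require upregulation against **every** other subtype
with BH FDR < 0.05 *within each pairwise comparison* (across features).
The per-comparison scheme was chosen over pooling all comparisons into
one FDR because the calls are intersections of three independent
contrasts; the all-three requirement is itself conservative, which the
null simulations in the tests confirm.

Survival uses the package's own Kaplan–Meier (censorings tied with an
event time remain at risk) and the k-group log-rank test with
hypergeometric variance and a generalized-inverse quadratic form
(robust to a degenerate covariance when a group runs out of events).
Samples lacking time or event for the chosen endpoint are excluded —
exactly those and no others.

## 3. Key parameters

| Parameter | Default | Where | Why |
|---|---|---|---|
| `fdr_max`, `fc_up`, `fc_down` | 0.05, 1.2, 5/6 | DEM screen | stated screening criteria; strict inequalities |
| `rsq_target` | 0.85 | soft-threshold scan | conventional scale-free fit target |
| `powers` | 1..20 | scan | standard WGCNA-style grid |
| `cut_quantile` | 0.92 | module detection | absolute static cut height on the [0,1] TOM-dissimilarity scale (see §2) |
| `min_module_size` | 5 | module detection | smallest module worth a trait test at metabolome scale |
| `mm_min`, `mes_min` | 0.7, 0.15 | hub selection | stated hub criteria, strict |
| `r_threshold` | 0.4 | MMI network | stated edge criterion, strict |
| `alpha` | 0.25 | ssGSEA | conventional rank-weight exponent |
| `k`, `reps`, `p_item`, `p_feature` | 3, 100, 0.8, 1.0 | consensus | stated consensus parameters |
| `fraction` | 0.3 | high/low grouping | stated top/bottom 30% rule |

## 4. The synthetic cohorts

`simulate_expression_cohort()` emulates a tumour expression cohort
(default n = 400, matching a TCGA-scale stomach cohort) in which each
pathway has a 20-gene coexpressed core plus 20 non-coexpressed decoy
genes inside its gene set, 2000 background genes, and four planted
subtypes in equal proportions. Core genes follow the latent-factor
construction $x_g = \sqrt\rho f + \sqrt{1-\rho}\,\varepsilon$, which
yields pairwise correlation exactly $\rho$ (default 0.8) in expectation.
The factor *is* the pathway activity: $f$ standardizes
$a_s = \mathrm{shift}\cdot\mathrm{on}_s + \eta_s$ with shift 1.5 and
intrinsic activity noise $\sigma_\eta = 0.3$. This choice — most of the
activity variance is carried by the subtype switch — reflects the
biology being emulated (pathway programs co-vary because a shared
regulator switches them) and is what makes a sign-threshold quadrant
classification recoverable at all; had the factor been pure unit
nuisance noise on top of the shift, the per-axis misclassification would
be $\Phi(-\mathrm{shift}/(2\sqrt\rho)) \approx 20\%$ and no pipeline
could reach high subtype recovery, so the generator would contradict the
very design it is meant to exercise. Survival is exponential
proportional hazards (baseline 5·10⁻⁴ per day ≈ 3.8-year median) with
planted log hazard ratios (GG log 2, mixed log 0.5 — worst and best
prognosis respectively) and uniform censoring whose horizon is solved
numerically to hit the target 30% censoring. An `ERBB2` marker gene is
planted one SD lower in the GG subtype.

`simulate_metabolome_cohort()` emulates a two-arm serum metabolome
(defaults: 112 tumour / 112 healthy samples, 1300 metabolites,
log-normal intensities with $\sigma = 0.3$ on the natural-log scale;
planted 50 up-regulated metabolites at FC 1.5 and 100 down at FC 2/3,
the mean ratio holding exactly in expectation because the shift is
applied on the log scale at equal variance). Correlated modules follow
the same latent-factor construction; the trait-linked module's factor is
correlated with a simulated HER2 IHC score drawn from the 30/11/5/5
distribution over scores 0–3 observed in a 51-patient IHC series, scaled
so the *metabolite-level* trait correlation hits its target.

What the generators do **not** emulate: batch and drift effects,
missing-value mechanisms and limits of detection, realistic KEGG
pathway topology or set overlap, correlated immune signatures, and
non-proportional hazards. A green test therefore establishes that the
pipeline recovers planted structure under clean log-normal noise — not
that it is robust to mass-spectrometry artefacts, which are upstream
QC concerns outside this package's scope.

## 5. Numerical conventions and degenerate inputs

* Rank tests use mid-ranks; the Wilcoxon switches from exact enumeration
  to the tie-corrected normal approximation above a total n of 16 (or
  whenever ties occur).
* BH is order-preserving and order-invariant; empty p-vectors error.
* The consensus matrix defines 0/0 (never co-sampled) as 0.
* All-equal score vectors partition by input order with a warning.
* Zero-variance metabolites are dropped from correlation networks with a
  warning; zero-variance features in the moderated t are shrunk to the
  prior and flagged.
* Percentages in cohort summaries round half-up to one decimal, the
  convention of printed clinical tables.
* Matrices are features × samples everywhere; TSV round trips are
  bitwise exact (`%.17g` rendering); tabular results render floats at 6
  significant digits.

## 6. Known limitations

* The WMCNA tree cut is static; fine module splitting that the dynamic
  hybrid cut would find is out of scope.
* The immune score is the ssGSEA score of a user-supplied signature;
  platform-corrected scores (ESTIMATE) and deconvolution methods are not
  re-implemented.
* Cox regression and multivariate survival models are out of scope; the
  survival layer is KM + log-rank.
* The 29 bundled immune sets produced by `make_gene_sets()` are
  placeholders of matching cardinality for testing, not curated
  signatures; real analyses must supply their own GMT.
* Headline counts from the motivating real-data analyses (e.g. module
  and hub counts from a private 51-sample metabolome) are not
  reproducible at desk scale and are not targets of the test suite;
  the suite validates properties on planted ground truth instead.
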