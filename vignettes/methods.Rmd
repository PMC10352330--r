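---
title: "Co-dependency networks and context associations: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-dependency networks and context associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Knockout of functionally related genes produces similar fitness effects
across a heterogeneous cell-line panel, so the correlation of two genes'
gene-effect profiles across many lines ("co-dependency") is a proxy for
functional relatedness. `depcornet` turns a genes × lines gene-effect
matrix into a thresholded, degree-capped co-dependency graph, calls
small modules from it, and tests each module's per-line dependency score
against molecular context.

The per-line dependency score of a module is the negated mean of its
members' gene-effect values in that line, so higher score = stronger
dependence. Averaging skips missing member values; a line is scored
missing only when every member is missing.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `effect_cutoff`, `line_fraction` | −1, 0.9 | a gene is common-essential when its effect is below −1 in strictly more than 90% of its observed lines; such genes are removed before correlation because they carry no context signal |
| `min_overlap` | 100 lines | pairwise-complete correlations from fewer shared lines are unstable and are marked missing rather than estimated |
| `matrix_cutoff` | 0.4 (signed r) | node admission: a gene enters the network only with at least one strong positive co-dependency, the complex-level step |
| `network_cutoff` | 0.34 (on \|r\|) | edge admission among admitted nodes; the looser cutoff captures cross-complex functional links |
| `k_max` | 15 | per-gene cap on retained edges (strongest by \|r\|); keeps hub neighborhoods readable |
| `max_module_size` | 15 | upper bound on called module size |
| association gates | freq ≥ 10, percentile 0.18, p < 0.05, q < 0.1, \|Δ\| > 0.1, fc 2 | see below |

The two-step cutoff is deliberate: a stringent signed cutoff (r > 0.4)
identifies complex-level interactions and defines the node set; a looser
absolute cutoff (|r| > 0.34) then draws edges among those nodes so that
weaker between-complex links are still captured. Edges are pruned to
each gene's `k_max` strongest, and an edge survives if **either**
endpoint retains it (union rule): this preserves hub–satellite edges
where the satellite's only edge is far down the hub's list. Nodes left
without edges are removed.

## Cutoff calibration

To choose (or audit) the edge cutoff, within-complex pairs from a
curated complex catalog are labelled 1 and an equal number of randomly
sampled non-catalog pairs 0. For each candidate threshold t,
sensitivity = fraction of complex-pair scores ≥ t and specificity =
fraction of random-pair scores < t. The AUC is computed as the rank
(Mann–Whitney) statistic — the probability that a random complex pair
outscores a random background pair, ties counted half — because that
form is exactly checkable against exhaustive pair enumeration. The
selected threshold maximizes Youden's J = sensitivity + specificity − 1,
with ties broken toward the larger (stricter) threshold. A per-threshold
selection rule based directly on t-test p-values was considered and
rejected: p-values saturate to machine zero for any reasonable
separation and therefore cannot rank thresholds; Youden's J is the
standard operating-point criterion on a ROC curve and is reported with
the full diagnostics table so the choice is auditable.

## Module calling

Modules are obtained deterministically: connected components of the
network that fit the size cap become modules directly; oversized
components are split by greedy modularity community detection (weights
|r|) applied recursively. When the modularity optimum refuses to split
an oversized component, the community dendrogram is cut at k = 2 to
force progress. Vertices are processed in lexicographic order, so the
partition is reproducible without randomness; singleton parts are
discarded and modules are numbered by descending mean internal |r|.
This caller replaces web-service/learned module detectors with a
transparent, dependency-free procedure; on data with block-structured
correlation it recovers planted blocks exactly (see the test suite),
but module counts on real data are approximate rather than exact
reproductions of any particular published partition.

## Association engine

All families use the pooled-variance unpaired two-tailed t-test
(df = n₁ + n₂ − 2) and report effect = mean(high/carrier group) −
mean(other group), so a positive effect always means the feature-high
(or high-dependency) group has the larger value. Zero pooled variance
returns a flagged non-significant sentinel (t = 0, p = 1) rather than an
error so family scans continue. Each family is corrected jointly by
Benjamini–Hochberg; the procedure is order-preserving, so permuting the
input order permutes, but never changes, the records.

* **Cancer type** — types with ≥ 10 annotated lines; each module × type
  contrast is type vs all other retained lines; gate q < 0.1.
* **Binary features** (mutations, signature carriers) — carriers vs
  non-carriers within a line subset; features with < 10 carriers are
  dropped; the mutational-signature convention gates on raw p < 0.05,
  other binary families on q < 0.1.
* **Continuous features** (chromatin marks, exposures) — top 18% of
  lines by feature value vs the rest; gates q < 0.1 and |Δ| > 0.1.
* **Dependency-group readouts** — lines are split into top and bottom
  18% by module score; hallmark signature scores (mean z-scored
  expression over set genes) gate on p < 0.01; drug ln-IC50, z-scored
  across lines per drug, gates on q < 0.1 and |mean z difference| > 0.2.
  Group sizes use floor(percentile · n) with ties broken by line id.
* The fold-change gate (`fc_cutoff = 2`) applies only to expression-level
  binary splits; it is exposed in the configuration for completeness.

Top-vs-bottom (rather than top-vs-rest) grouping is used for readout
contrasts, mirroring the ranked-split convention of the figure-legend
style analyses; the choice is symmetric and documented here because the
alternative is equally defensible.

The hallmark signature score is defined here as the mean across-line
z-score of the set genes' expression — a deliberate, simple replacement
for unstated enrichment-score formulas; it is monotone in coordinated
up/down-regulation of the set, which is the property the contrasts use.

## The synthetic generator

`sim_params()` defaults encode the reference study condition used by the
test suite and acceptance script: 20 disjoint planted modules of 4–8
genes among 3000 genes over 1000 lines. Each module is a one-factor
model: latent m_k ~ N(0, σ_m²) per line, member effect =
μ + λ·m_k + N(0, σ_e²), giving within-module correlation
λ²σ_m²/(λ²σ_m² + σ_e²); the defaults λ = 1, σ_m = 1, σ_e = √(2/3)
target r = 0.6, comfortably above the 0.4/0.34 cutoffs yet far from
degenerate. Fifty common essentials sit at mean −1.5 (sd 0.1), below
the filter threshold in essentially every line. Context couplings shift
a module's latent factor by `shift` latent-sd for feature carriers
(positive shift = carriers more dependent), tie continuous features
linearly to the latent factor, and tie drug ln-IC50 linearly to the
module score; the example coupling strengths (shift 1 with 10% carriers,
drug slope −0.8 with noise sd 0.5) are strong-but-realistic planted
effects that a working pipeline should detect with power ≥ 0.9 at these
sample sizes. All draws flow from one seeded stream in a documented
order, so bundles are bit-reproducible.

What the generator does **not** emulate: missing-data patterns of merged
screening projects (the matrix is complete unless you blank entries),
lineage-driven covariance between modules, overlapping complexes,
heavy-tailed screening artifacts, and batch effects. Passing tests
therefore demonstrate correctness of the machinery under a clean factor
model, not robustness to every pathology of real screens.

## Numerical choices and degenerate inputs

* Correlations on pairs with zero variance or insufficient overlap are
  missing, never 0; missing values propagate and are never imputed.
* The correlation matrix uses a complete-data fast path when no entries
  are missing; both paths produce identical results on complete data.
* Ranked splits error on constant inputs (no meaningful order) and on
  group sizes below 2; binary features with no contrast group are
  dropped with a warning, not an error.
* All tie-breaks (edge pruning, ranked splits, module ordering) are by
  lexicographic id, making every pipeline stage deterministic given the
  seed.
* Problem sizes in the test suite (micro-bundles of 30–60 genes,
  200–300 lines; 200 null replicates at 40 genes × 300 lines; the
  reference condition at 3000 × 1000) were chosen as the smallest sizes
  at which the asymptotic behaviour being tested is clearly expressed.

## Known limitations

* Negative-r edges are admitted by the |r| edge cutoff but node
  admission requires a positive strong partner; a gene whose only strong
  couplings are negative is excluded by construction.
* The greedy-modularity splitter optimizes modularity, not the planted
  block likelihood; on networks with weak between-block bridges it can
  in principle absorb a bridge node into the wrong side. The size cap
  bounds the damage.
* BH control is per family; no global correction across families is
  attempted, matching per-analysis reporting conventions.
* The ROC t-test p-value is reported for descriptive purposes only and
  plays no role in threshold selection.
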