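---
title: "Immune evasion subtyping: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune evasion subtyping: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunevasion)
```

## The problem

Bulk tumor expression cohorts mix patients whose tumors escape the immune
system in different ways. Receptor subtypes (HER2, Luminal A/B, TNBC) do
not track these escape routes, which is one reason checkpoint-inhibitor
response rates are poor when patients are selected on receptor status or
single markers. This package groups patients by coherent immune-gene
expression and reads an evasion mechanism off each group, using normal
tissue as the reference for what "up-regulated" means.

## The plaid model

An expression matrix `Y` (genes × patients, log2 scale) is modelled as a
two-way additive background plus additive layers restricted to subsets of
rows and columns:

$$Y_{ij} = \mu_0 + \alpha_{0i} + \beta_{0j} +
  \sum_k \rho_{ik}\kappa_{jk}\,(\mu_k + \alpha_{ik} + \beta_{jk}) + \varepsilon_{ij},$$

with binary memberships $\rho, \kappa$, zero-sum constraints on each
layer's $\alpha$ and $\beta$ (identifiability), and i.i.d. Gaussian error.
Layers are fitted greedily on the running residual. Within a layer the fit
alternates: two-way least squares of the effects on the member submatrix,
then a membership pass in which a row joins iff matching it to the layer's
effect field strictly reduces its residual sum of squares
($\sum_j (Z_{ij}-\theta_{ij})^2 < \sum_j Z_{ij}^2$, candidates entering
with $\alpha_i = 0$), and symmetrically for columns. Ties exclude, so
zero-signal rows cannot drift in.

Three numerical choices matter:

* **Initialization.** Each layer starts from the leading singular vector
  pair of the residual, thresholded at zero (the sign giving the larger
  fitted layer sum of squares wins). This is deterministic, so the only
  randomness in the whole fit is the permutation test, and one integer
  seed reproduces a run exactly.
* **Release pruning.** A member row's contribution is its residual
  sum-of-squares reduction $d_i$; rows with
  $d_i < \texttt{row\_release} \times \overline{d}$ (the *mean* member
  contribution) are released, columns analogously, both measured on the
  same pre-prune fit. The cutoff is deliberately relative to the typical
  member rather than the best one: contributions of genuine members of a
  homogeneous layer scatter around a common mean with spread
  $\approx 2\sigma\sqrt{\Sigma\theta^2}$, so a max-relative cutoff at 0.7
  would release a large share of true members on every application and
  erode real layers to fragments, while the mean-relative cutoff removes
  free riders and leaves homogeneous layers intact for any threshold
  below 1. Pruning runs after `iter_startup` membership passes.
* **Acceptance.** A fitted layer is kept only if its sum of squares
  exceeds that of a layer fitted (same budget) to each of `n_shuffles`
  copies of the residual with entries permuted within rows — permuting
  within rows preserves every gene's marginal distribution while
  destroying gene–patient association. `n_shuffles = 0` disables the test
  (documented escape hatch; it also makes the fit fully deterministic).
  Residuals below a relative floor (`1e-12` of the mean square of `Y`)
  stop extraction so numerical dust is never fitted.

Defaults (`plaid_params()`): full `m+a+b` layer model, releases 0.7,
3 shuffles, 5 startup + 10 total iterations, at most 20 layers. Genes are
rows and patients are columns throughout; the clusters of interest are
column (patient) sets.

## Sequential extraction and the 5% rule

Plaid layers may share patients. To get disjoint groups,
`sequential_bicluster()` refits the plaid model each round on the remaining
patients and promotes the earliest accepted layer with at least
`min_fraction` (default 0.05) of the **original** cohort, then removes
those patients. Two open points were settled as follows:

* The size threshold is read against the original cohort size, not the
  shrinking remainder — a fixed absolute bar is what guarantees each
  cluster is a representative slice of the population; with a relative
  bar, late rounds could promote tiny groups.
* Extraction stops when a round yields no qualifying layer (or at
  `max_rounds`, default 25). Unassigned patients are labelled `"other"`.

Reproducibility across seeds is the Rand-type concordance γ: the fraction
of patient pairs co-clustered in both runs or separated in both.
Unclustered patients keep the shared `"other"` label and therefore
participate in γ; the statistic is defined over all n patients and
excluding them would inflate agreement for runs that cluster little.

## Differential expression and direction calls

Each cluster is compared per gene against (a) all other tumors and (b)
normal samples, with Welch's unequal-variance t-test — cluster and
reference variances have no reason to be equal — and a log2 fold-change
cutoff. Calls: `up` iff p ≤ `p_thresh` and log2FC ≥ `fc_thresh`; `down`
symmetrically; else `not_up`. Defaults `p_thresh = 0.05` and
`fc_thresh = 1` log2 unit (a two-fold change) are package choices echoed
into every output; no multiple-testing correction is applied by default
(an optional BH flag exists) because each cluster's call set feeds a
coarse boolean rule engine rather than a gene-level discovery list.
Degenerate zero-variance comparisons are defined by convention (equal
means: p = 1; different: p = 0). Mechanism calling uses the
tumor-vs-normal calls only: a gene can exceed other tumors while still
sitting below normal, so the normal reference is the meaningful one.

## The mechanism rule engine

Rules are declarative boolean clauses (`any_up`, `all_not_up`,
`at_least_k_up`, `and`/`or`) over the 21-gene vocabulary, shipped as
editable YAML (`inst/extdata/mechanism_rules.yaml`). "Not up-regulated"
means the call is `down` *or* `not_up` — down-regulation is not required.
One genuinely ambiguous precedence was settled: the impaired-presentation
rule (M5) chains "presentation gene not up AND T-cell gene not up AND
(cytotoxicity gene up OR TGF-β1 up)". The final disjunct is nested inside
the conjunction: a bare top-level "or TGF-β1 up" would make M5 a subset of
M1 and collide with M6. Under this reading M5 (effectors present,
presentation impaired) and M6 (no danger signals at all) are mutually
exclusive for every input, which the tests verify by exhaustive
enumeration against an independently coded evaluation of the rules.

Note the rules interlock: TGF-β1 up with silent presentation genes implies
both M1 and M5; a fully silent vocabulary implies M6. The synthetic
generator therefore records as planted truth the mechanism set implied by
its intended direction calls, not the nominal plan — any other convention
would make the planted truth internally inconsistent.

## Clinical association

For each (cluster, label value), a 2×2 Fisher exact test compares the
cluster's with/without counts against reference counts. The default
reference is the **whole labeled cohort's totals** (cluster included):
this is the construction that asks whether a cluster's split differs from
the overall pattern, and it exactly reproduces the p-values printed
alongside published cluster-by-subtype count tables of this analysis
style, which a cluster-vs-rest construction does not. `reference = "rest"`
is available. For labels with more than two values,
`omnibus_enrichment()` runs one 2×k exact test per cluster against the
totals. Samples missing a label are excluded from all denominators, so
different labels can have different cluster sizes. No multiple-testing
correction is applied (each table is reported with its raw p and a
p ≤ 0.05 flag).

## Biomarker tree

A single Gini classification tree (`grow_tree()`) predicts cluster
membership from expression: exhaustive scan over genes and midpoints
between consecutive distinct values, split accepted when the node has
≥ `min_split` samples, both children ≥ `min_leaf`, and the data-share
weighted impurity decrease is ≥ `cp` times the root impurity (defaults
20 / 7 / 0.01, mirroring common recursive-partitioning practice). All
tie-breaks are deterministic (lexicographic gene, then lower threshold;
leaf ties to the lexicographically smallest label), so the tree needs no
seed; only the stratified cross-validation folds are seeded. A single
tree trades accuracy for interpretability deliberately — the output is a
short gene/cutoff rule list a clinician can read.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` plants exactly the structure the model assumes:
additive background (grand mean 8, gene-effect SD 1.5, sample-effect SD
0.25 on the log2 scale), disjoint column-block layers, mechanism
signatures shifted +2 log2 units over the normal baseline, marker genes
shifted +3 SD, i.i.d. Gaussian noise (SD 1), and per-cluster tilted
categorical labels. It does **not** emulate real RNA-seq: no gene–gene
correlation, no library-size or batch effects, no heavy-tailed or
count-level noise, no overlap between mechanism and layer genes. Passing
recovery tests therefore show the pipeline recovers the structure it
models when that structure is present — not that TCGA-scale data satisfy
those assumptions.

Validation problem sizes were chosen to exercise every stage while keeping
the full suite fast: cluster recovery uses 500 genes × 200 tumors with
three planted 40-patient clusters (layer effect 2, noise SD 1) over 10
seeds; mechanism recovery 10 cohorts of 160 tumors with 40 per cluster;
the tree check 40 cohorts of 120 tumors; the null calibration 1,000 genes
at 30 vs 30.

## Known limitations

* The plaid fitter assumes complete, finite matrices; impute or filter
  upstream.
* Clusters are defined by a single layer each; the residual unclustered
  patients ("other") are reported but not characterized.
* The mechanism vocabulary and therapy map are configuration, not claims:
  suggestions are hypothesis-generating, not clinical guidance.
* The exact test reference construction ("cohort") counts the cluster in
  its own reference margin; with very large clusters this is conservative.
* Percentages and γ are sensitive to how missing labels distribute across
  clusters, because denominators shrink per cluster.
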