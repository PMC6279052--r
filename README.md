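# immunevasion

Tumors escape immune destruction through a handful of recurrent mechanisms —
TGF-β/IL-10 immunosuppression, checkpoint-mediated tolerance (CTLA4,
PD-1/PD-L1, IFN-γ), resistance to apoptosis, counterattack via decoy
receptor 3, impaired antigen presentation, and ignorance (no danger
signals) — and different patients rely on different combinations of them.
`immunevasion` subtypes a tumor cohort by these mechanisms from bulk log2
expression of immune-related genes, for analysts who want
mechanism-level patient groups rather than receptor subtypes, and
biomarkers to assign new patients to those groups.

## The method

1. **Plaid biclustering.** Expression is modelled as
   `Y_ij ≈ (μ0 + α0_i + β0_j) + Σ_k ρ_ik κ_jk (μ_k + α_ik + β_jk)`:
   a two-way additive background plus additive *layers* active only on a
   subset of genes (rows) and patients (columns). `fit_plaid()` extracts
   layers greedily from the running residual with binary membership
   updates, release pruning of weak members, and a within-row permutation
   test that stops extraction when a layer is no better than shuffled data.
2. **Sequential cluster extraction.** Layers can overlap in patients;
   `sequential_bicluster()` repeatedly refits the plaid model, promotes the
   earliest layer covering ≥ 5% of the original cohort to a cluster, and
   removes its patients — yielding disjoint, representative patient groups.
   Reproducibility across seeds is measured by `pairwise_concordance()`,
   the Rand index γ = Σ_{i<j} δ_ij / C(n,2), where δ_ij = 1 when a patient
   pair is co-clustered in both runs or separated in both.
3. **Differential expression.** `de_table()` compares each cluster per gene
   against the other tumors and against normal tissue (Welch t-test +
   log2 fold-change cutoffs), calling each gene up / down / not up.
4. **Mechanism calling.** `call_mechanisms()` applies a declarative boolean
   rule set over the tumor-vs-normal calls (e.g. *M2: CTLA4 up, or PD-1 up
   together with PD-L1/2 up, or IFN-γ up*) and `therapy_suggestions()` maps
   active mechanisms to candidate immunotherapies.
5. **Clinical association.** `enrichment_scan()` tests each (cluster,
   label) pair by Fisher's exact test against the labeled cohort's totals;
   `composition()` tabulates the underlying counts and percentages.
6. **Biomarkers.** `grow_tree()` fits a Gini classification tree predicting
   cluster membership from expression; `extract_biomarkers()` reports the
   split genes with their log2 cutoffs.

`generate_cohort()` simulates cohorts with planted layers, mechanism
signatures, biased clinical labels, and marker genes, so the whole pipeline
is testable against known ground truth.

## Worked example

```r
library(immunevasion)

coh <- generate_cohort(
  n_genes = 300, n_tumor = 200, n_normal = 50,
  layers = list(list(n_genes = 60, n_cols = 40, mu = 2),
                list(n_genes = 60, n_cols = 40, mu = 2),
                list(n_genes = 60, n_cols = 40, mu = 2)),
  mechanism_plan = list(`1` = c("M1", "M4"), `2` = "M2", `3` = "M5"),
  label_plan = list(name = "histology", values = c("IDC", "ILC"),
                    base_probs = c(0.8, 0.2), odds = list(`1` = c(ILC = 8))),
  noise_sd = 1, seed = 42)

parts <- split_by_role(coh$expr)
asg <- sequential_bicluster(parts$tumor, min_fraction = 0.05, seed = 42)
asg
#> cluster_assignment: 200 patients, 3 cluster(s), 58.5% clustered
#>     1     2     3 other
#>    39    40    38    83
```

Three disjoint clusters close to the planted 40-patient groups; the
remaining patients stay in `"other"`. Mechanisms for one cluster:

```r
de1 <- de_table(parts$tumor, asg, "1", parts$normal)
mc1 <- call_mechanisms(de1, cluster = "1")
mc1
#> mechanism_call (cluster 1): M1, M4, M5
therapy_suggestions(mc1)
#> [1] "anti-TGF-beta1" "anti-DcR3"      "DC vaccine"
```

The planted signature (TGF-β1/IL-10 immunosuppression plus DcR3
counterattack) is recovered; M5 joins because TGF-β1 up-regulation with
silent antigen-presentation genes also satisfies the impaired-presentation
rule. The planted ILC bias is detected:

```r
subset(enrichment_scan(asg, coh$clinical, "histology"),
       significant & cluster != "other")
#>   cluster label_value in_with in_without ref_with ref_without odds_ratio      p_value significant
#> 1       1         IDC      14         25      144          56  0.2177778 2.947218e-05        TRUE
#> 2       1         ILC      25         14       56         144  4.5918367 2.947218e-05        TRUE
```

and a three-gene tree separates the clusters (cross-validated error 0.20):

```r
clustered <- names(asg$labels)[asg$labels != "other"]
X <- t(unclass(parts$tumor)[, clustered])
extract_biomarkers(grow_tree(X, asg$labels[clustered]))
#>        gene depth thresholds
#> 1 gene_0113     0    6.5439
#> 2 gene_0108     1    8.3210
#> 3 gene_0098     2    8.0595
```

One call runs all stages and writes TSV/JSON outputs plus a report:

```r
run_pipeline(system.file("extdata", "demo_cohort.yaml", package = "immunevasion"),
             out_dir = "demo_out")
```

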