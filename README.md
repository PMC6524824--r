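# apasig

Cell-type-specific alternative-polyadenylation signatures from
full-length single-cell RNA-seq.

## The problem

Alternative polyadenylation (APA) changes the length of a transcript's
3'UTR, and widespread 3'UTR **shortening** accompanies proliferation in
cancer and activated immune cells. Full-length scRNA-seq permits per-cell
estimates of 3'UTR length change — as DaPars-style ΔPDUI values (negative
= shortening) or Roar-style ratios (> 1 = shortening) — alongside TPM
expression. `apasig` asks: *which gene sets (or genes) show 3'UTR
shortening coupled with over-expression specifically in one cell type* —
tumor, B, T, myeloid, or stromal — and what that implies for tumor-type
differences and patient survival.

## The method

For a component *g* (a gene set after single-sample GSEA, or a single
gene) and a cell type *t*:

1. **Shortening orientation.** APA scores are oriented so larger = shorter
   3'UTR: *s* = −ΔPDUI (dapars) or *s* = log₂(ratio) (roar). Expression is
   log₂(TPM + 1).
2. **Enrichment.** Both channels are converted to component × cell
   matrices by ssGSEA: within each cell, genes are ranked by value, the
   gene at descending rank *j* gets weight |N − j + 1|^τ (τ = 0.25), and
   the score is the sum over the ranked list of the difference between
   the in-set cumulative weight fraction and the out-of-set cumulative
   count fraction.
3. **Variable components.** Each component's variation level is its s.d.
   across cells; components above the baseline (mean + s.d. of all
   variation levels) are kept.
4. **The joint signature statistic.** Each cell is flagged when it lies
   strictly above the global medians of both *s*-enrichment and
   expression-enrichment. The 2×2 table (A = in-type flagged, B =
   out-of-type flagged, C/D their complements) gives OR = AD/BC with a
   two-sided Fisher exact p; the within-type Pearson correlation *r*
   between the two channels gets a Fisher-Z p (z = atanh r, se =
   1/√(n−3)). A **hit** requires *r* > 0 (p < 0.05) **and** OR > 2
   (p < 0.01).
5. **Downstream.** Tumor types are contrasted per set by delta (mean
   in-type − others, Welch t); hit sets are clustered by parent-GO-term
   Jaccard (> 0.5 edges, components > 9 kept); survival is stratified by
   expression quartiles (≤ 25th = low, ≥ 75th = high), administratively
   censored at 10 years, and tested by Kaplan–Meier/log-rank plus
   multivariate Cox.

A synthetic-cohort generator (`simulate_cohort()`) plants type-specific
shortening + over-expression signatures with known ground truth, so the
entire pipeline is testable without controlled-access data.

## Worked example

```r
library(apasig)
library(dplyr)

cohort <- simulate_cohort(sim_config(seed = 1))
#> <sim_cohort> 2000 genes x 200 cells, 5 cell type(s), 300 gene set(s), dialect 'dapars'

result <- run_signature_pipeline(cohort$apa, cohort$expression,
                                 cohort$annotation, cohort$gene_sets)
#> <apa_pipeline> 300 component(s) scored, 15 variable, 15 hit pair(s)

glance(result$signatures)
#> # A tibble: 5 × 7
#>   cell_type n_tested n_eligible n_hits alpha_pcc alpha_or or_min
#> 1 B               15         15      3      0.05     0.01      2
#> 2 T               15         15      3      0.05     0.01      2
#> 3 myeloid         15         15      3      0.05     0.01      2
#> 4 stromal         15         15      3      0.05     0.01      2
#> 5 tumor           15         15      3      0.05     0.01      2

tidy(result$signatures) |> filter(hit) |> head(3)
#>   component cell_type n_type   pcc    pcc_p  A  B C   D odds_ratio     or_p  hit
#> 1    GS0005         B     40 0.746 4.54e-09 40 23 0 137        474 4.58e-26 TRUE
#> 2    GS0006         B     40 0.684 3.69e-07 40 23 0 137        474 4.58e-26 TRUE
#> 3    GS0004         B     40 0.820 2.00e-12 40 24 0 136        451 1.22e-25 TRUE
```

The screen kept the 15 variable components — exactly the 15 planted
sets (3 per type) — and called each one a hit in its own cell type: the
B-specific sets correlate strongly within B cells (r ≈ 0.7–0.8) and all
40 B cells sit jointly above both medians (A = 40, C = 0, OR ≈ 470).
`autoplot(result$signatures)` draws the OR-versus-r panels per cell type.

Survival stratification on a simulated two-group cohort with a planted
log hazard ratio of 1:

```r
sv <- simulate_survival(survival_sim_config(n_patients = 200,
                                            log_hazard_ratio = 1, seed = 1),
                        group = rep(c(0, 1), 100))
sv$group <- ifelse(sv$group == 1, "high", "low")
lr <- logrank_test(censor_at_horizon(sv))
#> chi-square: 54.39   p: 1.65e-13
```

The `high` group's excess hazard is detected decisively;
`autoplot(km_fit(censor_at_horizon(sv)))` draws the two product-limit
curves.

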