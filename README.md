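# ovasig

Integrative multi-cohort prognostic signature analysis for gene
expression data, built around the workflow used in ovarian-cancer
outcome studies: merge several expression cohorts into one training set
with empirical-Bayes batch adjustment, fit a supervised
principal-component survival classifier on survival-screened genes,
assign high/low risk groups by leave-one-out cross-validation with
permutation significance, transfer the frozen model to co-adjusted
validation cohorts, and characterize the risk phenotypes by subclass
mapping between cohorts, gene-set analysis (maxmean / EASE) and
Bayesian probit pathway-activation scoring.

## Who it is for

Computational biologists who have several genes-by-samples log2
expression matrices with survival annotation (GCT/TSV + CSV clinical
tables) and want a tested, reproducible implementation of this whole
pipeline — plus a synthetic-data module that generates complete
multi-batch studies with known ground truth, so every stage can be
validated without touching real data.

## The model at the core

Genes are screened by univariate Cox regression of overall survival on
standardized expression (score test at `beta = 0`, Newton-refined
coefficients; compiled, so cross-validation loops are fast). Genes with
`p < 0.05` are ranked by `|beta|`; the top *k* enter a principal
component decomposition, and survival is regressed on the leading
components:

```
h(t | x) = h0(t) * exp( sum_p beta_p * PC_p(x) )
```

The risk score is the PC-Cox linear predictor; samples above the median
score form the high-risk group. Cross-validated risk groups re-run the
entire pipeline (screening, ranking, PC fit, Cox fit) on every
leave-one-out fold. Because the risk direction is still selected using
all outcomes jointly, the asymptotic log-rank p of the cross-validated
split is anticonservative; the calibrated significance is the
permutation p, which repeats the whole cross-validation on survival
data reassigned at random (`B = 100` by default). Batch effects are
removed by a location/scale empirical-Bayes adjustment (parametric and
nonparametric modes, verified against the reference implementation);
model transfer co-adjusts `[training | validation]` with cohort as
batch and applies the frozen model without re-estimation.

## Worked example

A three-batch synthetic study with 20 planted prognostic genes
(`beta = 0.8` per SD of the latent risk score) and strong batch
effects:

```r
library(ovasig)
study <- simulate_integration_study(sim_config(
  n_batches = 3, samples_per_batch = 80, n_genes = 1500,
  n_prognostic = 20, beta = 0.8, gamma_sd = 2, seed = 42))
study$expression
#> ExpressionMatrix: 1500 genes x 240 samples
#> batches: batch1(80), batch2(80), batch3(80)

adj <- combat_adjust(study$expression)$adjusted
ranked <- screen_and_rank(adj, study$clinical, alpha = 0.05)
head(ranked, 5)
#>    gene       coef            p
#> 1 G0019  0.7467592 2.572495e-16
#> 2 G0015  0.7076152 2.202623e-15
#> 3 G0009  0.7042390 1.531271e-15
#> 4 G0005  0.7016930 2.594428e-14
#> 5 G0010 -0.6884048 1.208141e-14
sum(study$truth$prognostic_gene_ids %in% ranked$gene)
#> [1] 20
```

All 20 planted genes pass the screen, with coefficients near the
planted per-SD log-hazard. Cross-validated risk groups and their
survival split:

```r
cv <- loocv_risk_groups(adj, study$clinical, top_k = 20)
table(cv$assignment$group)
#> high  low
#>  120  120
km <- km_estimate(study$clinical$os_months, study$clinical$event,
                  cv$assignment$group)
c(high = km$high$median, low = km$low$median)
#>     high      low
#> 21.62276 53.51214
perm <- permutation_pvalue(adj, study$clinical, top_k = 20, B = 50, seed = 7)
perm$p
#> [1] 0.01960784
```

The high-risk group's median overall survival is 21.6 months versus
53.5 months for the low-risk group, and no permutation out of 50
reaches the observed log-rank statistic (add-one p = 0.0196) — the
pipeline recovers the planted program and certifies it without
selection-bias optimism. `apply_model()` then scores a co-adjusted
validation cohort with the frozen model, `run_submap()` checks that the
risk phenotypes correspond across cohorts, and `gsa()` /
`ease_analysis()` / `train_signature()` + `predict_activation()`
characterize them functionally.

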